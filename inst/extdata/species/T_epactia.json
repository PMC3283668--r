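{
  "name": "T_epactia",
  "stages": ["seed", "seedling", "adult2", "adult3", "postclimax"],
  "matrix": [0, 0, 4, 4, 0, 1, 0, 0, 0, 0, 0, 0.5, 0, 0, 0, 0, 0, 0.9, 0, 0, 0, 0, 0, 0.9, 0.9],
  "fire_response": "facultative_resprouter",
  "dispersal_mode": "seed_global",
  "climax_stage": 3,
  "post_climax_survival": 0.9,
  "adult_stages": [3, 4, 5],
  "seedling_stage": 2,
  "germination": 1,
  "fire_gated_germination": true,
  "fire_survival": [0, 0, 0.9, 0.9, 0.9],
  "postfire_propagules": 0
}
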