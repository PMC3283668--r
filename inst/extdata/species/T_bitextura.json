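{
  "name": "T_bitextura",
  "stages": ["ramet", "adult2", "adult3", "adult4", "adult5", "postclimax"],
  "matrix": [0, 0.6, 0.6, 0.6, 0.6, 0.6, 0.9, 0, 0, 0, 0, 0, 0, 0.9, 0, 0, 0, 0, 0, 0, 0.9, 0, 0, 0, 0, 0, 0, 0.9, 0, 0, 0, 0, 0, 0, 0.9, 0.9],
  "fire_response": "obligate_resprouter",
  "dispersal_mode": "vegetative_neighbour",
  "climax_stage": 5,
  "post_climax_survival": 0.9,
  "adult_stages": [1, 2, 3, 4, 5, 6],
  "germination": 1,
  "fire_gated_germination": false,
  "fire_survival": [0.42, 0.42, 0.42, 0.42, 0.42, 0.42],
  "postfire_propagules": 0.2
}
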