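{
  "name": "Triodia_sp",
  "stages": ["seed", "seedling", "adult2", "adult3", "adult4"],
  "matrix": [0, 0, 0.22, 11, 11, 1, 0, 0, 0, 0, 0, 0.5, 0, 0, 0, 0, 0, 0.9, 0, 0, 0, 0, 0, 0.9, 0],
  "fire_response": "obligate_seeder",
  "dispersal_mode": "seed_global",
  "climax_stage": 4,
  "senescence_age": 4,
  "adult_stages": [3, 4, 5],
  "seedling_stage": 2,
  "germination": 1,
  "fire_gated_germination": true,
  "fire_survival": [0, 0, 0, 0, 0],
  "postfire_propagules": 0
}
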