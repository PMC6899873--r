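[
  {
    "id": 1,
    "name": "csf",
    "T1": 2569,
    "T2": 329,
    "PD": 1,
    "texture_sd": 0.04,
    "texture_scale": 2.2
  },
  {
    "id": 2,
    "name": "gray_matter",
    "T1": 833,
    "T2": 83,
    "PD": 0.86,
    "texture_sd": 0.1,
    "texture_scale": 1
  },
  {
    "id": 3,
    "name": "white_matter",
    "T1": 500,
    "T2": 70,
    "PD": 0.77,
    "texture_sd": 0.06,
    "texture_scale": 1.6
  },
  {
    "id": 4,
    "name": "fat",
    "T1": 350,
    "T2": 70,
    "PD": 1,
    "texture_sd": 0.12,
    "texture_scale": 0.7
  },
  {
    "id": 5,
    "name": "muscle",
    "T1": 900,
    "T2": 47,
    "PD": 1,
    "texture_sd": 0.09,
    "texture_scale": 1.3
  },
  {
    "id": 6,
    "name": "skin",
    "T1": 570,
    "T2": 30,
    "PD": 0.85,
    "texture_sd": 0.08,
    "texture_scale": 0.9
  },
  {
    "id": 7,
    "name": "skull",
    "T1": 380,
    "T2": 20,
    "PD": 0.15,
    "texture_sd": 0.14,
    "texture_scale": 0.6
  },
  {
    "id": 8,
    "name": "glial_matter",
    "T1": 790,
    "T2": 90,
    "PD": 0.88,
    "texture_sd": 0.11,
    "texture_scale": 1.9
  },
  {
    "id": 9,
    "name": "connective_tissue",
    "T1": 600,
    "T2": 55,
    "PD": 0.7,
    "texture_sd": 0.13,
    "texture_scale": 1.1
  },
  {
    "id": 10,
    "name": "marrow",
    "T1": 420,
    "T2": 45,
    "PD": 0.9,
    "texture_sd": 0.07,
    "texture_scale": 2.5
  }
]
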