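name: cirrhosis_CP_B
population: {category: cirrhosis_CP_B, age_range: [20, 50], sex_ratio: 0.5}
regimen: regimen_A
seed: 20
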