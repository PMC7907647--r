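name: pediatric_6_12
population: {category: pediatric, age_range: [6, 12], sex_ratio: 0.5}
regimen: regimen_A
seed: 20
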