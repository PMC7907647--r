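name: pregnancy_week_37
population: {category: pregnant, age_range: [20, 50], gestational_week: 37}
regimen: regimen_A
seed: 20
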