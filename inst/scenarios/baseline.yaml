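name: baseline
population: {category: healthy, age_range: [20, 50], sex_ratio: 0.5}
regimen: regimen_A
seed: 20
compare_to_baseline: false
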