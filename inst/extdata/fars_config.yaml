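n_informants: 200
n_species: 31
n_families: 21
n_categories: 15
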