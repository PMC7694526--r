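name: pam3_slab_5
geometry: slab
box_A: [500, 100, 100]
layer_A: 100
solute: Pam3CSK4
solute_pct: 5
matrix: table1
duration_ns: 300
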