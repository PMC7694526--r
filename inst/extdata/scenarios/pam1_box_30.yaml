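name: pam1_box_30
geometry: box
box_A: [280, 280, 280]
solute: Pam1CSK4
solute_pct: 30
matrix: table1
duration_ns: 10
basis: bead
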