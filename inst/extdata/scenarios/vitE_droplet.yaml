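name: vitE_droplet
geometry: droplet
box_A: [280, 280, 280]
droplet_radius_A: 130
composition: {water: 750, PLA_70: 125, vitaminE: 117}
comp_scale: 2
matrix: table2
duration_ns: 30
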