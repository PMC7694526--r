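name: pam1_droplet
geometry: droplet
box_A: [280, 280, 280]
droplet_radius_A: 130
composition: {water: 201, PLA_70: 67, Pam1CSK4: 1}
comp_scale: 4
matrix: table1
duration_ns: 30
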