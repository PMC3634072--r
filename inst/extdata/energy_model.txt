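# Simplified nearest-neighbour RNA energy model, 37 C, kcal/mol.
# stack <outer pair> <inner pair> <dG>: energy of stacking the inner base
# pair directly on the outer one inside a helix. Pairs are written
# 5'base + 3'base of the closing pair. Table is symmetric in the two
# pairs; magnitudes follow Turner-style averages for Watson-Crick steps,
# with G:U wobble steps at reduced stability.
stack AU AU -1.1
stack AU UA -0.9
stack AU GC -2.1
stack AU CG -2.2
stack AU GU -0.6
stack AU UG -1.0
stack UA UA -1.3
stack UA GC -2.1
stack UA CG -2.4
stack UA GU -1.0
stack UA UG -0.8
stack GC GC -3.3
stack GC CG -3.4
stack GC GU -1.5
stack GC UG -2.1
stack CG CG -3.3
stack CG GU -1.4
stack CG UG -2.1
stack GU GU -0.5
stack GU UG -0.6
stack UG UG -0.5
# Loop penalties (kcal/mol), linear in unpaired length:
#   hairpin loop of n nt  : hairpin_base + hairpin_slope * (n - min_loop)
#   bulge of n nt         : bulge_base + bulge_slope * n
#   internal loop n1 x n2 : internal_base + internal_slope * (n1 + n2)
hairpin_base 5.4
hairpin_slope 0.15
bulge_base 6.0
bulge_slope 0.8
internal_base 6.5
internal_slope 0.8
# Structural limits
min_loop 3
max_interior 15
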