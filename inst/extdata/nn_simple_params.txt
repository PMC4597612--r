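# Simplified nearest-neighbor free-energy parameters, kcal/mol at 37 C.
# STACK <closing pair> <stacked pair> <dG>: pairs written 5'i 3'j; the
#   stacked pair is (i+1, j-1). All 36 contexts over {AU,UA,CG,GC,GU,UG}.
# HAIRPIN/BULGE/INTERNAL <n unpaired> <dG>: loop initiation by length;
#   lengths beyond the table are extrapolated with 1.75*R*T*ln(n/nmax).
# MULTI a|b|c: affine multibranch cost (offset, per branch, per unpaired).
# No dangling ends, no helix-end penalties, no special tetraloops.

STACK AU AU -0.9
STACK AU CG -2.2
STACK AU GC -2.1
STACK AU UA -1.1
STACK AU GU -0.6
STACK AU UG -1.4
STACK CG AU -2.1
STACK CG CG -3.3
STACK CG GC -2.4
STACK CG UA -2.1
STACK CG GU -1.4
STACK CG UG -2.1
STACK GC AU -2.4
STACK GC CG -3.4
STACK GC GC -3.3
STACK GC UA -2.2
STACK GC GU -1.5
STACK GC UG -2.5
STACK UA AU -1.3
STACK UA CG -2.4
STACK UA GC -2.1
STACK UA UA -0.9
STACK UA GU -1.0
STACK UA UG -1.3
STACK GU AU -1.3
STACK GU CG -2.5
STACK GU GC -2.1
STACK GU UA -1.4
STACK GU GU -0.5
STACK GU UG 1.3
STACK UG AU -1.0
STACK UG CG -1.5
STACK UG GC -1.4
STACK UG UA -0.6
STACK UG GU 0.3
STACK UG UG -0.5

HAIRPIN 3 5.4
HAIRPIN 4 5.6
HAIRPIN 5 5.7
HAIRPIN 6 5.4
HAIRPIN 7 6.0
HAIRPIN 8 5.5
HAIRPIN 9 6.4

BULGE 1 3.8
BULGE 2 2.8
BULGE 3 3.2
BULGE 4 3.6
BULGE 5 4.0
BULGE 6 4.4

INTERNAL 2 1.5
INTERNAL 3 1.6
INTERNAL 4 1.7
INTERNAL 5 1.8
INTERNAL 6 2.0

MULTI a 3.4
MULTI b 0.4
MULTI c 0.0
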