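# Macroscopic reactions of the day/night carbon-storage model of
# Tisochrysis lutea (one reaction per sub-network elementary mode).
# Light is a non-material pseudo-species (photon count).
MR1: 30 Light + 3 CO2 + 2 H2O + Pi -> GAP + 3 O2
MR2: ATP + H2O -> ADP + Pi + H
MR3: 2 GAP + H2O -> G6P + Pi
MR4: G6P + ATP -> H + ADP + 2 GAP
MR5: GAP + ADP + Pi + NAD <-> PEP + ATP + NADH + H2O + H
MR6: G6P <-> CARB + Pi
MR7: GAP + 16.61 PEP + 2 ADP + 13.46 NAD + 29.3 NADPH + 34.48 H + 2.15 O2 <-> PA + 14.61 Pi + 2 ATP + 13.46 NADH + 29.3 NADP + 4.31 H2O + 16.61 CO2
MR8: 3.13 PEP + 7.37 O2 + 4.46 H + 1.31 NO3 + 1.14 G6P + 0.11 PA + 0.03 SO4 + 0.0025 Mg -> B + 11.67 CO2 + 4.23 Pi + 6 H2O
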