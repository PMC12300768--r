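# SWM4-NDP: rigid four-site Drude-polarizable water.
# The M site (OM) sits 0.24 A from O toward the hydrogen midpoint along the
# bisector and carries the negative charge; O itself is uncharged but hosts the
# (negative) Drude pair.  r_OH = 0.9572 A per the model definition.
name: swm4-ndp
geometry:
  kind: rigid
  r_oh: 0.9572
  hoh_angle: 104.52
charges:
  O: 0.0
  H1: 0.55733
  H2: 0.55733
  OM: -1.11466
virtual_sites:
  - label: OM
    rule: bisector
    displacement: 0.24
drude:
  host: O
  charge: -1.71636
  alpha: 0.97825
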