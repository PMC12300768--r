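# SPC/E: rigid, non-polarizable, three-site.
# Charges from the published model; r_OH = 1.0 A and the tetrahedral angle are
# part of the model definition (the charge table alone does not fix geometry).
name: spce
geometry:
  kind: rigid
  r_oh: 1.0
  hoh_angle: 109.47
charges:
  O: -0.848
  H1: 0.424
  H2: 0.424
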