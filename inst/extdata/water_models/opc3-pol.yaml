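# OPC3-pol: rigid three-site Drude-polarizable water, tetrahedral angle,
# r_OH = 0.97888 A (OPC3 geometry).  The printed site charges are treated as
# the permanent set; the Drude pair is regarded as purely induced.  Note that
# the permanent/induced partition of this model is ambiguous: the charges below
# give |mu_perm| = 1.66 D, not the 2.05 D sometimes quoted for a different
# partition.  Drude parameters are omitted (not needed for the permanent set).
name: opc3-pol
geometry:
  kind: rigid
  r_oh: 0.97888
  hoh_angle: 109.47
charges:
  O: -0.610
  H1: 0.305
  H2: 0.305
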