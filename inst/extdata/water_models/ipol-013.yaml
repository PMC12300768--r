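# IPOL-0.13: rigid three-site Drude-polarizable water with a tetrahedral angle.
# Only the partial charges and the angle are tabulated here; r_OH = 1.0 A is the
# cited model's bond length (consistent with the reported 1.86 D permanent
# dipole).  The Drude charge/polarizability pair is not carried because the
# permanent-dipole analysis does not need it.
name: ipol-013
geometry:
  kind: rigid
  r_oh: 1.0
  hoh_angle: 109.47
charges:
  O: -0.669
  H1: 0.3345
  H2: 0.3345
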