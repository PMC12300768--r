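# AMOEBA14: flexible multipole water, represented here at its equilibrium
# monomer geometry (r_OH = 0.9565 A, H-O-H = 107.91 deg).  Each atom carries a
# permanent charge, a permanent dipole (D) in its local frame, and a symmetric
# traceless quadrupole (D A) in the same frame.  Local frames: oxygen z along
# the H-O-H bisector, x in-plane; hydrogen z from H toward O, x in-plane
# pointing inward.  Quadrupoles are stored as printed; the one_third convention
# divides them by 3 when building lab-frame tensors (the value the simulation
# engine consumes).
name: amoeba14
geometry:
  kind: rigid
  r_oh: 0.9565
  hoh_angle: 107.91
charges:
  O: -0.42616
  H1: 0.21308
  H2: 0.21308
atomic_dipoles:
  O:  [0.0, 0.0, 0.159]
  H1: [-0.257, 0.0, -0.691]
  H2: [-0.257, 0.0, -0.691]
atomic_quadrupoles:
  O:
    xx: 0.236
    yy: -0.312
    zz: 0.075
  H1:
    xx: 0.165
    yy: 0.120
    zz: -0.286
    xz: -0.094
  H2:
    xx: 0.165
    yy: 0.120
    zz: -0.286
    xz: -0.094
quadrupole_scale_convention: one_third
polarizability:
  O: 1.47
thole: 0.39
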