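# CHELPG charge set of an optimized water dimer (two monomers, one hydrogen
# bond).  The monomers are individually non-neutral (+-0.043 e intermolecular
# charge transfer); only the six-site set is neutral.  No rigid geometry is
# attached: dimer geometries are built by build_dimer().
name: water-dimer
geometry:
  kind: flexible
charges:
  O1: -0.810
  H11: 0.384
  H12: 0.383
  O2: -0.752
  H21: 0.394
  H22: 0.401
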