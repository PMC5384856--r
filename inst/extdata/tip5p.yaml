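# TIP5P rigid 5-site water model (Mahoney & Jorgensen 2000).
# Body frame: oxygen at origin, H-O-H bisector along +z (hydrogens in the
# xz plane), lone pairs in the yz plane on the -z side.
# Units: Angstrom, elementary charge, kJ/mol.
name: tip5p
sites:
  - {site: O,  x: 0.0,       "y": 0.0,       z: 0.0,       charge: 0.0}
  - {site: H1, x: 0.756950,  "y": 0.0,       z: 0.585882,  charge: 0.241}
  - {site: H2, x: -0.756950, "y": 0.0,       z: 0.585882,  charge: 0.241}
  - {site: L1, x: 0.0,       "y": 0.571543,  z: -0.404151, charge: -0.241}
  - {site: L2, x: 0.0,       "y": -0.571543, z: -0.404151, charge: -0.241}
lennard_jones:
  sigma: 3.12
  epsilon: 0.66944
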