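# Rigid gauche-gauche dimethylphosphate (CH3O)2PO2^- with united-atom methyls.
# Coordinates built from standard internal coordinates (P-O 1.48 A free /
# 1.60 A ester, O-P-O 119.6 deg free / 102.6 deg ester, O-C 1.42 A,
# P-O-C 119 deg, both C-O-P-O dihedrals +70 deg).
# SYNTHETIC partial charges and LJ parameters: the published charge set this
# stands in for is not reproduced here; values are a plausible ESP-like set
# constrained to net charge -1 e. Units: Angstrom, e, kJ/mol.
name: dmp_gg_synthetic
probe_atoms: {P: P, O1: O1, O2: O2}
atoms:
  - {label: P,   x: 0.0,     "y": 0.0,     z: 0.0,     charge: 1.20,  sigma: 3.83, epsilon: 0.84}
  - {label: O1,  x: 0.7445,  "y": 1.2791,  z: 0.0,     charge: -0.80, sigma: 3.03, epsilon: 0.50}
  - {label: O2,  x: 0.7445,  "y": -1.2791, z: 0.0,     charge: -0.80, sigma: 3.03, epsilon: 0.50}
  - {label: OS1, x: -1.0004, "y": 0.0,     z: 1.2487,  charge: -0.50, sigma: 2.95, epsilon: 0.42}
  - {label: OS2, x: -1.0004, "y": 0.0,     z: -1.2487, charge: -0.50, sigma: 2.95, epsilon: 0.42}
  - {label: C1,  x: -1.7623, "y": -1.1671, z: 1.5204,  charge: 0.20,  sigma: 3.67, epsilon: 0.68}
  - {label: C2,  x: -1.7623, "y": 1.1671,  z: -1.5204, charge: 0.20,  sigma: 3.67, epsilon: 0.68}
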