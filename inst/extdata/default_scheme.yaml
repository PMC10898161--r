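# Default seven-probe restraint scheme.
# Residue codes match the packaged probe templates; override them to
# suit your force-field topology naming.
probes:
  - label: benzene
    resname: BENX
    anchor: {type: com}
  - label: propane
    resname: PRPN
    anchor: {type: central_atom, atom: C2}
  - label: methanol
    resname: MEOH
    anchor: {type: central_atom, atom: C}
  - label: formamide
    resname: FORM
    anchor: {type: central_atom, atom: C}
  - label: acetaldehyde
    resname: ACEH
    anchor: {type: central_atom, atom: C2}
  - label: acetate
    resname: ACET
    anchor: {type: central_atom, atom: C2}
  - label: methylammonium
    resname: MAMM
    # quoted: bare N is YAML-1.1 boolean false
    anchor: {type: central_atom, atom: "N"}
pair_rules:
  - [benzene, benzene]
  - [propane, benzene]
  - [propane, propane]
  - [acetate, methylammonium]
walls:
  production: {k: 20000, a: 0.8, s: 1.0, e: 4, energy: kJ/mol, length: nm}
  soft: {k: 10, a: 0.8, s: 1.0, e: 2, energy: kJ/mol, length: nm}
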