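{
  "comment": "RyR2 CaM-binding-domain peptide registry (human RyR2 numbering, UniProtKB Q92736). All assay peptides carry an N-terminal 5-TAMRA label (epsilon_556 = 103000 /M/cm). null_probe is the free-dye no-binding control.",
  "label": {"fluorophore": "5-TAMRA", "epsilon_556_per_M_cm": 103000},
  "peptides": [
    {"id": "CaMBD1a", "ryr2_start": 1942, "ryr2_end": 1966,
     "sequence": "RFRYNEVMQALNMSAALTARKTKEF", "modifications": []},
    {"id": "CaMBD1b", "ryr2_start": 2022, "ryr2_end": 2052,
     "sequence": "DLTIRGRLLSLVEKVTYLKKKQAEKPVESDS", "modifications": []},
    {"id": "CaMBD1b+P", "ryr2_start": 2022, "ryr2_end": 2052,
     "sequence": "DLTIRGRLLSLVEKVTYLKKKQAEKPVESDS",
     "modifications": [{"type": "phospho", "residue": "S", "position": 2031}]},
    {"id": "CaMBD2", "ryr2_start": 3581, "ryr2_end": 3607,
     "sequence": "RSKKAVWHKLLSKQRKRAVVACFRMAP", "modifications": []},
    {"id": "CaMBD2(+)", "ryr2_start": 3581, "ryr2_end": 3611,
     "sequence": "RSKKAVWHKLLSKQRKRAVVACFRMAPLYNL", "modifications": []},
    {"id": "CaMBD2(+)-W/A", "ryr2_start": 3581, "ryr2_end": 3611,
     "sequence": "RSKKAVAHKLLSKQRKRAVVACFRMAPLYNL",
     "modifications": [{"type": "substitution", "from": "W", "to": "A", "position": 3587}]},
    {"id": "CaMBD2(+)-F/A", "ryr2_start": 3581, "ryr2_end": 3611,
     "sequence": "RSKKAVWHKLLSKQRKRAVVACARMAPLYNL",
     "modifications": [{"type": "substitution", "from": "F", "to": "A", "position": 3603}]},
    {"id": "CaMBD3", "ryr2_start": 4246, "ryr2_end": 4276,
     "sequence": "FALRYNILTLMRMLSLKSLKKQMKKVKKMTV", "modifications": []},
    {"id": "null_probe", "ryr2_start": null, "ryr2_end": null,
     "sequence": "", "modifications": [],
     "note": "free 5-TAMRA dye; no CaM binding"}
  ]
}
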