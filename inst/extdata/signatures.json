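{
  "AV": ["Mfge8", "Trf", "Csn3", "Wfdc18", "Ltf"],
  "HS": ["Prlr", "Pgr", "Esr1", "Cited1", "Prom1"],
  "ME": ["Krt17", "Krt14", "Krt5"],
  "proliferation": ["Cenpe", "Ccna2", "Ccnb2", "Mcm6", "Ccnf", "Bud1"],
  "regulon": ["Bclaf1", "Cux1", "E2f1", "E2f4", "Esr1", "Foxm1", "Gtf2b", "Max", "Myc", "Nfya", "Nr4a1", "Nrf1", "Smarca4", "Taf1"]
}
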