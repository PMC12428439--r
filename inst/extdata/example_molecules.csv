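id,smiles,name
aspirin,CC(=O)Oc1ccccc1C(=O)O,acetylsalicylic acid
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,caffeine
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O,ibuprofen
glycine,NCC(=O)O,glycine
leu_enkephalin,NCC(=O)NCC(=O)N[C@@H](Cc1ccccc1)C(=O)N[C@@H](CC(C)C)C(=O)O,GGFL tetrapeptide
cyclosporin_fragment,CC[C@H](C)[C@@H](C(=O)N[C@@H](CC(C)C)C(=O)O)NC(=O)[C@@H](C)N,branched tripeptide
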