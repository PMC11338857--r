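[
 {
  "name": "Thalidomide",
  "file": "graphs/01-thalidomide.edges",
  "n_vertices": 19,
  "n_edges": 21,
  "smiles": "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1"
 },
 {
  "name": "Aspirin",
  "file": "graphs/02-aspirin.edges",
  "n_vertices": 13,
  "n_edges": 13,
  "smiles": "CC(=O)Oc1ccccc1C(=O)O"
 },
 {
  "name": "Valproic Acid",
  "file": "graphs/03-valproic-acid.edges",
  "n_vertices": 10,
  "n_edges": 9,
  "smiles": "CCCC(CCC)C(=O)O"
 },
 {
  "name": "Celecoxib",
  "file": "graphs/04-celecoxib.edges",
  "n_vertices": 26,
  "n_edges": 28,
  "smiles": "Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1"
 },
 {
  "name": "Leflunomide",
  "file": "graphs/05-leflunomide.edges",
  "n_vertices": 19,
  "n_edges": 20,
  "smiles": "Cc1oncc1C(=O)Nc1ccc(C(F)(F)F)cc1"
 },
 {
  "name": "Wortmannin",
  "file": "graphs/06-wortmannin.edges",
  "n_vertices": 31,
  "n_edges": 35,
  "depiction_note": "edge list reconstructed from the study's tabulated descriptors (all six values reproduce, partition uniquely determined); differs from the canonical natural-product skeleton in the arrangement of the two quaternary ring-fusion carbons",
  "as_depicted": true
 },
 {
  "name": "Zoledronic Acid",
  "file": "graphs/07-zoledronic-acid.edges",
  "n_vertices": 16,
  "n_edges": 16,
  "smiles": "OC(Cn1ccnc1)(P(=O)(O)O)P(=O)(O)O"
 },
 {
  "name": "Minocycline",
  "file": "graphs/08-minocycline.edges",
  "n_vertices": 35,
  "n_edges": 38,
  "smiles": "CN(C)C1C2CC3CC4=C(C(=C(C=C4)N(C)C)O)C(=O)C3=C(C2(O)C(=O)C(=C1O)C(=O)N)O",
  "depiction_note": "canonical structure plus hydroxyls on the C4a and C5a ring-fusion carbons, matching the study's drawing (reproduces ABC-R, SDD, GA and both exponential indices exactly)",
  "as_depicted": true
 },
 {
  "name": "Metformin",
  "file": "graphs/09-metformin.edges",
  "n_vertices": 9,
  "n_edges": 8,
  "smiles": "CN(C)C(=N)NC(=N)N"
 },
 {
  "name": "Thiocolchicoside",
  "file": "graphs/10-thiocolchicoside.edges",
  "n_vertices": 39,
  "n_edges": 42,
  "smiles": "CC(=O)NC1CCc2cc(OC3OC(CO)C(O)C(O)C3O)c(OC)c(OC)c2-c2ccc(SC)c(=O)cc21"
 },
 {
  "name": "Noscapine",
  "file": "graphs/11-noscapine.edges",
  "n_vertices": 30,
  "n_edges": 34,
  "smiles": "CN1CCc2cc3OCOc3c(OC)c2C1C1OC(=O)c2c1ccc(OC)c2OC",
  "depiction_note": "canonical structure; the study's printed index row is internally inconsistent and matches no graph"
 },
 {
  "name": "Nitroxoline",
  "file": "graphs/12-nitroxoline.edges",
  "n_vertices": 14,
  "n_edges": 15,
  "smiles": "Oc1ccc([N+](=O)[O-])c2cccnc12"
 },
 {
  "name": "Methotrexate",
  "file": "graphs/13-methotrexate.edges",
  "n_vertices": 33,
  "n_edges": 35,
  "smiles": "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc1"
 },
 {
  "name": "Vesnarinone",
  "file": "graphs/14-vesnarinone.edges",
  "n_vertices": 29,
  "n_edges": 32,
  "smiles": "COc1ccc(C(=O)N2CCN(c3ccc4c(c3)CCC(=O)N4)CC2)cc1OC"
 },
 {
  "name": "Simvastatin",
  "file": "graphs/15-simvastatin.edges",
  "n_vertices": 31,
  "n_edges": 33,
  "smiles": "CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C12",
  "depiction_note": "canonical structure plus a hydroxyl on the C8a ring-fusion carbon, matching the study's drawing (reproduces ABC-R, SDD, GA and both exponential indices exactly)",
  "as_depicted": true
 }
]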