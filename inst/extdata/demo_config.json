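{
  "seed": 101,
  "cla": "synthetic_scop_cla.tsv",
  "des": "synthetic_scop_des.tsv",
  "fasta": "synthetic_scop.fasta",
  "fe_seeds": "fe_seeds.txt",
  "cu_seeds": "cu_seeds.txt",
  "geochem_csv": "geochem_synthetic.csv",
  "tax_nodes": "taxonomy_nodes.dmp",
  "tax_names": "taxonomy_names.dmp",
  "exclusions": "c.83.1.1",
  "samples": ["s03", "s06", "s07", "s10", "s13"],
  "reads_per_sample": 100,
  "total_protein_coding": {
    "s03": 120000,
    "s06": 135000,
    "s07": 128000,
    "s10": 142000,
    "s13": 117000
  },
  "read_length": 120,
  "substitution_rate": 0.01,
  "bit_cutoff": 50,
  "evalue_cutoff": 0.1,
  "threshold_fraction": 0.04,
  "top_percent": 10
}
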