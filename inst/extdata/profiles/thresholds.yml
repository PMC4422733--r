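domains:
  GSTN:
    seed: GSTN_seed_synthetic.fasta
    threshold: 12.75
  GSTC:
    seed: GSTC_seed_synthetic.fasta
    threshold: 10.14
  THX:
    seed: THX_seed_synthetic.fasta
    threshold: 11.21
  MAPEG:
    seed: MAPEG_seed_synthetic.fasta
    threshold: 5.09
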