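.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "probability", "in_coding", "in_noncoding", "category",
  "mirna_id", "transcript_id", "gene_id", "start", "cds_start", "cds_end",
  "end", "length"
))
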