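# data.table / tidy-eval column references used non-standardly
utils::globalVariables(c("gene_id", "transcript_id", "dz", "chrom",
                         "strand", ".data"))
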