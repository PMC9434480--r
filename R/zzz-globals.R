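# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele", "freq",
  "info", "z", "n", "beta", "se", "a1", "a2", "p_ref", "badds_p", "badds_i",
  "badds_m", "badds_d", "psychosis", "mips", "badds_inconsistent", "V1",
  "V2", "V4", "V5", "V6", "ld_score", "model", ".y", "p"
))
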