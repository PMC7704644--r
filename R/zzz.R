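.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".SD", "hap_a", "hap_b", "start_site", "start_cM", "end_cM",
  "start_bp", "end_bp", "length_cM", "score", "age_est", "tmrca",
  "n_mismatch_windows", "ind_a", "ind_b", "gene", "individual",
  "window_index", "drc", "p_value", "mism"))
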