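## Default desk-scale scenario shared by the acceptance tests: 100
## haploids over 10 cM under the bundled two-epoch European-like
## demography (recent Ne 10000, ancestral 2500 from generation 300),
## ascertained to ~75 array SNPs per cM with a common-variant-weighted
## frequency spectrum. Built once per test run (about a minute).
fixture_default_scenario <- function() {
  if (is.null(.fixture_env$default_scenario)) {
    mm <- demographic_model(c(0, 300), c(10000, 2500))
    sim <- simulate_panel(100, 10, mm, seed = 101)
    sim <- suppressMessages(ascertain_sites(
      sim, target_density = 75,
      target_spectrum = list(breaks = c(0, 0.05, 0.1, 0.2, 0.35, 0.5, 1),
                             weights = c(0.1, 0.15, 0.2, 0.25, 0.2, 0.1)),
      seed = 102))
    cand <- find_candidates(sim$panel, word_size = 32, max_bin_size = 64,
                            max_gap_windows = 1, min_length_cM = 1,
                            depth_cap = 4)
    segs <- detect_ibd(sim$panel, mm, T_threshold = 50,
                       min_length_cM = 1, word_size = 32)
    .fixture_env$default_scenario <-
      list(model = mm, sim = sim, candidates = cand, segments = segs)
  }
  .fixture_env$default_scenario
}
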