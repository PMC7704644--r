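#' Trim a candidate segment by posterior-vs-prior comparison
#'
#' A site is called IBD when the posterior mass of coalescence before the
#' time threshold exceeds its prior, `P(t <= T | data) > P(t <= T)`.
#' Maximal runs of such sites inside the candidate become verified IBD
#' segments; each run's IBD quality score is the mean `mass_below_T` over
#' its sites and its age estimate the mean MAP representative TMRCA. Runs
#' shorter than `min_output_cM` are dropped.
#'
#' @param candidate one row of [find_candidates()] output (list or
#'   single-row data.frame with `hap_a`, `hap_b`, `start_site`, `end_site`,
#'   `n_mismatch_windows`).
#' @param post a [decode_posterior()] result covering the candidate's site
#'   range.
#' @param decoder the [pair_decoder()] used (provides the threshold, its
#'   prior mass and the panel coordinates).
#' @param min_output_cM minimum genetic length of an emitted segment.
#' @return `data.table` of verified segments (possibly empty) with columns
#'   `hap_a`, `hap_b`, `start_site`, `end_site`, `start_bp`, `end_bp`,
#'   `start_cM`, `end_cM`, `length_cM`, `score`, `age_est`,
#'   `n_mismatch_windows`.
#' @export
refine_segment <- function(candidate, post, decoder, min_output_cM = 0) {
  sites <- post$sites
  if (sites[1L] > candidate$start_site ||
      sites[length(sites)] < candidate$end_site - 1L)
    stop("posterior does not cover the candidate's site range")
  keep <- sites >= candidate$start_site & sites < candidate$end_site
  idx <- which(keep)
  ok <- post$mass_below_T[idx] > decoder$prior_below
  segs <- .logical_runs(ok)
  st <- decoder$panel$sites
  out <- list(); n <- 0L
  for (r in segs) {
    gsites <- sites[idx[r[1L]:r[2L]]]
    s0 <- gsites[1L]; s1 <- gsites[length(gsites)]
    len <- st$gen_pos[s1] - st$gen_pos[s0]
    if (len < min_output_cM) next
    n <- n + 1L
    out[[n]] <- data.table::data.table(
      hap_a = candidate$hap_a, hap_b = candidate$hap_b,
      start_site = s0, end_site = s1 + 1L,
      start_bp = st$phys_pos[s0], end_bp = st$phys_pos[s1],
      start_cM = st$gen_pos[s0], end_cM = st$gen_pos[s1],
      length_cM = len,
      score = mean(post$mass_below_T[idx[r[1L]:r[2L]]]),
      age_est = mean(post$map_time[idx[r[1L]:r[2L]]]),
      n_mismatch_windows = candidate$n_mismatch_windows)
  }
  if (n == 0L) .empty_ibd_sites() else data.table::rbindlist(out)
}

.logical_runs <- function(x) {
  if (!any(x)) return(list())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

.empty_ibd_sites <- function() {
  data.table::data.table(
    hap_a = integer(), hap_b = integer(), start_site = integer(),
    end_site = integer(), start_bp = numeric(), end_bp = numeric(),
    start_cM = numeric(), end_cM = numeric(), length_cM = numeric(),
    score = numeric(), age_est = numeric(), n_mismatch_windows = integer())
}

#' Detect verified IBD segments in a phased panel
#'
#' Runs the full two-stage pipeline: hash-based identification of
#' candidate segments ([find_candidates()]), then coalescent-HMM
#' verification of each candidate (posterior decoding, posterior-vs-prior
#' trimming, IBD quality score and MAP age). Output is deterministic for a
#' fixed panel and parameter set. Candidates stream through the decoder in
#' buffers; the buffer size affects throughput only, never results.
#'
#' @param panel a [haplotype_panel()].
#' @param model a [demographic_model()].
#' @param T_threshold IBD time threshold in generations (default 50).
#' @param disc optional `time_discretization`; by default `K` quantile
#'   intervals with `T_threshold` pinned as a boundary plus a refinement
#'   at `T * c(1.5, 2, 3, 4, 6)`. Quantile boundaries alone put the first
#'   interior boundary at the prior's 1/K quantile (hundreds of
#'   generations under growth models), leaving MAP ages with no
#'   resolution on the recent time scales IBD detection cares about;
#'   refining just above `T` is standard practice for coalescent HMMs
#'   aimed at recent-time questions. Boundaries below `T` are not added:
#'   inside called runs the discordance signal cannot separate very
#'   recent intervals, and a finer recent grid only drags the MAP toward
#'   its lowest representative.
#' @param K intervals for the default discretization (default 30).
#' @param word_size,max_bin_size,max_gap_windows,min_length_cM,depth_cap
#'   identification parameters, see [find_candidates()].
#' @param min_output_cM minimum emitted segment length; defaults to
#'   `min_length_cM / 2` so trimming can shorten but not silently delete
#'   long candidates.
#' @param freq_bins,max_calib_pairs emission calibration parameters.
#' @param pairs optional restriction to given haplotype pairs (2-column
#'   matrix), e.g. from [partition_jobs()].
#' @param buffer_size candidates decoded per batch (throughput only).
#' @return `data.table` of verified IBD segments with individual/haplotype
#'   labels (`ind_a`, `hap_a`, `ind_b`, `hap_b`), coordinates, `length_cM`,
#'   `score`, `age_est`, `n_mismatch_windows`, plus site indices.
#' @export
detect_ibd <- function(panel, model, T_threshold = 50, disc = NULL,
                       K = 30L, word_size = 32L, max_bin_size = 64L,
                       max_gap_windows = 1L, min_length_cM = 1.0,
                       depth_cap = 4L, min_output_cM = min_length_cM / 2,
                       freq_bins = 5L, max_calib_pairs = 200L,
                       pairs = NULL, buffer_size = 1000L) {
  if (is.null(disc))
    disc <- make_quantile_discretization(
      model, K, pinned = T_threshold * c(1, 1.5, 2, 3, 4, 6))
  hmm <- coal_hmm(disc, model)
  emission <- calibrate_emission(panel, disc, freq_bins = freq_bins,
                                 max_pairs = max_calib_pairs)
  decoder <- pair_decoder(panel, hmm, emission, T_threshold)
  cand <- find_candidates(panel, word_size = word_size,
                          max_bin_size = max_bin_size,
                          max_gap_windows = max_gap_windows,
                          min_length_cM = min_length_cM,
                          depth_cap = depth_cap, pairs = pairs)
  segs <- verify_candidates(cand, decoder, min_output_cM = min_output_cM)
  .label_segments(segs, panel)
}

#' Verify a table of candidate segments
#'
#' @param candidates output of [find_candidates()].
#' @param decoder a [pair_decoder()].
#' @param min_output_cM minimum emitted segment length.
#' @return `data.table` of verified segments (haplotype indices, no
#'   individual labels).
#' @export
verify_candidates <- function(candidates, decoder, min_output_cM = 0) {
  if (nrow(candidates) == 0L) return(.empty_ibd_sites())
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cnd <- candidates[i]
    obs <- pair_observation(decoder$panel, cnd$hap_a, cnd$hap_b,
                            cnd$start_site, cnd$end_site)
    post <- decode_posterior(obs, decoder)
    out[[i]] <- refine_segment(cnd, post, decoder, min_output_cM)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res)) data.table::setorder(res, hap_a, hap_b, start_site)
  res
}

.label_segments <- function(segs, panel) {
  if (nrow(segs) == 0L) {
    return(data.table::data.table(
      ind_a = character(), hap_a = integer(), ind_b = character(),
      hap_b = integer(), chrom = character(), start_bp = numeric(),
      end_bp = numeric(), length_cM = numeric(), score = numeric(),
      age_est = numeric(), n_mismatch_windows = integer(),
      start_cM = numeric(), end_cM = numeric(), start_site = integer(),
      end_site = integer(), hap_a_idx = integer(), hap_b_idx = integer()))
  }
  data.table::data.table(
    ind_a = panel$individual_ids[segs$hap_a],
    hap_a = panel$hap_index[segs$hap_a],
    ind_b = panel$individual_ids[segs$hap_b],
    hap_b = panel$hap_index[segs$hap_b],
    chrom = panel$sites$chrom[segs$start_site],
    start_bp = segs$start_bp, end_bp = segs$end_bp,
    length_cM = segs$length_cM, score = segs$score,
    age_est = segs$age_est,
    n_mismatch_windows = segs$n_mismatch_windows,
    start_cM = segs$start_cM, end_cM = segs$end_cM,
    start_site = segs$start_site, end_site = segs$end_site,
    hap_a_idx = segs$hap_a, hap_b_idx = segs$hap_b)
}
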