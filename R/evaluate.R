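#' Site-level confusion counts under the TMRCA-threshold IBD definition
#'
#' A `(pair, site)` unit is predicted IBD iff at least one reported
#' segment for that pair covers the site; its truth label is
#' `true TMRCA < T`. Counts are accumulated over all pairs present in the
#' truth table and all panel sites.
#'
#' @param truth truth table (`hap_a`, `hap_b`, `start_cM`, `end_cM`,
#'   `tmrca`) covering every evaluated pair.
#' @param calls segment table with `hap_a`, `hap_b` haplotype indices
#'   (columns `hap_a_idx`/`hap_b_idx` are used when present, as in
#'   [detect_ibd()] output) and `start_cM`, `end_cM`.
#' @param T_threshold IBD time threshold (generations).
#' @param site_cM genetic positions of the evaluated sites.
#' @param pairs optional 2-column matrix of evaluated pairs; defaults to
#'   all pairs in `truth`.
#' @return list with `TP`, `FP`, `TN`, `FN`, `precision`, `recall`,
#'   `threshold`; precision is `NaN` (with a warning) when nothing is
#'   called.
#' @export
site_confusion <- function(truth, calls, T_threshold, site_cM,
                           pairs = NULL) {
  calls <- .calls_hap_idx(calls)
  if (is.null(pairs)) {
    pairs <- unique(data.table::as.data.table(truth)[, list(hap_a, hap_b)])
    pairs <- as.matrix(pairs)
  }
  TP <- FP <- TN <- FN <- 0L
  truth <- data.table::as.data.table(truth)
  tsplit <- split(truth, paste(truth$hap_a, truth$hap_b))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    sub <- tsplit[[paste(a, b)]]
    if (is.null(sub)) stop("pair (", a, ",", b, ") not in truth")
    tt <- .tmrca_lookup(sub, site_cM)
    if (anyNA(tt)) stop("truth does not cover pair (", a, ",", b, ")")
    lab <- tt < T_threshold
    pred <- .covered_sites(calls, a, b, site_cM)
    TP <- TP + sum(pred & lab); FP <- FP + sum(pred & !lab)
    FN <- FN + sum(!pred & lab); TN <- TN + sum(!pred & !lab)
  }
  prec <- if (TP + FP == 0L) {
    warning("no called sites; precision undefined (NaN)")
    NaN
  } else TP / (TP + FP)
  rec <- if (TP + FN == 0L) NaN else TP / (TP + FN)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       precision = prec, recall = rec, threshold = T_threshold)
}

.calls_hap_idx <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if ("hap_a_idx" %in% names(calls)) {
    calls$hap_a <- calls$hap_a_idx
    calls$hap_b <- calls$hap_b_idx
  }
  calls
}

.covered_sites <- function(calls, a, b, site_cM) {
  sub <- calls[calls$hap_a == a & calls$hap_b == b]
  pred <- rep(FALSE, length(site_cM))
  for (s in seq_len(nrow(sub)))
    pred <- pred | (site_cM >= sub$start_cM[s] & site_cM <= sub$end_cM[s])
  pred
}

#' Precision-recall curve and auPRC for scored segment calls
#'
#' Sweeps thresholds over the unique call scores in descending order; at
#' each threshold, calls at or above it are kept and site-level precision
#' and recall are computed. The area under the curve is the trapezoid over
#' the achieved recall range (reported alongside).
#'
#' @param calls scored segment table (column `score`; for raw candidates
#'   use `length_cM` as the score, the field's standard proxy).
#' @param truth truth table as in [site_confusion()].
#' @param T_threshold IBD time threshold.
#' @param site_cM genetic positions of evaluated sites.
#' @param score_col column to rank by (default `"score"`).
#' @param pairs optional evaluated pair matrix (defaults: all truth pairs).
#' @param max_thresholds cap on swept thresholds (quantile-thinned).
#' @return list with `curve` (`data.table`: threshold, precision, recall),
#'   `auprc`, `recall_range`, `prevalence`.
#' @export
precision_recall_curve <- function(calls, truth, T_threshold, site_cM,
                                   score_col = "score", pairs = NULL,
                                   max_thresholds = 50L) {
  calls <- .calls_hap_idx(calls)
  if (nrow(calls) == 0L) stop("no calls to evaluate")
  truth <- data.table::as.data.table(truth)
  if (is.null(pairs)) {
    pairs <- as.matrix(unique(truth[, list(hap_a, hap_b)]))
  }
  ## truth labels once (truth pre-split by pair: avoids rescanning the
  ## full table for every pair)
  tsplit <- split(truth, paste(truth$hap_a, truth$hap_b))
  labs <- list(); n_pos <- 0L
  for (k in seq_len(nrow(pairs))) {
    sub <- tsplit[[paste(pairs[k, 1L], pairs[k, 2L])]]
    if (is.null(sub)) stop("truth does not cover pair (", pairs[k, 1L],
                           ",", pairs[k, 2L], ")")
    tt <- .tmrca_lookup(sub, site_cM)
    labs[[k]] <- tt < T_threshold
    n_pos <- n_pos + sum(labs[[k]])
  }
  if (n_pos == 0L) stop("no positive truth sites at T = ", T_threshold)
  sc <- calls[[score_col]]
  thr <- sort(unique(sc), decreasing = TRUE)
  if (length(thr) > max_thresholds)
    thr <- unique(stats::quantile(thr, probs = seq(0, 1,
                                                   length.out = max_thresholds),
                                  names = FALSE, type = 1))
  thr <- sort(thr, decreasing = TRUE)
  ## per (pair, site): the best score among covering segments, computed
  ## once; the threshold sweep is then cumulative counting
  pair_key <- paste(calls$hap_a, calls$hap_b)
  call_groups <- split(seq_len(nrow(calls)), pair_key)
  best_pos <- numeric(0); best_neg <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    key <- paste(pairs[k, 1L], pairs[k, 2L])
    idx <- call_groups[[key]]
    if (is.null(idx)) next
    best <- rep(-Inf, length(site_cM))
    for (i in idx) {
      hit <- site_cM >= calls$start_cM[i] & site_cM <= calls$end_cM[i]
      best[hit] <- pmax(best[hit], sc[i])
    }
    cov <- is.finite(best)
    best_pos <- c(best_pos, best[cov & labs[[k]]])
    best_neg <- c(best_neg, best[cov & !labs[[k]]])
  }
  res <- data.table::data.table(threshold = thr, precision = NA_real_,
                                recall = NA_real_)
  for (i in seq_along(thr)) {
    TP <- sum(best_pos >= thr[i]); FP <- sum(best_neg >= thr[i])
    res$precision[i] <- if (TP + FP == 0L) NaN else TP / (TP + FP)
    res$recall[i] <- TP / n_pos
  }
  res <- res[!is.nan(res$precision)]
  data.table::setorder(res, recall)
  auprc <- if (nrow(res) < 2L) 0 else
    sum(diff(res$recall) * (utils::head(res$precision, -1) +
                              utils::tail(res$precision, -1)) / 2)
  n_units <- nrow(pairs) * length(site_cM)
  list(curve = res, auprc = auprc,
       recall_range = range(res$recall), prevalence = n_pos / n_units)
}

#' Length-based maximum-likelihood age of an IBD segment
#'
#' Given TMRCA `g`, a shared segment's length is exponential with rate
#' `2g` per Morgan, so the likelihood of `g` for an observed length `l`
#' (Morgans) is `(2g) exp(-2lg)` and the MLE is `1/(2l)`.
#'
#' @param length_morgans segment length in Morgans (> 0).
#' @return age estimate in generations.
#' @examples
#' mle_age(0.01)  # 1 cM -> 50 generations
#' @export
mle_age <- function(length_morgans) {
  if (any(length_morgans <= 0)) stop("segment length must be > 0 Morgans")
  1 / (2 * length_morgans)
}

#' Median absolute age-estimation error by minimum-length cutoff
#'
#' For each minimum-length cutoff, computes the median absolute error of
#' the MAP age estimate (`age_est`) and of the length-based MLE over all
#' segments at least that long. The true age of a detected segment is the
#' length-weighted mean truth TMRCA over its span.
#'
#' @param calls segment table with `start_cM`, `end_cM`, `length_cM`,
#'   `age_est` and haplotype indices.
#' @param truth truth table.
#' @param min_length_grid cutoffs in cM (default `c(0.5, 1, 2, 3)`).
#' @return `data.table`: `min_length_cM`, `n_segments`, `mae_map`,
#'   `mae_mle` (NaN with a warning for empty bins).
#' @export
age_error_summary <- function(calls, truth,
                              min_length_grid = c(0.5, 1, 2, 3)) {
  calls <- .calls_hap_idx(calls)
  truth <- data.table::as.data.table(truth)
  true_age <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    true_age[i] <- .segment_true_age(truth, calls$hap_a[i], calls$hap_b[i],
                                     calls$start_cM[i], calls$end_cM[i])
  }
  mle <- mle_age(pmax(calls$length_cM, 1e-9) / 100)
  out <- data.table::data.table(min_length_cM = min_length_grid,
                                n_segments = NA_integer_,
                                mae_map = NA_real_, mae_mle = NA_real_)
  for (i in seq_along(min_length_grid)) {
    keep <- calls$length_cM >= min_length_grid[i]
    out$n_segments[i] <- sum(keep)
    if (!any(keep)) {
      warning("no segments >= ", min_length_grid[i], " cM")
      out$mae_map[i] <- NaN; out$mae_mle[i] <- NaN
    } else {
      out$mae_map[i] <- stats::median(abs(calls$age_est[keep] -
                                            true_age[keep]))
      out$mae_mle[i] <- stats::median(abs(mle[keep] - true_age[keep]))
    }
  }
  out
}

## length-weighted mean truth TMRCA over [l, r] for a pair
.segment_true_age <- function(truth, a, b, l, r) {
  sub <- truth[truth$hap_a == a & truth$hap_b == b]
  if (nrow(sub) == 0L) stop("pair (", a, ",", b, ") not in truth")
  ol <- pmax(sub$start_cM, l); or <- pmin(sub$end_cM, r)
  w <- pmax(or - ol, 0)
  if (sum(w) <= 0) {  # zero-width segment: take TMRCA at the point
    return(truth_tmrca_at(truth, a, b, (l + r) / 2))
  }
  sum(w * sub$tmrca) / sum(w)
}
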