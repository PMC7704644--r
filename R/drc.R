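#' Density-of-recent-coalescence (DRC) statistic in genetic windows
#'
#' At each site, the DRC is the mean over all analyzed pairs of the pair's
#' IBD quality score at that site (0 where no segment covers the site for
#' a pair); it estimates the probability that a random pair coalesced
#' within the time threshold at that position. Sites are averaged within
#' half-open windows of `window_cM` tiling the genetic map from
#' `anchor_cM`.
#'
#' @param calls scored segment table (`hap_a`/`hap_b` or `*_idx` columns,
#'   `start_cM`, `end_cM`, `score`).
#' @param n_pairs_analyzed number of pairs the scan is averaged over
#'   (> 0); pairs without segments contribute zeros.
#' @param site_cM genetic positions of the analyzed sites.
#' @param site_bp physical positions (for window bp bounds; optional).
#' @param window_cM window width (default 0.05 cM).
#' @param anchor_cM genetic position where the window tiling starts
#'   (default 0).
#' @param chrom chromosome label for the output.
#' @return `data.table`: `chrom`, `start_cM`, `end_cM`, `start_bp`,
#'   `end_bp`, `n_sites`, `drc`; windows with no sites are flagged by
#'   `n_sites == 0` and excluded from testing downstream.
#' @export
drc_statistic <- function(calls, n_pairs_analyzed, site_cM, site_bp = NULL,
                          window_cM = 0.05, anchor_cM = 0, chrom = "1") {
  if (n_pairs_analyzed <= 0) stop("n_pairs_analyzed must be > 0")
  calls <- .calls_hap_idx(calls)
  bad <- nrow(calls) > 0 &
    (calls$start_cM < min(site_cM) - window_cM |
       calls$end_cM > max(site_cM) + window_cM)
  if (any(bad))
    stop("segment outside the analyzed site range (first at row ",
         which(bad)[1L], ")")
  site_score <- numeric(length(site_cM))
  for (i in seq_len(nrow(calls))) {
    hit <- site_cM >= calls$start_cM[i] & site_cM <= calls$end_cM[i]
    site_score[hit] <- site_score[hit] + calls$score[i]
  }
  site_drc <- site_score / n_pairs_analyzed
  win <- floor((site_cM - anchor_cM) / window_cM)
  all_win <- seq(min(win), max(win))
  agg <- data.table::data.table(win = win, drc = site_drc)
  agg <- agg[, list(n_sites = .N, drc = mean(drc)), by = "win"]
  out <- data.table::data.table(win = all_win)
  out <- agg[out, on = "win"]
  out$n_sites[is.na(out$n_sites)] <- 0L
  out$start_cM <- anchor_cM + out$win * window_cM
  out$end_cM <- out$start_cM + window_cM
  if (!is.null(site_bp)) {
    out$start_bp <- stats::approx(site_cM, site_bp, out$start_cM,
                                  rule = 2, ties = "ordered")$y
    out$end_bp <- stats::approx(site_cM, site_bp, out$end_cM,
                                rule = 2, ties = "ordered")$y
  } else {
    out$start_bp <- NA_real_; out$end_bp <- NA_real_
  }
  out$chrom <- chrom
  out$win <- NULL
  data.table::setcolorder(out, c("chrom", "start_cM", "end_cM",
                                 "start_bp", "end_bp", "n_sites", "drc"))
  out[]
}

#' Fit the Gamma null model on putative-neutral windows
#'
#' Maximum-likelihood Gamma fit (location fixed at 0) to the DRC values of
#' windows not overlapping any excluded region (padded by `pad_bp`).
#' Exact zeros are excluded from the fit (their count is reported); the
#' one-sided p-value of a window is the fitted upper-tail probability at
#' its DRC.
#'
#' @param windows output of [drc_statistic()].
#' @param exclude optional `data.frame` of regions (`start_bp`, `end_bp`,
#'   optionally `chrom`) treated as non-neutral.
#' @param pad_bp padding around excluded regions (default 500,000 bp).
#' @return list with `shape`, `scale`, `n_neutral`, `n_zero_dropped` and
#'   a function `p_value(drc)`.
#' @export
fit_gamma_null <- function(windows, exclude = NULL, pad_bp = 5e5) {
  neutral <- windows[windows$n_sites > 0L]
  if (!is.null(exclude) && nrow(exclude) > 0L && nrow(neutral) > 0L) {
    drop <- rep(FALSE, nrow(neutral))
    for (i in seq_len(nrow(exclude))) {
      if ("chrom" %in% names(exclude) &&
          !is.na(exclude$chrom[i])) {
        same <- neutral$chrom == as.character(exclude$chrom[i])
      } else same <- TRUE
      drop <- drop | (same &
                        neutral$end_bp >= exclude$start_bp[i] - pad_bp &
                        neutral$start_bp <= exclude$end_bp[i] + pad_bp)
    }
    neutral <- neutral[!drop]
  }
  if (nrow(neutral) == 0L) stop("all windows excluded; cannot fit null")
  x <- neutral$drc
  n_zero <- sum(x <= 0)
  x <- x[x > 0]
  if (length(x) < 30L)
    stop("need >= 30 positive neutral windows to fit the Gamma null (have ",
         length(x), ")")
  fit <- .gamma_mle(x)
  p_value <- function(drc) {
    stats::pgamma(drc, shape = fit$shape, scale = fit$scale,
                  lower.tail = FALSE)
  }
  list(shape = fit$shape, scale = fit$scale, n_neutral = length(x),
       n_zero_dropped = n_zero, p_value = p_value)
}

## Gamma MLE via the digamma equation for the shape, scale = mean/shape.
.gamma_mle <- function(x) {
  mlog <- mean(log(x)); m <- mean(x)
  s <- log(m) - mlog
  if (s <= 0) return(list(shape = 1e6, scale = m / 1e6))
  f <- function(k) log(k) - digamma(k) - s
  k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  lo <- k0 / 10; hi <- k0 * 10
  while (f(lo) < 0) lo <- lo / 10
  while (f(hi) > 0) hi <- hi * 10
  k <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(shape = k, scale = m / k)
}

#' Selection scan with iteratively refined Gamma null
#'
#' Fits the Gamma null on the current putative-neutral window set,
#' computes one-sided p-values, flags windows below the Bonferroni
#' threshold `alpha / n_tested`, removes newly significant windows from
#' the neutral set, and repeats until the significant set is stable.
#'
#' @param windows output of [drc_statistic()].
#' @param exclude optional known-selection regions (BED-like, bp).
#' @param alpha family-wise error target (default 0.05).
#' @param pad_bp exclusion padding (bp).
#' @param max_iter iteration cap (default 20; non-convergence errors).
#' @return list with `windows` (input plus `p_value` and `significant`),
#'   `fit` (final Gamma fit), `threshold` (per-test), `n_tested`,
#'   `iterations`, `iteration_log`.
#' @export
selection_scan <- function(windows, exclude = NULL, alpha = 0.05,
                           pad_bp = 5e5, max_iter = 20L) {
  windows <- data.table::as.data.table(windows)
  tested <- windows$n_sites > 0L
  n_tested <- sum(tested)
  if (n_tested == 0L) stop("no testable windows")
  threshold <- alpha / n_tested
  sig_regions <- NULL
  prev_sig <- NULL
  log_lines <- character()
  for (it in seq_len(max_iter)) {
    excl <- exclude
    if (!is.null(sig_regions) && nrow(sig_regions) > 0L)
      excl <- if (is.null(excl)) sig_regions else
        rbind(excl[, c("start_bp", "end_bp")],
              sig_regions[, c("start_bp", "end_bp")])
    fit <- fit_gamma_null(windows[tested], exclude = excl, pad_bp = pad_bp)
    pv <- rep(NA_real_, nrow(windows))
    pv[tested] <- fit$p_value(windows$drc[tested])
    sig <- which(!is.na(pv) & pv < threshold)
    log_lines <- c(log_lines,
                   sprintf("iteration %d: shape=%.4g scale=%.4g significant=%d",
                           it, fit$shape, fit$scale, length(sig)))
    if (identical(sig, prev_sig)) {
      windows$p_value <- pv
      windows$significant <- seq_len(nrow(windows)) %in% sig
      return(list(windows = windows[], fit = fit, threshold = threshold,
                  n_tested = n_tested, iterations = it,
                  iteration_log = log_lines))
    }
    prev_sig <- sig
    sig_regions <- data.frame(start_bp = windows$start_bp[sig],
                              end_bp = windows$end_bp[sig])
  }
  stop("selection scan did not converge after ", max_iter,
       " iterations; log:\n", paste(log_lines, collapse = "\n"))
}

#' Read a BED-like exclusion region file
#' @param path 3-column tab/space separated file: chrom, start, end (bp).
#' @return `data.frame` with `chrom`, `start_bp`, `end_bp`.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  dt <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(dt[[1L]]), start_bp = dt[[2L]],
             end_bp = dt[[3L]], stringsAsFactors = FALSE)
}
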