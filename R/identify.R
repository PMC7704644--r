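#' Window layout for hashing
#'
#' Sites are partitioned into consecutive windows of `word_size` SNPs; the
#' final window keeps its true (possibly smaller) width.
#'
#' @param n_sites number of sites in the panel.
#' @param word_size SNPs per window (8-64).
#' @return 2-column matrix of half-open site ranges `[start, end)`
#'   (1-based start, exclusive end), one row per window.
#' @export
window_ranges <- function(n_sites, word_size) {
  if (word_size < 2L) stop("word_size must be >= 2")
  starts <- seq(1L, n_sites, by = as.integer(word_size))
  cbind(start = starts,
        end = pmin(starts + as.integer(word_size), n_sites + 1L))
}

## Allele words (binary strings) for one site range, one per haplotype.
.window_words <- function(panel, start, end) {
  sub <- panel$alleles[, start:(end - 1L), drop = FALSE]
  do.call(paste0, as.data.frame(sub))
}

#' Hash one window of a haplotype panel
#'
#' Converts each haplotype's alleles inside the window to a binary word and
#' bins haplotypes by exact word identity: two haplotypes share a bin iff
#' they are identical across the window.
#'
#' @param panel a [haplotype_panel()].
#' @param window_index window ordinal (1-based).
#' @param word_size SNPs per window.
#' @return object of class `window_hash`: list with `window_index`,
#'   `bins` (named list: word -> integer haplotype indices), `depth` (0),
#'   `at_cap` (logical per bin) and the window's site range.
#' @export
hash_window <- function(panel, window_index, word_size = 32L) {
  wr <- window_ranges(n_sites(panel), word_size)
  if (window_index < 1L || window_index > nrow(wr))
    stop("window_index out of range")
  words <- .window_words(panel, wr[window_index, 1L], wr[window_index, 2L])
  bins <- split(seq_len(n_haplotypes(panel)), words)
  structure(list(window_index = as.integer(window_index),
                 word_size = as.integer(word_size),
                 bins = bins, depth = rep(0L, length(bins)),
                 at_cap = rep(FALSE, length(bins)),
                 site_start = wr[window_index, 1L],
                 site_end = wr[window_index, 2L]),
            class = "window_hash")
}

#' Recursively diversify low-complexity bins
#'
#' Bins holding more than `max_bin_size` haplotypes (low-complexity bins,
#' typical of recombination cold spots) are re-hashed by extending the word
#' into the following window, recursively, until every bin is small enough,
#' no further windows exist, or `depth_cap` recursions have been spent.
#' Bins emitted because the cap or the panel end was hit are flagged
#' `at_cap`.
#'
#' @param hash a [hash_window()] result.
#' @param panel the panel the hash was built from.
#' @param max_bin_size largest bin emitted without recursion.
#' @param depth_cap maximum number of recursive extensions.
#' @return a `window_hash` whose bins are all `<= max_bin_size` or flagged
#'   `at_cap`; haplotypes in one bin of depth `d` are identical over
#'   windows `w .. w + d`.
#' @export
diversify_bins <- function(hash, panel, max_bin_size = 64L, depth_cap = 4L) {
  stopifnot(inherits(hash, "window_hash"))
  wr <- window_ranges(n_sites(panel), hash$word_size)
  n_win <- nrow(wr)
  out_bins <- list(); out_depth <- integer(); out_cap <- logical()
  recurse <- function(idx, word, depth) {
    if (length(idx) <= max_bin_size || depth >= depth_cap ||
        hash$window_index + depth >= n_win) {
      out_bins[[length(out_bins) + 1L]] <<- idx
      names(out_bins)[length(out_bins)] <<- word
      out_depth[length(out_bins)] <<- depth
      out_cap[length(out_bins)] <<- length(idx) > max_bin_size
      return(invisible())
    }
    nxt <- hash$window_index + depth + 1L
    ext <- .window_words(panel, wr[nxt, 1L], wr[nxt, 2L])[idx]
    for (grp in split(idx, ext)) {
      recurse(grp, paste0(word, .window_words(panel, wr[nxt, 1L],
                                              wr[nxt, 2L])[grp[1L]]),
              depth + 1L)
    }
  }
  for (b in seq_along(hash$bins))
    recurse(hash$bins[[b]], names(hash$bins)[b], 0L)
  hash$bins <- out_bins
  hash$depth <- out_depth
  hash$at_cap <- out_cap
  hash
}

#' Identify candidate IBD segments by windowed hashing
#'
#' Hash-based identification: the panel is scanned one window at a
#' time; haplotypes are hashed into bins of identical words (recursively
#' diversified in low-complexity regions), all haplotype pairs co-occurring
#' in a bin are recorded as matching at that window, and maximal runs of
#' matching windows -- tolerating up to `max_gap_windows` consecutive
#' non-matching windows, which absorbs typical phasing switch errors -- are
#' emitted as candidates once their genetic length reaches
#' `min_length_cM`. Candidate boundaries snap to window edges; fine
#' trimming is the verification step's job.
#'
#' @param panel a [haplotype_panel()], sites sorted by position.
#' @param word_size SNPs per window (default 32).
#' @param max_bin_size low-complexity threshold for bin diversification.
#' @param max_gap_windows tolerated consecutive non-matching windows inside
#'   a run.
#' @param min_length_cM minimum candidate genetic length (> 0).
#' @param depth_cap recursion cap for [diversify_bins()].
#' @param pairs optional 2-column matrix restricting the scan to given
#'   haplotype pairs (used by job partitioning).
#' @return `data.table` of candidates sorted by `(hap_a, hap_b,
#'   start_site)` with columns `hap_a`, `hap_b` (1-based haplotype indices,
#'   a < b), `start_window`, `end_window` (inclusive ordinals),
#'   `start_site`, `end_site` (half-open site range), `start_bp`, `end_bp`,
#'   `start_cM`, `end_cM`, `length_cM`, `n_mismatch_windows`.
#' @export
find_candidates <- function(panel, word_size = 32L, max_bin_size = 64L,
                            max_gap_windows = 1L, min_length_cM = 1.0,
                            depth_cap = 4L, pairs = NULL) {
  if (min_length_cM <= 0) stop("min_length_cM must be > 0")
  wr <- window_ranges(n_sites(panel), word_size)
  n_win <- nrow(wr)
  allowed <- NULL
  if (!is.null(pairs)) {
    a <- pmin(pairs[, 1L], pairs[, 2L]); b <- pmax(pairs[, 1L], pairs[, 2L])
    allowed <- new.env(hash = TRUE, parent = emptyenv())
    for (k in seq_along(a)) assign(paste0(a[k], ":", b[k]), TRUE, allowed)
  }
  state <- new.env(hash = TRUE, parent = emptyenv())
  done <- list(); n_done <- 0L
  close_run <- function(st, key) {
    gen <- panel$sites$gen_pos
    s0 <- wr[st$start_w, 1L]; s1 <- wr[st$last_w, 2L]
    len <- gen[s1 - 1L] - gen[s0]
    if (len >= min_length_cM) {
      n_done <<- n_done + 1L
      done[[n_done]] <<- list(key = key, start_w = st$start_w,
                              end_w = st$last_w, start_site = s0,
                              end_site = s1, mism = st$mism)
    }
  }
  for (w in seq_len(n_win)) {
    h <- hash_window(panel, w, word_size)
    h <- diversify_bins(h, panel, max_bin_size, depth_cap)
    for (bin in h$bins) {
      if (length(bin) < 2L) next
      pr <- utils::combn(sort(bin), 2L)
      for (k in seq_len(ncol(pr))) {
        key <- paste0(pr[1L, k], ":", pr[2L, k])
        if (!is.null(allowed) && !exists(key, allowed, inherits = FALSE))
          next
        st <- state[[key]]
        if (is.null(st)) {
          state[[key]] <- list(start_w = w, last_w = w, mism = 0L)
        } else if (w - st$last_w - 1L <= max_gap_windows) {
          st$mism <- st$mism + (w - st$last_w - 1L)
          st$last_w <- w
          state[[key]] <- st
        } else {
          close_run(st, key)
          state[[key]] <- list(start_w = w, last_w = w, mism = 0L)
        }
      }
    }
  }
  for (key in ls(state)) close_run(state[[key]], key)
  if (n_done == 0L) {
    return(data.table::data.table(
      hap_a = integer(), hap_b = integer(), start_window = integer(),
      end_window = integer(), start_site = integer(), end_site = integer(),
      start_bp = numeric(), end_bp = numeric(), start_cM = numeric(),
      end_cM = numeric(), length_cM = numeric(),
      n_mismatch_windows = integer()))
  }
  ab <- do.call(rbind, strsplit(vapply(done, `[[`, "", "key"), ":",
                                fixed = TRUE))
  st <- panel$sites
  out <- data.table::data.table(
    hap_a = as.integer(ab[, 1L]), hap_b = as.integer(ab[, 2L]),
    start_window = vapply(done, `[[`, 0L, "start_w"),
    end_window = vapply(done, `[[`, 0L, "end_w"),
    start_site = vapply(done, `[[`, 0L, "start_site"),
    end_site = vapply(done, `[[`, 0L, "end_site"),
    mism = vapply(done, `[[`, 0L, "mism"))
  out[, `:=`(start_bp = st$phys_pos[out$start_site],
             end_bp = st$phys_pos[out$end_site - 1L],
             start_cM = st$gen_pos[out$start_site],
             end_cM = st$gen_pos[out$end_site - 1L])]
  out[, length_cM := end_cM - start_cM]
  data.table::setnames(out, "mism", "n_mismatch_windows")
  data.table::setcolorder(out, c("hap_a", "hap_b", "start_window",
                                 "end_window", "start_site", "end_site",
                                 "start_bp", "end_bp", "start_cM", "end_cM",
                                 "length_cM", "n_mismatch_windows"))
  data.table::setorder(out, hap_a, hap_b, start_site)
  out[]
}
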