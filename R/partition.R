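#' Partition pairwise analyses into parallel jobs
#'
#' Splits `n_samples` samples into `S` disjoint sets of near-equal size and
#' assigns one job to every unordered pair of sets `{i, j}` with
#' `i <= j` (the diagonal jobs analyze within-set pairs). The requested job
#' count `K` must therefore be a triangular number `K = S(S+1)/2` for an
#' integer `S >= 1`; each sample pair is covered by exactly one job.
#'
#' @param n_samples number of samples (>= 2).
#' @param K requested number of jobs; must equal `S(S+1)/2`.
#' @return list of `K` jobs, each a list with integer sample index vectors
#'   `set_a` and `set_b` (identical for diagonal jobs) and the set labels
#'   `i`, `j`.
#' @examples
#' partition_jobs(4, 3)  # S = 2
#' @export
partition_jobs <- function(n_samples, K) {
  if (n_samples < 2L) stop("n_samples must be >= 2")
  S <- (sqrt(1 + 8 * K) - 1) / 2
  if (!isTRUE(all.equal(S, round(S))) || K < 1) {
    Sl <- floor((sqrt(1 + 8 * K) - 1) / 2); Su <- Sl + 1
    stop("K = ", K, " is not triangular (S(S+1)/2); nearest valid K: ",
         Sl * (Sl + 1) / 2, " or ", Su * (Su + 1) / 2)
  }
  S <- as.integer(round(S))
  if (S > n_samples)
    stop("K = ", K, " implies ", S, " sample sets but only ", n_samples,
         " samples are available")
  sizes <- rep(n_samples %/% S, S)
  if (n_samples %% S > 0L) sizes[seq_len(n_samples %% S)] <- sizes[seq_len(n_samples %% S)] + 1L
  sets <- split(seq_len(n_samples), rep(seq_len(S), times = sizes))
  jobs <- list()
  for (i in seq_len(S)) for (j in i:S) {
    jobs[[length(jobs) + 1L]] <-
      list(i = i, j = j, set_a = sets[[i]], set_b = sets[[j]])
  }
  jobs
}

#' Unordered sample pairs analyzed by one job
#' @param job one element of [partition_jobs()] output.
#' @return 2-column integer matrix of sample index pairs (a < b).
#' @export
job_pairs <- function(job) {
  if (job$i == job$j) {
    s <- job$set_a
    if (length(s) < 2L) return(matrix(integer(), ncol = 2L))
    t(utils::combn(s, 2L))
  } else {
    as.matrix(expand.grid(a = job$set_a, b = job$set_b,
                          KEEP.OUT.ATTRS = FALSE))
  }
}
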