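#' Piecewise-constant demographic model
#'
#' A demographic model specifies the effective population size `Ne(t)` as a
#' piecewise-constant function of time measured backwards in generations.
#' `Ne` is defined on the pairwise-coalescent scale: a pair of haplotypes
#' alive at time `t` coalesces at instantaneous rate `1/Ne(t)` per
#' generation, so under a constant model the pairwise TMRCA is exponential
#' with mean `Ne`. This convention is stated explicitly to avoid the
#' diploid factor-of-two ambiguity; demography files written for this
#' package use the same units.
#'
#' @param start_generation numeric vector of epoch start times in
#'   generations; must begin at 0 and be strictly increasing.
#' @param ne numeric vector of effective sizes, one per epoch; all > 0.
#' @return an object of class `demographic_model`.
#' @examples
#' demographic_model(0, 5000)
#' demographic_model(c(0, 300), c(10000, 2500))
#' @export
demographic_model <- function(start_generation, ne) {
  start_generation <- as.numeric(start_generation)
  ne <- as.numeric(ne)
  if (length(start_generation) != length(ne) || length(ne) < 1L)
    stop("start_generation and ne must have equal, positive length")
  if (start_generation[1L] != 0)
    stop("first epoch must start at generation 0")
  if (is.unsorted(start_generation, strictly = TRUE))
    stop("epoch start times must be strictly increasing")
  if (any(!is.finite(ne)) || any(ne <= 0))
    stop("Ne must be positive and finite in every epoch")
  structure(list(start = start_generation, ne = ne),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Piecewise-constant demographic model (", length(x$ne), " epoch",
      if (length(x$ne) > 1L) "s", "):\n", sep = "")
  ends <- c(x$start[-1L], Inf)
  for (i in seq_along(x$ne))
    cat(sprintf("  [%g, %g) generations: Ne = %g\n", x$start[i], ends[i], x$ne[i]))
  invisible(x)
}

## Internal precomputation: epoch starts, coalescent rates and the cumulative
## hazard Lambda(t) = int_0^t 1/Ne(u) du evaluated at each epoch start.
.demo_prep <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  s <- model$start
  rate <- 1 / model$ne
  cumL <- c(0, cumsum(rate[-length(rate)] * diff(s)))
  ## cumulative integral of exp(Lambda) up to each epoch start (for the SMC
  ## re-coalescence algebra); finite because epochs are finite except the last
  ce <- numeric(length(s))
  if (length(s) > 1L) {
    for (i in seq_len(length(s) - 1L)) {
      ce[i + 1L] <- ce[i] +
        exp(cumL[i]) * (exp(rate[i] * (s[i + 1L] - s[i])) - 1) / rate[i]
    }
  }
  list(s = s, rate = rate, cumL = cumL, ce = ce)
}

.demo_epoch <- function(prep, t) {
  pmax(findInterval(t, prep$s), 1L)
}

## Cumulative coalescent hazard Lambda(t); vectorized, Lambda(Inf) = Inf.
.demo_Lambda <- function(prep, t) {
  i <- .demo_epoch(prep, t)
  out <- prep$cumL[i] + prep$rate[i] * (t - prep$s[i])
  out[is.infinite(t)] <- Inf
  out
}

## Inverse of Lambda; vectorized over hazard values L >= 0.
.demo_Lambda_inv <- function(prep, L) {
  i <- pmax(findInterval(L, prep$cumL), 1L)
  prep$s[i] + (L - prep$cumL[i]) / prep$rate[i]
}

#' Coalescent survival function
#'
#' `S(t) = P(TMRCA > t)` for a random haplotype pair under the model:
#' `S(t) = exp(-int_0^t dt'/Ne(t'))`.
#'
#' @param model a [demographic_model()].
#' @param t numeric vector of times in generations (>= 0).
#' @return numeric vector of survival probabilities.
#' @export
coalescent_survival <- function(model, t) {
  if (any(t < 0)) stop("t must be non-negative")
  exp(-.demo_Lambda(.demo_prep(model), t))
}

#' Quantiles of the pairwise TMRCA distribution
#'
#' @param model a [demographic_model()].
#' @param p probabilities in `[0, 1)`.
#' @return times t such that `P(TMRCA <= t) = p`.
#' @export
coalescent_quantile <- function(model, p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  .demo_Lambda_inv(.demo_prep(model), -log1p(-p))
}

## E[t | a <= t < b] under the coalescent prior, closed form within epochs.
.interval_mean <- function(prep, a, b) {
  den <- exp(-.demo_Lambda(prep, a)) - exp(-.demo_Lambda(prep, b))
  if (den <= 0) return((a + b) / 2)  # degenerate sliver; midpoint
  m <- length(prep$s)
  ends <- c(prep$s[-1L], Inf)
  num <- 0
  for (i in seq_len(m)) {
    u <- max(a, prep$s[i]); v <- min(b, ends[i])
    if (u >= v) next
    lam <- prep$rate[i]
    Ssi <- exp(-prep$cumL[i])
    term_u <- (u + 1 / lam) * exp(-lam * (u - prep$s[i]))
    term_v <- if (is.infinite(v)) 0 else (v + 1 / lam) * exp(-lam * (v - prep$s[i]))
    num <- num + Ssi * (term_u - term_v)
  }
  num / den
}

#' Discretized coalescent prior over TMRCA intervals
#'
#' Computes, for a set of interval boundaries
#' `t_0 = 0 < t_1 < ... < t_K = Inf`, the prior probability of each interval
#' `pi_k = S(t_k) - S(t_{k+1})` and its representative time
#' `E[t | t in interval]` under the model, both in closed form within
#' constant epochs.
#'
#' @param model a [demographic_model()].
#' @param boundaries increasing numeric vector starting at 0 and ending at
#'   `Inf` (a final `Inf` is appended if missing; a leading 0 likewise).
#' @return list with `boundaries`, `probs` (summing to 1) and
#'   `representatives` (one per interval, inside it).
#' @examples
#' m <- demographic_model(0, 5000)
#' coalescent_prior(m, c(0, 50, Inf))$probs[1]  # 1 - exp(-50/5000)
#' @export
coalescent_prior <- function(model, boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) == 0) stop("boundaries must be non-empty")
  if (boundaries[1L] != 0) boundaries <- c(0, boundaries)
  if (is.finite(boundaries[length(boundaries)])) boundaries <- c(boundaries, Inf)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  prep <- .demo_prep(model)
  S <- exp(-.demo_Lambda(prep, boundaries))
  probs <- -diff(S)
  K <- length(probs)
  reps <- vapply(seq_len(K), function(k) {
    .interval_mean(prep, boundaries[k], boundaries[k + 1L])
  }, numeric(1))
  list(boundaries = boundaries, probs = probs, representatives = reps)
}

#' Time discretization at prior quantiles
#'
#' Builds a `TimeDiscretization` whose interior boundaries sit at the prior
#' quantiles `i/K` of the pairwise TMRCA distribution, optionally with
#' additional boundaries pinned at exact generation values (typically the
#' IBD time threshold `T`, so that `P(t <= T)` is an exact partial sum of
#' interval probabilities).
#'
#' @param model a [demographic_model()].
#' @param K number of quantile intervals (>= 2).
#' @param pinned optional numeric vector of generation values inserted
#'   verbatim as boundaries; must be > 0.
#' @return object of class `time_discretization`: list with `boundaries`
#'   (length `n_intervals + 1`, first 0, last `Inf`), `probs` and
#'   `representatives`.
#' @export
make_quantile_discretization <- function(model, K, pinned = NULL) {
  if (K < 2) stop("K must be >= 2")
  if (!is.null(pinned) && any(pinned <= 0))
    stop("pinned boundaries must be > 0")
  qs <- coalescent_quantile(model, seq_len(K - 1L) / K)
  boundaries <- sort(unique(c(0, qs, pinned, Inf)))
  pr <- coalescent_prior(model, boundaries)
  structure(list(boundaries = pr$boundaries, probs = pr$probs,
                 representatives = pr$representatives),
            class = "time_discretization")
}

#' Wrap explicit boundaries as a time discretization
#'
#' @param model a [demographic_model()] used to compute interval priors and
#'   representatives.
#' @param boundaries increasing generation values (0 and `Inf` added if
#'   absent).
#' @return a `time_discretization`.
#' @export
time_discretization <- function(model, boundaries) {
  pr <- coalescent_prior(model, boundaries)
  structure(list(boundaries = pr$boundaries, probs = pr$probs,
                 representatives = pr$representatives),
            class = "time_discretization")
}

#' @export
print.time_discretization <- function(x, ...) {
  cat("TMRCA discretization with", length(x$probs), "intervals\n")
  cat("  boundaries:", paste(signif(utils::head(x$boundaries, 8), 4),
                             collapse = ", "),
      if (length(x$boundaries) > 8) "...", "\n")
  invisible(x)
}

## Number of leading intervals entirely below threshold T; errors unless T is
## an exact boundary so that P(t <= T) is an exact partial sum.
.intervals_below <- function(disc, T) {
  hit <- which(disc$boundaries == T)
  if (length(hit) != 1L)
    stop("time threshold T = ", T,
         " is not a discretization boundary; pin it when building the ",
         "discretization")
  hit - 1L
}
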