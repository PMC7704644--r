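## Coalescent HMM over discretized TMRCA intervals.
##
## The hidden state at a site is the TMRCA interval of the haplotype pair.
## Along the genome the TMRCA follows a sequentially-Markov-coalescent
## (SMC) process: at TMRCA t, recombination strikes at rate 2t per Morgan;
## the detached lineage (pruned at a point uniform on (0, t)) re-coalesces
## at rate 1/Ne(s). We discretize this process by its *flux*: the rate of
## probability flow between intervals under the stationary (prior)
## distribution. The genome process is reversible, so the flux matrix is
## symmetric; symmetrizing the quadrature result makes the prior an exact
## stationary vector of the generator Q, and transition matrices over any
## genetic distance d are M(d) = exp(d * Q), computed via the symmetric
## eigendecomposition of D^{1/2} Q D^{-1/2} (D = diag(prior)).

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
.gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b; J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
}

## int_0^x exp(Lambda(u)) du, vectorized (x finite).
.demo_intE <- function(prep, x) {
  i <- .demo_epoch(prep, x)
  prep$ce[i] + exp(prep$cumL[i]) *
    (exp(prep$rate[i] * (x - prep$s[i])) - 1) / prep$rate[i]
}

## H_j(t) = int_0^t G_j(u) du where G_j(u) is the probability that a
## lineage detached at height u re-coalesces inside interval [a, b).
.smc_H <- function(prep, t, a, b) {
  Sa <- exp(-.demo_Lambda(prep, a)); Sb <- exp(-.demo_Lambda(prep, b))
  low <- .demo_intE(prep, pmin(t, a)) * (Sa - Sb)
  tb <- pmin(t, b)
  mid <- ifelse(t > a,
                (tb - a) - Sb * (.demo_intE(prep, tb) - .demo_intE(prep, a)),
                0)
  low + mid
}

## Symmetric SMC flux matrix between TMRCA intervals (per Morgan).
.smc_flux <- function(disc, model, n_gauss = 24L) {
  prep <- .demo_prep(model)
  K <- length(disc$probs)
  bnd <- disc$boundaries
  t_max <- .demo_Lambda_inv(prep, -log(1e-14))  # truncate S(t) < 1e-14
  bt <- pmin(bnd, t_max)
  if (bt[K + 1L] <= bt[K]) bt[K + 1L] <- bt[K] * 1.5 + 1
  gl <- .gauss_legendre(n_gauss)
  brk_base <- prep$s
  FL <- matrix(0, K, K)
  for (k in seq_len(K)) {
    lo <- bt[k]; hi <- bt[k + 1L]
    for (j in seq_len(K)) {
      a <- bt[j]; b <- bt[j + 1L]
      cuts <- sort(unique(c(lo, hi,
                            brk_base[brk_base > lo & brk_base < hi],
                            c(a, b)[c(a, b) > lo & c(a, b) < hi])))
      acc <- 0
      for (seg in seq_len(length(cuts) - 1L)) {
        p <- cuts[seg]; q <- cuts[seg + 1L]
        x <- (p + q) / 2 + (q - p) / 2 * gl$x
        lam <- prep$rate[.demo_epoch(prep, x)]
        fx <- 2 * lam * exp(-.demo_Lambda(prep, x)) * .smc_H(prep, x, a, b)
        acc <- acc + (q - p) / 2 * sum(gl$w * fx)
      }
      FL[k, j] <- acc
    }
  }
  (FL + t(FL)) / 2
}

#' Build the coalescent HMM machinery for a discretization and model
#'
#' Precomputes the prior, the symmetric-generator eigendecomposition used
#' for transition matrices, and (optionally) per-site emissions and
#' per-gap transitions for a panel.
#'
#' @param disc a `time_discretization` (see
#'   [make_quantile_discretization()]).
#' @param model a [demographic_model()].
#' @return object of class `coal_hmm` with fields `prior`, `eigen`
#'   (values/vectors of the symmetrized generator), `disc`, `model`.
#' @export
coal_hmm <- function(disc, model) {
  stopifnot(inherits(disc, "time_discretization"))
  FL <- .smc_flux(disc, model)
  prior <- disc$probs
  K <- length(prior)
  sq <- sqrt(prior)
  B <- FL / (sq %o% sq)
  diag(B) <- 0
  diag(B) <- -rowSums(FL / prior)  # total jump rate out of each interval
  ## restore self-flux on the diagonal: Q[k,k] = (F[k,k] - sum_j F[k,j])/pi_k
  diag(B) <- diag(B) + diag(FL) / prior
  e <- eigen(B, symmetric = TRUE)
  structure(list(prior = prior, disc = disc, model = model,
                 eigen = e, sq = sq), class = "coal_hmm")
}

#' TMRCA transition matrix over a genetic distance
#'
#' Row-stochastic matrix of interval-to-interval TMRCA transition
#' probabilities across a genetic distance `d_cM` under the SMC kernel.
#' Satisfies: `d = 0` gives the identity; the prior is stationary; rows
#' converge to the prior as `d` grows.
#'
#' @param d_cM genetic distance in cM (>= 0).
#' @param disc a `time_discretization`, or a prebuilt [coal_hmm()].
#' @param model a [demographic_model()] (ignored when `disc` is a
#'   `coal_hmm`).
#' @return `K x K` stochastic matrix.
#' @export
transition_matrix <- function(d_cM, disc, model = NULL) {
  if (d_cM < 0) stop("genetic distance must be non-negative")
  hmm <- if (inherits(disc, "coal_hmm")) disc else coal_hmm(disc, model)
  K <- length(hmm$prior)
  if (d_cM == 0) return(diag(K))
  d_M <- d_cM / 100
  V <- hmm$eigen$vectors
  ev <- exp(hmm$eigen$values * d_M)
  M <- (V %*% (ev * t(V)))
  M <- M * ((1 / hmm$sq) %o% hmm$sq)
  M[M < 0] <- 0
  M / rowSums(M)
}

## ---- emission model ------------------------------------------------------

#' Calibrate the frequency-binned emission model
#'
#' The emission treats the per-site pair observation as a Bernoulli
#' discordance with `P(discordant | t) = 1 - exp(-2 mu_b t)`, where `mu_b`
#' is an effective per-site rate for the site's derived-frequency bin.
#' Each `mu_b` is calibrated so that the prior-expected discordance
#' `E_pi[1 - exp(-2 mu_b t)]` (over interval representatives) equals the
#' panel's observed mean pairwise discordance in that bin, measured on a
#' deterministic systematic subsample of haplotype pairs. This replaces a
#' full frequency-spectrum-conditioned emission with a documented,
#' testable approximation.
#'
#' @param panel a [haplotype_panel()].
#' @param disc a `time_discretization`.
#' @param freq_bins number of derived-frequency bins (default 5).
#' @param max_pairs cap on calibration pairs (default 200).
#' @return object of class `emission_model`: list with `breaks`, `mu`
#'   (per-bin rates), `p_obs` (observed discordances) and the
#'   discretization representatives used.
#' @export
calibrate_emission <- function(panel, disc, freq_bins = 5L,
                               max_pairs = 200L) {
  stopifnot(inherits(disc, "time_discretization"))
  freq <- panel$sites$derived_freq
  breaks <- unique(stats::quantile(freq, probs = seq(0, 1,
                                                     length.out = freq_bins + 1L),
                                   names = FALSE, type = 7))
  breaks[1L] <- 0; breaks[length(breaks)] <- 1
  ## collapse breaks that would leave a frequency bin without sites
  repeat {
    bin <- findInterval(freq, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    n_bin <- length(breaks) - 1L
    empty <- which(tabulate(bin, n_bin) == 0L)
    if (length(empty) == 0L) break
    breaks <- breaks[-(empty[1L] + 1L)]
    if (length(breaks) < 2L) stop("every frequency bin needs >= 1 site")
  }
  pr <- .systematic_pairs(n_haplotypes(panel), max_pairs)
  disc_counts <- numeric(n_bin); tot_counts <- numeric(n_bin)
  for (k in seq_len(nrow(pr))) {
    mism <- panel$alleles[pr[k, 1L], ] != panel$alleles[pr[k, 2L], ]
    disc_counts <- disc_counts + vapply(seq_len(n_bin), function(b)
      sum(mism[bin == b]), numeric(1))
    tot_counts <- tot_counts + tabulate(bin, n_bin)
  }
  p_obs <- disc_counts / tot_counts
  reps <- disc$representatives
  pi_k <- disc$probs
  mu <- vapply(seq_len(n_bin), function(b) {
    p <- p_obs[b]
    if (p <= 0) return(0)
    if (p >= 1) stop("observed discordance in bin ", b,
                     " reaches the model's maximum; cannot calibrate")
    f <- function(m) sum(pi_k * (1 - exp(-2 * m * reps))) - p
    hi <- 1e-6
    while (f(hi) < 0) hi <- hi * 10
    stats::uniroot(f, c(0, hi), tol = hi * 1e-10)$root
  }, numeric(1))
  structure(list(breaks = breaks, mu = mu, p_obs = p_obs,
                 representatives = reps, prior = pi_k),
            class = "emission_model")
}

## deterministic systematic pair subsample: increasing offsets
.systematic_pairs <- function(n_hap, max_pairs) {
  out <- matrix(integer(), ncol = 2L)
  for (o in seq_len(n_hap - 1L)) {
    i <- seq_len(n_hap - o)
    out <- rbind(out, cbind(i, i + o))
    if (nrow(out) >= max_pairs) return(out[seq_len(max_pairs), , drop = FALSE])
  }
  out
}

#' Emission probability of a pair observation
#'
#' @param discordant logical/0-1: whether the pair's alleles differ at the
#'   site.
#' @param derived_freq the site's derived allele frequency (selects the
#'   calibrated bin).
#' @param t TMRCA in generations (typically an interval representative).
#' @param emission a calibrated [calibrate_emission()] model.
#' @return probability of the observation given `t`;
#'   `P(discordant | t) = 1 - exp(-2 mu_b t)`, strictly increasing in `t`.
#' @export
emission_probs <- function(discordant, derived_freq, t, emission) {
  if (!inherits(emission, "emission_model"))
    stop("emission model not calibrated; run calibrate_emission() first")
  b <- findInterval(derived_freq, emission$breaks, rightmost.closed = TRUE,
                    all.inside = TRUE)
  p_disc <- 1 - exp(-2 * emission$mu[b] * t)
  ifelse(as.logical(discordant), p_disc, 1 - p_disc)
}

## ---- panel-level HMM setup and decoding ----------------------------------

#' Attach a panel to the HMM: per-gap transitions and per-site emissions
#'
#' @param panel a [haplotype_panel()].
#' @param hmm a [coal_hmm()].
#' @param emission a calibrated [calibrate_emission()] model.
#' @param T_threshold IBD time threshold in generations; must be a
#'   discretization boundary.
#' @return object of class `pair_decoder`.
#' @export
pair_decoder <- function(panel, hmm, emission, T_threshold) {
  stopifnot(inherits(hmm, "coal_hmm"))
  n_below <- .intervals_below(hmm$disc, T_threshold)
  gaps <- diff(panel$sites$gen_pos)
  key <- signif(gaps, 9)
  uk <- unique(key)
  tmats <- lapply(uk, function(d) transition_matrix(d, hmm))
  trans_idx <- match(key, uk)
  reps <- hmm$disc$representatives
  b <- findInterval(panel$sites$derived_freq, emission$breaks,
                    rightmost.closed = TRUE, all.inside = TRUE)
  e_disc <- 1 - exp(-2 * outer(reps, emission$mu[b]))  # K x n_sites
  e_disc <- pmin(pmax(e_disc, 1e-12), 1 - 1e-12)
  structure(list(panel = panel, hmm = hmm, emission = emission,
                 T_threshold = T_threshold, n_below = n_below,
                 prior_below = sum(hmm$prior[seq_len(n_below)]),
                 tmats = tmats, trans_idx = trans_idx, e_disc = e_disc),
            class = "pair_decoder")
}

#' Per-site observation sequence for a haplotype pair
#' @param panel a [haplotype_panel()].
#' @param hap_a,hap_b haplotype indices.
#' @param start_site,end_site half-open site range (defaults: full panel).
#' @return list with `discordant` (0/1 vector), `sites` (global indices).
#' @export
pair_observation <- function(panel, hap_a, hap_b, start_site = 1L,
                             end_site = n_sites(panel) + 1L) {
  sites <- start_site:(end_site - 1L)
  list(discordant = as.integer(panel$alleles[hap_a, sites] !=
                                 panel$alleles[hap_b, sites]),
       sites = sites)
}

#' Posterior decoding of a pair observation
#'
#' Standard scaled forward-backward over the TMRCA intervals. Columns are
#' normalized; the per-site MAP interval breaks ties toward the most
#' recent interval; `mass_below_T` is the exact posterior mass in the
#' intervals entirely below the time threshold.
#'
#' @param obs a [pair_observation()].
#' @param decoder a [pair_decoder()].
#' @return object of class `posterior_matrix`: list with `posterior`
#'   (`K x L`), `map_index`, `map_time`, `mass_below_T`, `sites`.
#' @export
decode_posterior <- function(obs, decoder) {
  stopifnot(inherits(decoder, "pair_decoder"))
  L <- length(obs$sites)
  if (L < 1L) stop("observation must cover >= 1 site")
  K <- length(decoder$hmm$prior)
  em <- matrix(0, K, L)
  ed <- decoder$e_disc[, obs$sites, drop = FALSE]
  for (l in seq_len(L))
    em[, l] <- if (obs$discordant[l] == 1L) ed[, l] else 1 - ed[, l]
  fwd <- matrix(0, K, L); scale <- numeric(L)
  v <- decoder$hmm$prior * em[, 1L]
  scale[1L] <- sum(v)
  if (scale[1L] <= 0) stop("zero likelihood at first site")
  fwd[, 1L] <- v / scale[1L]
  if (L > 1L) {
    for (l in 2L:L) {
      tm <- decoder$tmats[[decoder$trans_idx[obs$sites[l - 1L]]]]
      v <- as.vector(crossprod(tm, fwd[, l - 1L])) * em[, l]
      scale[l] <- sum(v)
      if (scale[l] <= 0) stop("zero likelihood at site ", obs$sites[l])
      fwd[, l] <- v / scale[l]
    }
  }
  bwd <- matrix(0, K, L)
  bwd[, L] <- 1
  if (L > 1L) {
    for (l in (L - 1L):1L) {
      tm <- decoder$tmats[[decoder$trans_idx[obs$sites[l]]]]
      bwd[, l] <- as.vector(tm %*% (em[, l + 1L] * bwd[, l + 1L]))
      bwd[, l] <- bwd[, l] / sum(bwd[, l])
    }
  }
  post <- fwd * bwd
  post <- sweep(post, 2L, colSums(post), "/")
  map_index <- apply(post, 2L, which.max)  # ties -> most recent interval
  nb <- decoder$n_below
  mass_below <- if (nb == 0L) rep(0, L) else
    colSums(post[seq_len(nb), , drop = FALSE])
  structure(list(posterior = post, map_index = map_index,
                 map_time = decoder$hmm$disc$representatives[map_index],
                 mass_below_T = mass_below, sites = obs$sites),
            class = "posterior_matrix")
}
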