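## Independent reference implementations used as oracles. These are kept
## deliberately naive (string grouping, exhaustive enumeration, dense
## grids) and share no code with the package internals they check.

## -- brute-force candidate scan -------------------------------------------

## Recursive grouping by concatenated window strings, then a per-pair run
## scan under the same gap/length rules as find_candidates.
oracle_candidates <- function(panel, word_size, max_bin_size, max_gap,
                              min_len, depth_cap) {
  wr <- window_ranges(n_sites(panel), word_size)
  n_win <- nrow(wr)
  nh <- n_haplotypes(panel)
  word <- function(h, w)
    paste(panel$alleles[h, wr[w, 1]:(wr[w, 2] - 1)], collapse = "")
  keyfun <- function(w) {
    grp <- function(idx, d) {
      ks <- vapply(idx, function(h)
        paste(vapply(0:d, function(o) word(h, w + o), ""), collapse = ""),
        "")
      out <- rep(NA_character_, length(idx))
      names(out) <- idx
      for (k in unique(ks)) {
        mem <- idx[ks == k]
        if (length(mem) > max_bin_size && d < depth_cap &&
            w + d + 1 <= n_win) {
          out[as.character(mem)] <- grp(mem, d + 1)
        } else {
          out[as.character(mem)] <- paste0(k, "|d", d)
        }
      }
      out
    }
    grp(seq_len(nh), 0)
  }
  keys <- vapply(seq_len(n_win), keyfun, character(nh))
  keys <- matrix(keys, nrow = nh)
  res <- list()
  for (a in seq_len(nh - 1)) for (b in (a + 1):nh) {
    ws <- which(keys[a, ] == keys[b, ])
    if (length(ws) == 0) next
    runs <- list(); cur <- c(ws[1], ws[1], 0)
    for (w in ws[-1]) {
      if (w - cur[2] - 1 <= max_gap) {
        cur[3] <- cur[3] + (w - cur[2] - 1); cur[2] <- w
      } else { runs[[length(runs) + 1]] <- cur; cur <- c(w, w, 0) }
    }
    runs[[length(runs) + 1]] <- cur
    for (r in runs) {
      s0 <- wr[r[1], 1]; s1 <- wr[r[2], 2]
      len <- panel$sites$gen_pos[s1 - 1] - panel$sites$gen_pos[s0]
      if (len >= min_len)
        res[[length(res) + 1]] <- data.frame(
          hap_a = a, hap_b = b, start_site = s0, end_site = s1,
          n_mismatch_windows = r[3])
    }
  }
  if (length(res) == 0) {
    return(data.frame(hap_a = integer(), hap_b = integer(),
                      start_site = integer(), end_site = integer(),
                      n_mismatch_windows = integer()))
  }
  r <- do.call(rbind, res)
  r <- r[order(r$hap_a, r$hap_b, r$start_site), ]
  rownames(r) <- NULL
  r
}

## -- exhaustive-path posterior --------------------------------------------

oracle_posterior <- function(prior, tmats, emis) {
  K <- length(prior); L <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  lik <- apply(paths, 1, function(pt) {
    v <- prior[pt[1]] * emis[pt[1], 1]
    if (L > 1) for (l in 2:L)
      v <- v * tmats[[l - 1]][pt[l - 1], pt[l]] * emis[pt[l], l]
    v
  })
  post <- matrix(0, K, L)
  for (l in seq_len(L)) for (k in seq_len(K))
    post[k, l] <- sum(lik[paths[, l] == k])
  sweep(post, 2, colSums(post), "/")
}

## -- dense-grid SMC flux (constant Ne only) -------------------------------

oracle_transition_const_ne <- function(N, boundaries, d_cM,
                                       ngrid_t = 1500, ngrid_u = 800) {
  K <- length(boundaries) - 1
  tmax <- -N * log(1e-14)
  bt <- pmin(boundaries, tmax)
  if (bt[K + 1] <= bt[K]) bt[K + 1] <- bt[K] * 1.5 + 1
  G <- function(u, a, b)
    exp(u / N) * (exp(-pmax(a, u) / N) - exp(-b / N)) * (u < b)
  FL <- matrix(0, K, K)
  for (k in seq_len(K)) {
    tt <- seq(bt[k], bt[k + 1], length.out = ngrid_t)
    dt <- tt[2] - tt[1]; tt <- tt[-1] - dt / 2
    for (j in seq_len(K)) {
      a <- bt[j]; b <- bt[j + 1]
      Hj <- vapply(tt, function(t) {
        uu <- seq(0, t, length.out = ngrid_u)
        du <- uu[2] - uu[1]; uu <- uu[-1] - du / 2
        sum(G(uu, a, b)) * du
      }, 0)
      FL[k, j] <- sum((1 / N) * exp(-tt / N) * 2 * Hj) * dt
    }
  }
  FL <- (FL + t(FL)) / 2
  pri <- exp(-boundaries[-length(boundaries)] / N) -
    exp(-boundaries[-1] / N)
  Q <- FL / pri
  diag(Q) <- diag(Q) - rowSums(FL / pri)
  as.matrix(Matrix::expm(Q * d_cM / 100))
}

## -- grid-counting coverage -----------------------------------------------

oracle_union_length <- function(starts, ends, lo, hi, res = 0.001) {
  grid <- seq(lo, hi, by = res)
  covered <- rep(FALSE, length(grid))
  for (i in seq_along(starts))
    covered <- covered | (grid >= starts[i] & grid <= ends[i])
  sum(covered) * res
}

## -- naive O(n^3) average linkage on similarities -------------------------

oracle_average_linkage_merges <- function(S) {
  n <- nrow(S)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_s <- -Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        s <- mean(S[clusters[[i]], clusters[[j]]])
        if (s > best_s + 1e-15) { best_s <- s; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- c(sort(c(ids[i], ids[j])), best_s)
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- length(merges)
    clusters[[j]] <- NULL; ids <- ids[-j]
  }
  do.call(rbind, merges)
}

## -- shared fixtures -------------------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

## a modest simulated panel shared across test files (built once)
fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_panel(
      40, 4, demographic_model(c(0, 100), c(2000, 1000)), seed = 42)
  }
  .fixture_env$sim
}

fixture_model <- function() demographic_model(c(0, 100), c(2000, 1000))

random_panel <- function(nh, ns, seed, p = 0.4, clone = TRUE) {
  set.seed(seed)
  al <- matrix(stats::rbinom(nh * ns, 1, p), nh, ns)
  if (clone && nh >= 2) {
    al[2, ] <- al[1, ]
    flips <- sample(ns, max(1, ns %/% 40))
    al[2, flips] <- 1 - al[2, flips]
  }
  keep <- colMeans(al) > 0 & colMeans(al) < 1
  al <- al[, keep, drop = FALSE]
  haplotype_panel(al, "1", seq_len(ncol(al)) * 1000,
                  seq_len(ncol(al)) * 0.02)
}
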