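## Ground-truth coalescent simulation.
##
## Two generators: a sequentially-Markov pair simulator (TMRCA path along
## the chromosome for a single haplotype pair) and a discrete-generation
## Wright-Fisher (DTWF) backward simulator for many haploid samples, with
## per-generation recombination (Poisson on the genetic map), coalescence
## by collision among Ne(g) parent slots, and mutations dropped on
## ancestral material (equivalent to Poisson on marginal-tree branches).
## Both return piecewise-constant true TMRCA, the quantity the detector is
## benchmarked against.

#' Simulate a TMRCA path for one haplotype pair
#'
#' The initial TMRCA is drawn from the pair coalescent under the model;
#' along the map, the distance to the next recombination is exponential
#' with rate `2t` per Morgan at the current TMRCA `t`; at a breakpoint the
#' new TMRCA is drawn from the SMC re-coalescence kernel (detachment point
#' uniform on `(0, t)`, re-coalescence at rate `1/Ne(s)`), the same kernel
#' that drives [transition_matrix()].
#'
#' @param map_length_cM map length in cM (> 0).
#' @param model a [demographic_model()].
#' @param seed optional RNG seed for a reproducible path.
#' @return `data.table` with `start_cM`, `end_cM`, `tmrca` (piecewise
#'   constant, breakpoints strictly increasing).
#' @export
simulate_pair_path <- function(map_length_cM, model, seed = NULL) {
  if (map_length_cM <= 0) stop("map_length_cM must be > 0")
  if (!is.null(seed)) set.seed(seed)
  prep <- .demo_prep(model)
  L <- map_length_cM / 100  # Morgans
  single_epoch <- length(prep$s) == 1L
  rate1 <- prep$rate[1L]
  ## block RNG: standard exponentials/uniforms drawn in batches and
  ## rescaled per step (identical in distribution, far fewer calls)
  blk <- 4096L
  eb <- stats::rexp(blk); ub <- stats::runif(blk); bi <- 0L
  draw <- function() {
    bi <<- bi + 1L
    if (bi > blk) { eb <<- stats::rexp(blk); ub <<- stats::runif(blk); bi <<- 1L }
    c(eb[bi], ub[bi])
  }
  t <- .demo_Lambda_inv(prep, stats::rexp(1))
  pos <- 0
  cap <- 256L; n_seg <- 0L
  starts <- numeric(cap); ends <- numeric(cap); tm <- numeric(cap)
  while (pos < L) {
    z <- draw()
    d <- z[1L] / (2 * t)
    nxt <- if (pos + d < L) pos + d else L
    n_seg <- n_seg + 1L
    if (n_seg > cap) {
      cap <- cap * 2L
      length(starts) <- cap; length(ends) <- cap; length(tm) <- cap
    }
    starts[n_seg] <- pos; ends[n_seg] <- nxt; tm[n_seg] <- t
    pos <- nxt
    if (pos < L) {
      ## SMC'-style update: detach at u ~ U(0, t); the floating lineage
      ## re-coalesces onto either surviving branch (rate 2/Ne while both
      ## are present, i.e. below t), restoring the old TMRCA half the
      ## time; above t a single ancestral stem remains (rate 1/Ne). The
      ## plain detach-and-discard kernel is not exactly stationary and
      ## visibly depletes recent TMRCA occupation.
      u <- z[2L] * t
      z2 <- draw()
      if (single_epoch) {
        s_cand <- u + z2[1L] / (2 * rate1)
        if (s_cand < t) {
          if (z2[2L] < 0.5) t <- s_cand  # else back-coalescence: t stays
        } else {
          t <- t + draw()[1L] / rate1
        }
      } else {
        s_cand <- .demo_Lambda_inv(prep, .demo_Lambda(prep, u) +
                                     z2[1L] / 2)
        if (s_cand < t) {
          if (z2[2L] < 0.5) t <- s_cand
        } else {
          t <- .demo_Lambda_inv(prep, .demo_Lambda(prep, t) + draw()[1L])
        }
      }
    }
  }
  idx <- seq_len(n_seg)
  data.table::data.table(start_cM = starts[idx] * 100,
                         end_cM = ends[idx] * 100, tmrca = tm[idx])
}

## growing record store for pairwise coalescence events (chunked list to
## keep appends O(1))
.new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$chunks <- vector("list", 1024L)
  env$n <- 0L
  env
}

.rec_add <- function(rec, a, b, l, r, g) {
  m <- length(a)
  if (m == 0L) return(invisible())
  if (rec$n + 1L > length(rec$chunks))
    rec$chunks <- c(rec$chunks, vector("list", length(rec$chunks)))
  rec$n <- rec$n + 1L
  rec$chunks[[rec$n]] <- list(a = a, b = b, l = rep_len(l, m),
                              r = rep_len(r, m), g = rep_len(g, m))
  invisible()
}

.rec_collect <- function(rec) {
  ch <- rec$chunks[seq_len(rec$n)]
  data.table::data.table(
    hap_a = unlist(lapply(ch, `[[`, "a"), use.names = FALSE),
    hap_b = unlist(lapply(ch, `[[`, "b"), use.names = FALSE),
    start_cM = unlist(lapply(ch, `[[`, "l"), use.names = FALSE),
    end_cM = unlist(lapply(ch, `[[`, "r"), use.names = FALSE),
    tmrca = unlist(lapply(ch, `[[`, "g"), use.names = FALSE))
}

## merge >= 2 chunk-lineages that landed in the same parent slot at
## generation g; records all cross-pair coalescences on overlapping
## material and drops fully-coalesced (grand-MRCA) material.
.merge_chunks <- function(chunks, g, n_samples, rec) {
  bnd <- sort(unique(unlist(lapply(chunks, function(ch) c(ch$l, ch$r)))))
  if (length(bnd) < 2L)
    return(list(l = numeric(), r = numeric(), sets = list()))
  out_l <- numeric(); out_r <- numeric(); out_sets <- list()
  for (i in seq_len(length(bnd) - 1L)) {
    x0 <- bnd[i]; x1 <- bnd[i + 1L]
    mid <- (x0 + x1) / 2
    members <- list()
    for (ch in chunks) {
      hit <- which(ch$l <= mid & ch$r > mid)
      if (length(hit) == 1L)
        members[[length(members) + 1L]] <- ch$sets[[hit]]
    }
    if (length(members) == 0L) next
    if (length(members) > 1L) {
      for (p in seq_len(length(members) - 1L)) {
        for (q in (p + 1L):length(members)) {
          gridpq <- expand.grid(x = members[[p]], y = members[[q]],
                                KEEP.OUT.ATTRS = FALSE)
          .rec_add(rec, pmin(gridpq$x, gridpq$y), pmax(gridpq$x, gridpq$y),
                   x0, x1, g)
        }
      }
    }
    set <- sort(unique(unlist(members)))
    if (length(set) == n_samples) next  # grand MRCA: drop material
    ## merge with previous elementary interval when contiguous & same set
    k <- length(out_l)
    if (k > 0L && out_r[k] == x0 && identical(out_sets[[k]], set)) {
      out_r[k] <- x1
    } else {
      out_l <- c(out_l, x0); out_r <- c(out_r, x1)
      out_sets[[k + 1L]] <- set
    }
  }
  list(l = out_l, r = out_r, sets = out_sets)
}

## split one lineage at recombination breakpoints (cM positions inside its
## hull); alternating chunks go to two parents.
.split_lineage <- function(lin, breaks) {
  if (length(breaks) == 0L) return(list(lin))
  cuts <- sort(breaks)
  piece_l <- numeric(); piece_r <- numeric(); piece_sets <- list()
  for (s in seq_along(lin$l)) {
    inner <- cuts[cuts > lin$l[s] & cuts < lin$r[s]]
    edges <- c(lin$l[s], inner, lin$r[s])
    for (e in seq_len(length(edges) - 1L)) {
      piece_l <- c(piece_l, edges[e]); piece_r <- c(piece_r, edges[e + 1L])
      piece_sets[[length(piece_l)]] <- lin$sets[[s]]
    }
  }
  parity <- findInterval((piece_l + piece_r) / 2, cuts) %% 2L
  out <- list()
  for (p in c(0L, 1L)) {
    sel <- which(parity == p)
    if (length(sel) == 0L) next
    out[[length(out) + 1L]] <- list(l = piece_l[sel], r = piece_r[sel],
                                    sets = piece_sets[sel])
  }
  out
}

#' Simulate a multi-sample panel with ground-truth TMRCA
#'
#' Discrete-generation Wright-Fisher backward simulation of `n_haploids`
#' haploid samples over a region of `region_cM`. Each generation, every
#' ancestral lineage recombines at Poisson breakpoints (rate = its
#' ancestral-material hull in Morgans) and its chunks pick parents among
#' `Ne(g)` slots; lineages colliding in a slot coalesce.
#' Mutations accrue on ancestral material at `mutation_rate` per bp per
#' generation. The full pairwise TMRCA truth is recorded.
#'
#' @param n_haploids number of haploid samples (>= 2).
#' @param region_cM region length in cM; physical coordinates use
#'   `bp_per_cM` (default 1 Mb/cM).
#' @param model a [demographic_model()].
#' @param mutation_rate per-bp per-generation mutation rate (default
#'   1.2e-8).
#' @param seed RNG seed.
#' @param bp_per_cM physical bp per cM.
#' @param budget desk-scale guard: `n_haploids * region_cM` must not
#'   exceed it (default 4000); larger designs should use
#'   [simulate_pair_path()] per pair.
#' @return object of class `sim_panel`: list with `panel` (a
#'   [haplotype_panel()]), `truth` (`data.table` of `hap_a`, `hap_b`,
#'   `start_cM`, `end_cM`, `tmrca` covering every pair over the whole
#'   region), and `params`.
#' @export
simulate_panel <- function(n_haploids, region_cM, model,
                           mutation_rate = 1.2e-8, seed = NULL,
                           bp_per_cM = 1e6, budget = 4000) {
  if (n_haploids < 2L) stop("n_haploids must be >= 2")
  if (region_cM <= 0) stop("region_cM must be > 0")
  if (n_haploids * region_cM > budget)
    stop("n_haploids * region_cM = ", n_haploids * region_cM,
         " exceeds the desk-scale budget (", budget,
         "); use simulate_pair_path() for larger designs")
  if (!is.null(seed)) set.seed(seed)
  prep <- .demo_prep(model)
  n <- as.integer(n_haploids)
  L <- region_cM
  mu_cM <- mutation_rate * bp_per_cM  # mutations per cM per generation
  lineages <- lapply(seq_len(n), function(i)
    list(l = 0, r = L, sets = list(i)))
  rec <- .new_recorder()
  mut_chunks <- list(); n_mut_chunks <- 0L
  g <- 0
  while (length(lineages) > 0L) {
    k <- length(lineages)
    hull_M <- vapply(lineages, function(x)
      (max(x$r) - min(x$l)) / 100, numeric(1))
    mat_cM <- vapply(lineages, function(x) sum(x$r - x$l), numeric(1))
    ## mutations over the generation
    n_mut <- stats::rpois(1, mu_cM * sum(mat_cM))
    if (n_mut > 0L) {
      which_lin <- sample.int(k, n_mut, replace = TRUE, prob = mat_cM)
      mpos <- numeric(n_mut); msets <- vector("list", n_mut)
      for (m in seq_len(n_mut)) {
        lin <- lineages[[which_lin[m]]]
        w <- lin$r - lin$l
        s <- if (length(w) == 1L) 1L else sample.int(length(w), 1L, prob = w)
        mpos[m] <- stats::runif(1, lin$l[s], lin$r[s])
        msets[[m]] <- lin$sets[[s]]
      }
      n_mut_chunks <- n_mut_chunks + 1L
      mut_chunks[[n_mut_chunks]] <- list(pos = mpos, sets = msets)
    }
    g <- g + 1
    ne_g <- model$ne[.demo_epoch(prep, g)]
    slots_n <- max(2, round(ne_g))
    ## recombination: split each lineage into parent chunks (vectorized
    ## over lineages; most lineages do not recombine in a generation)
    nb <- stats::rpois(k, hull_M)
    chunks <- vector("list", k + sum(nb))
    n_chunks <- 0L
    for (li in seq_len(k)) {
      if (nb[li] == 0L) {
        n_chunks <- n_chunks + 1L
        chunks[[n_chunks]] <- lineages[[li]]
      } else {
        lin <- lineages[[li]]
        parts <- .split_lineage(
          lin, stats::runif(nb[li], min(lin$l), max(lin$r)))
        for (p in parts) {
          n_chunks <- n_chunks + 1L
          chunks[[n_chunks]] <- p
        }
      }
    }
    chunks <- chunks[seq_len(n_chunks)]
    owner_slot <- sample.int(slots_n, n_chunks, replace = TRUE)
    ## coalesce chunks sharing a slot
    dup_slots <- unique(owner_slot[duplicated(owner_slot)])
    singles <- !(owner_slot %in% dup_slots)
    new_lineages <- chunks[singles]
    for (slot in dup_slots) {
      lin <- .merge_chunks(chunks[owner_slot == slot], g, n, rec)
      if (length(lin$l) > 0L)
        new_lineages[[length(new_lineages) + 1L]] <- lin
    }
    lineages <- new_lineages
  }
  ## assemble truth paths, fusing contiguous runs with equal TMRCA
  truth <- .rec_collect(rec)
  data.table::setorder(truth, hap_a, hap_b, start_cM)
  new_run <- c(TRUE, truth$hap_a[-1] != truth$hap_a[-nrow(truth)] |
                 truth$hap_b[-1] != truth$hap_b[-nrow(truth)] |
                 truth$tmrca[-1] != truth$tmrca[-nrow(truth)] |
                 truth$start_cM[-1] > truth$end_cM[-nrow(truth)] + 1e-12)
  truth$run <- cumsum(new_run)
  truth <- truth[, list(hap_a = hap_a[1L], hap_b = hap_b[1L],
                        start_cM = min(start_cM), end_cM = max(end_cM),
                        tmrca = tmrca[1L]), by = "run"]
  truth$run <- NULL
  ## assemble panel from mutations
  mut_pos <- unlist(lapply(mut_chunks, `[[`, "pos"), use.names = FALSE)
  mut_sets <- do.call(c, lapply(mut_chunks, `[[`, "sets"))
  if (is.null(mut_pos)) mut_pos <- numeric()
  if (is.null(mut_sets)) mut_sets <- list()
  poly <- lengths(mut_sets) > 0L & lengths(mut_sets) < n
  mut_pos <- mut_pos[poly]; mut_sets <- mut_sets[poly]
  ord <- order(mut_pos)
  mut_pos <- mut_pos[ord]; mut_sets <- mut_sets[ord]
  dup <- duplicated(mut_pos)
  mut_pos <- mut_pos[!dup]; mut_sets <- mut_sets[!dup]
  if (length(mut_pos) < 2L)
    stop("simulation produced <2 polymorphic sites; increase ",
         "mutation_rate or region_cM")
  alleles <- matrix(0L, nrow = n, ncol = length(mut_pos))
  for (s in seq_along(mut_pos)) alleles[mut_sets[[s]], s] <- 1L
  phys <- floor(mut_pos * bp_per_cM) + 1
  for (s in seq_along(phys)[-1]) {  # force strictly increasing bp
    if (phys[s] <= phys[s - 1L]) phys[s] <- phys[s - 1L] + 1
  }
  panel <- haplotype_panel(alleles, chrom = "1", phys_pos = phys,
                           gen_pos = mut_pos,
                           individual_ids = sprintf("sim%03d", seq_len(n)),
                           hap_index = rep(0L, n))
  structure(list(panel = panel, truth = truth,
                 params = list(n_haploids = n, region_cM = region_cM,
                               model = model, mutation_rate = mutation_rate,
                               seed = seed, bp_per_cM = bp_per_cM)),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("Simulated panel:", x$params$n_haploids, "haploids,",
      x$params$region_cM, "cM,", n_sites(x$panel), "polymorphic sites\n")
  invisible(x)
}

#' True TMRCA for a pair at given genetic positions
#' @param truth the `truth` table of a [simulate_panel()] result.
#' @param hap_a,hap_b haplotype indices (a < b).
#' @param gen_pos genetic positions (cM).
#' @return numeric TMRCA values (NA outside recorded coverage).
#' @export
truth_tmrca_at <- function(truth, hap_a, hap_b, gen_pos) {
  sel <- truth[["hap_a"]] == hap_a & truth[["hap_b"]] == hap_b
  sub <- data.table::as.data.table(truth)[which(sel)]
  if (nrow(sub) == 0L) stop("pair (", hap_a, ",", hap_b, ") not in truth")
  .tmrca_lookup(sub, gen_pos)
}

## interval lookup on one pair's (sorted) truth path
.tmrca_lookup <- function(sub, gen_pos) {
  idx <- findInterval(gen_pos, sub$start_cM)
  out <- rep(NA_real_, length(gen_pos))
  ok <- idx >= 1L & gen_pos <= sub$end_cM[pmax(idx, 1L)] + 1e-12
  out[ok] <- sub$tmrca[idx[ok]]
  out
}

#' Ascertain sites to mimic a SNP array
#'
#' Subsamples polymorphic sites to a target marker density and (optionally)
#' a target derived-allele-frequency spectrum, emulating array design:
#' retained count is about `target_density * region_cM`, per-frequency-bin
#' targets are filled as far as availability allows (shortfalls are
#' reported), and sampling is without replacement under the given seed.
#'
#' @param sim a [simulate_panel()] result.
#' @param target_density retained SNPs per cM (> 0).
#' @param target_spectrum optional list with `breaks` (frequency bin edges
#'   spanning 0..1) and `weights` (relative bin masses); `NULL` keeps the
#'   observed spectrum (uniform thinning).
#' @param seed RNG seed.
#' @return a `sim_panel` with the subsampled panel (truth unchanged).
#' @export
ascertain_sites <- function(sim, target_density, target_spectrum = NULL,
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_panel"))
  if (target_density <= 0) stop("target_density must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_target <- min(round(target_density * sim$params$region_cM),
                  n_sites(sim$panel))
  freq <- sim$panel$sites$derived_freq
  if (is.null(target_spectrum)) {
    keep <- sort(sample.int(length(freq), n_target))
  } else {
    breaks <- target_spectrum$breaks
    w <- target_spectrum$weights / sum(target_spectrum$weights)
    bin <- findInterval(freq, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    keep <- integer()
    for (b in seq_along(w)) {
      avail <- which(bin == b)
      want <- round(w[b] * n_target)
      if (want > length(avail))
        message("frequency bin ", b, ": wanted ", want, ", only ",
                length(avail), " available")
      take <- min(want, length(avail))
      if (take > 0L)
        keep <- c(keep, sample(avail, take))
    }
    keep <- sort(keep)
  }
  sim$panel <- .subset_panel_sites(sim$panel, keep)
  sim
}

.subset_panel_sites <- function(panel, idx) {
  haplotype_panel(panel$alleles[, idx, drop = FALSE],
                  chrom = panel$sites$chrom[idx],
                  phys_pos = panel$sites$phys_pos[idx],
                  gen_pos = panel$sites$gen_pos[idx],
                  individual_ids = panel$individual_ids,
                  hap_index = panel$hap_index,
                  id = panel$sites$id[idx], ref = panel$sites$ref[idx],
                  alt = panel$sites$alt[idx])
}

#' Write / read a truth-path table
#' @param truth truth `data.table` (`hap_a`, `hap_b`, `start_cM`,
#'   `end_cM`, `tmrca`).
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  data.table::fread(path, sep = "\t")
}
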