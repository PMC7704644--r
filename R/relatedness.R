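#' Per-pair IBD sharing summaries
#'
#' For every pair with at least one segment: segment count, total shared
#' length and fraction of genome shared `f_T` (union of the pair's
#' segments divided by the map length). Overlapping segments for a pair
#' are unioned before any coverage arithmetic.
#'
#' @param calls segment table (individual ids `ind_a`/`ind_b` or haplotype
#'   indices; `start_cM`, `end_cM`).
#' @param total_cM total map length in cM (> 0).
#' @param by `"individual"` (default) or `"haplotype"` pairing unit.
#' @return `data.table`: `id_a`, `id_b`, `n_segments`, `total_cM`
#'   (union length), `fraction_genome`.
#' @export
pair_summaries <- function(calls, total_cM, by = c("individual",
                                                   "haplotype")) {
  by <- match.arg(by)
  calls <- data.table::as.data.table(calls)
  if (total_cM <= 0) stop("total_cM must be > 0")
  if (nrow(calls) > 0 && max(calls$end_cM) - min(calls$start_cM) >
        total_cM + 1e-9)
    stop("segment outside the map")
  if (by == "individual" && "ind_a" %in% names(calls)) {
    ka <- as.character(calls$ind_a); kb <- as.character(calls$ind_b)
  } else {
    calls <- .calls_hap_idx(calls)
    ka <- as.character(calls$hap_a); kb <- as.character(calls$hap_b)
  }
  id_a <- ifelse(ka <= kb, ka, kb); id_b <- ifelse(ka <= kb, kb, ka)
  dt <- data.table::data.table(id_a = id_a, id_b = id_b,
                               start = calls$start_cM, end = calls$end_cM)
  out <- dt[, {
    u <- .interval_union(start, end)
    list(n_segments = .N, total_cM = u)
  }, by = c("id_a", "id_b")]
  out$fraction_genome <- pmin(out$total_cM / total_cM, 1)
  data.table::setorder(out, id_a, id_b)
  out[]
}

## total length of the union of intervals [s, e]
.interval_union <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0; cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
  }
  tot + (cur_e - cur_s)
}

#' Fraction of an individual's genome covered by IBD with anyone
#'
#' @param calls segment table.
#' @param individual individual id (or haplotype index with
#'   `by = "haplotype"`).
#' @param total_cM map length in cM.
#' @param by pairing unit as in [pair_summaries()].
#' @return fraction in `[0, 1]`.
#' @export
genome_coverage <- function(calls, individual, total_cM,
                            by = c("individual", "haplotype")) {
  by <- match.arg(by)
  calls <- data.table::as.data.table(calls)
  if (by == "individual" && "ind_a" %in% names(calls)) {
    hit <- calls$ind_a == individual | calls$ind_b == individual
  } else {
    calls <- .calls_hap_idx(calls)
    hit <- calls$hap_a == individual | calls$hap_b == individual
  }
  sub <- calls[hit]
  if (nrow(sub) == 0L) return(0)
  min(.interval_union(sub$start_cM, sub$end_cM) / total_cM, 1)
}

#' IBD-based effective population size estimate
#'
#' Under a constant pairwise-coalescent size `Ne`,
#' `P(TMRCA <= T) = 1 - exp(-T/Ne) ~ T/Ne`, and the expected fraction of
#' genome in IBD segments with threshold `T` equals that probability, so
#' `Ne` is estimated as `T / mean(f_T)`.
#'
#' @param f_T_mean sample mean of the fraction of genome shared (> 0).
#' @param T_threshold IBD time threshold in generations (> 0).
#' @return single aggregate effective size estimate.
#' @examples
#' estimate_ne(0.01, 50)  # 5000
#' @export
estimate_ne <- function(f_T_mean, T_threshold) {
  if (T_threshold <= 0) stop("T_threshold must be > 0")
  if (f_T_mean <= 0) stop("mean sharing fraction is 0; estimate is infinite")
  T_threshold / f_T_mean
}

#' Expected total IBD sharing between k-th degree cousins
#'
#' `2 G (1/2)^(2(k+1))` centimorgans, where `G` is the total diploid
#' genome size in cM and `2(k+1)` the number of meioses separating the
#' cousins. Halves by a factor of 4 per degree.
#'
#' @param k cousin degree (>= 1).
#' @param G total diploid genome size in cM (default 7247.14).
#' @return expected shared cM.
#' @examples
#' expected_cousin_sharing(2)  # ~226.5 cM
#' @export
expected_cousin_sharing <- function(k, G = 7247.14) {
  if (any(k < 1)) stop("cousin degree k must be >= 1")
  if (G <= 0) stop("G must be > 0")
  2 * G * (1 / 2)^(2 * (k + 1))
}

#' k-nearest-neighbour prediction of location from IBD sharing
#'
#' Predicts each query's planar coordinates as the unweighted mean of the
#' coordinates of its `K` most IBD-sharing neighbours (ties broken by
#' neighbour id), excluding listed close-relative pairs.
#'
#' @param similarity `data.table`/data.frame of pair similarities
#'   (`id_a`, `id_b`, `total_cM`), symmetric by construction.
#' @param coords data.frame with `id`, `x`, `y` for reference individuals
#'   (queries may also appear: their rows supply truth for the error
#'   summary and are never used as their own neighbours).
#' @param queries character vector of query ids.
#' @param K neighbours used (default 5).
#' @param exclude optional 2-column pair list of close relatives to
#'   ignore.
#' @return list with `predictions` (`data.table`: id, pred_x, pred_y,
#'   error), `median_error`, `mean_error`, `cor_x`, `cor_y` (NA when no
#'   truth available).
#' @export
knn_predict_location <- function(similarity, coords, queries, K = 5L,
                                 exclude = NULL) {
  sim <- data.table::as.data.table(similarity)
  coords <- as.data.frame(coords)
  excl_keys <- character()
  if (!is.null(exclude) && NROW(exclude) > 0L) {
    ea <- as.character(exclude[[1L]]); eb <- as.character(exclude[[2L]])
    excl_keys <- paste(pmin(ea, eb), pmax(ea, eb))
  }
  preds <- data.table::data.table(id = queries, pred_x = NA_real_,
                                  pred_y = NA_real_, error = NA_real_)
  for (i in seq_along(queries)) {
    q <- queries[i]
    nb <- sim[sim$id_a == q | sim$id_b == q]
    if (nrow(nb) == 0L) { warning("query ", q, " has no neighbours"); next }
    other <- ifelse(nb$id_a == q, nb$id_b, nb$id_a)
    keep <- !(paste(pmin(q, other), pmax(q, other)) %in% excl_keys)
    other <- other[keep]; s <- nb$total_cM[keep]
    known <- other %in% coords$id & other != q
    other <- other[known]; s <- s[known]
    if (length(other) < K) {
      warning("query ", q, " has fewer than K=", K,
              " usable neighbours; NaN prediction")
      next
    }
    o <- order(-s, other)
    top <- other[o][seq_len(K)]
    cc <- coords[match(top, coords$id), ]
    preds$pred_x[i] <- mean(cc$x); preds$pred_y[i] <- mean(cc$y)
    truth_row <- match(q, coords$id)
    if (!is.na(truth_row)) {
      preds$error[i] <- sqrt((preds$pred_x[i] - coords$x[truth_row])^2 +
                               (preds$pred_y[i] - coords$y[truth_row])^2)
    }
  }
  have <- !is.na(preds$error)
  truth_xy <- coords[match(preds$id, coords$id), ]
  cor_x <- if (sum(have) > 2 && stats::sd(preds$pred_x[have]) > 0 &&
                 stats::sd(truth_xy$x[have]) > 0)
    stats::cor(preds$pred_x[have], truth_xy$x[have]) else NA_real_
  cor_y <- if (sum(have) > 2 && stats::sd(preds$pred_y[have]) > 0 &&
                 stats::sd(truth_xy$y[have]) > 0)
    stats::cor(preds$pred_y[have], truth_xy$y[have]) else NA_real_
  list(predictions = preds,
       median_error = stats::median(preds$error, na.rm = TRUE),
       mean_error = mean(preds$error, na.rm = TRUE),
       cor_x = cor_x, cor_y = cor_y)
}

#' Allele-sharing (GRM) similarity baseline
#'
#' Standardized-genotype inner products, the classical genetic
#' relatedness matrix, returned in the same sparse pair format as IBD
#' similarities so it can be plugged into [knn_predict_location()] for
#' the IBD-vs-allele-sharing contrast.
#'
#' @param genotypes matrix of dosages (individuals x sites).
#' @param ids individual ids (default rownames).
#' @return `data.table`: `id_a`, `id_b`, `total_cM` (the GRM entry, named
#'   for interface compatibility).
#' @export
grm_similarity <- function(genotypes, ids = rownames(genotypes)) {
  X <- scale(genotypes)
  X[is.nan(X)] <- 0
  G <- X %*% t(X) / ncol(genotypes)
  idx <- which(upper.tri(G), arr.ind = TRUE)
  data.table::data.table(id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
                         total_cM = G[idx])
}

#' Average-linkage hierarchical clustering of a sparse similarity
#'
#' Agglomerative average-linkage clustering on a sparse non-negative
#' similarity: the pair of clusters with the highest mean cross-pair
#' similarity (absent entries count as 0) is merged at each step.
#' Restricted to the largest connected component; smaller components are
#' dropped with a message. Flat clusters are cut where merge similarity
#' drops below `cut`; clusters smaller than `min_cluster_size` are
#' labelled `NA` (unassigned).
#'
#' @param similarity pair table (`id_a`, `id_b`, `similarity` or
#'   `total_cM`), non-negative.
#' @param cut flat-cut similarity level (merges below it are not applied
#'   for the flat labels; the full dendrogram is still returned).
#' @param min_cluster_size smallest reported flat cluster (default 1).
#' @return list with `labels` (node ids), `merges` (`data.table`: step,
#'   a, b, similarity; negative entries index leaves, positive entries
#'   merge steps, hclust-style), `flat` (named cluster assignment, NA =
#'   unassigned), `dropped` (ids outside the largest component).
#' @export
cluster_average_linkage <- function(similarity, cut = 0,
                                    min_cluster_size = 1L) {
  sim <- data.table::as.data.table(similarity)
  scol <- if ("similarity" %in% names(sim)) "similarity" else "total_cM"
  if (any(sim[[scol]] < 0)) stop("similarities must be non-negative")
  ids <- sort(unique(c(as.character(sim$id_a), as.character(sim$id_b))))
  if (length(ids) == 0L) stop("empty similarity")
  ## largest connected component via union-find
  parent <- seq_along(ids); names(parent) <- ids
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(sim))) {
    a <- find(match(as.character(sim$id_a[r]), ids))
    b <- find(match(as.character(sim$id_b[r]), ids))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  comp_sizes <- table(roots)
  main_root <- as.integer(names(comp_sizes)[which.max(comp_sizes)])
  keep <- roots == main_root
  dropped <- ids[!keep]
  if (length(dropped) > 0L)
    message("dropping ", length(dropped),
            " node(s) outside the largest connected component")
  ids <- ids[keep]
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  ina <- match(as.character(sim$id_a), ids)
  inb <- match(as.character(sim$id_b), ids)
  ok <- !is.na(ina) & !is.na(inb)
  S[cbind(ina[ok], inb[ok])] <- sim[[scol]][ok]
  S[cbind(inb[ok], ina[ok])] <- sim[[scol]][ok]
  diag(S) <- -Inf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  node_id <- -seq_len(n)  # hclust convention: negative = leaf
  merges <- data.table::data.table(step = integer(), a = integer(),
                                   b = integer(), similarity = numeric())
  members <- as.list(seq_len(n))
  flat_members <- as.list(seq_len(n))  # only merges >= cut applied
  step <- 0L
  ## Lance-Williams average linkage on similarities:
  ## s(A+B, C) = (nA s(A,C) + nB s(B,C)) / (nA + nB)
  while (sum(active) > 1L) {
    act <- which(active)
    sub <- S[act, act, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- act[min(best)]; j <- act[max(best)]
    h <- S[i, j]
    step <- step + 1L
    ab <- sort(c(node_id[i], node_id[j]))
    merges <- rbind(merges,
                    data.table::data.table(step = step, a = ab[1],
                                           b = ab[2], similarity = h))
    newS <- (size[i] * S[i, ] + size[j] * S[j, ]) / (size[i] + size[j])
    S[i, ] <- newS; S[, i] <- newS
    S[i, i] <- -Inf; S[i, j] <- -Inf; S[j, i] <- -Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    node_id[i] <- step
    members[[i]] <- c(members[[i]], members[[j]])
    if (h >= cut) flat_members[[i]] <- c(flat_members[[i]],
                                         flat_members[[j]])
    S[!active, ] <- -Inf; S[, !active] <- -Inf
  }
  ## flat assignment: clusters are the flat_members groups of surviving
  ## representatives plus unmerged-below-cut leaves
  assigned <- rep(NA_integer_, n); names(assigned) <- ids
  cl <- 0L
  seen <- rep(FALSE, n)
  for (i in order(-vapply(flat_members, length, integer(1)))) {
    mem <- flat_members[[i]]
    mem <- mem[!seen[mem]]
    if (length(mem) == 0L) next
    seen[mem] <- TRUE
    if (length(mem) >= min_cluster_size) {
      cl <- cl + 1L
      assigned[mem] <- cl
    }
  }
  list(labels = ids, merges = merges, flat = assigned, dropped = dropped)
}
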