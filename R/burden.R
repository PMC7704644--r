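#' Identify LoF-segments: IBD segments linking carriers to the
#' non-sequenced cohort
#'
#' A LoF-segment for a gene is any IBD segment whose two endpoint
#' individuals are (i) an exome-sequenced loss-of-function carrier for the
#' gene and (ii) a non-sequenced individual, and which overlaps the gene
#' interval by at least 1 bp. Either haplotype of either individual
#' qualifies: the test is phase-agnostic because the phase of the LoF
#' allele is unknown.
#'
#' @param calls IBD segment table (`ind_a`, `ind_b`, `start_bp`, `end_bp`,
#'   `score`).
#' @param carriers `data.frame` of genes: `gene`, `start_bp`, `end_bp`,
#'   `carrier_ids` (list column or comma-separated string of individual
#'   ids).
#' @param sequenced_ids ids of the exome-sequenced cohort.
#' @param nonsequenced_ids ids of the non-sequenced cohort (disjoint from
#'   `sequenced_ids`).
#' @return `data.table`: `gene`, `individual` (non-sequenced), `carrier`,
#'   `score`, one row per qualifying segment.
#' @export
lof_segments <- function(calls, carriers, sequenced_ids,
                         nonsequenced_ids) {
  if (length(intersect(sequenced_ids, nonsequenced_ids)) > 0L)
    stop("individual(s) in both cohorts: ",
         paste(utils::head(intersect(sequenced_ids, nonsequenced_ids), 3),
               collapse = ", "))
  calls <- data.table::as.data.table(calls)
  carriers <- as.data.frame(carriers)
  out <- list()
  for (g in seq_len(nrow(carriers))) {
    cids <- carriers$carrier_ids[[g]]
    if (is.character(cids) && length(cids) == 1L && grepl(",", cids))
      cids <- strsplit(cids, ",")[[1L]]
    cids <- intersect(cids, sequenced_ids)
    if (length(cids) == 0L) next
    ov <- calls$end_bp >= carriers$start_bp[g] &
      calls$start_bp <= carriers$end_bp[g]
    a_car <- calls$ind_a %in% cids & calls$ind_b %in% nonsequenced_ids
    b_car <- calls$ind_b %in% cids & calls$ind_a %in% nonsequenced_ids
    hit <- which(ov & (a_car | b_car))
    if (length(hit) == 0L) next
    out[[length(out) + 1L]] <- data.table::data.table(
      gene = carriers$gene[g],
      individual = ifelse(a_car[hit], calls$ind_b[hit], calls$ind_a[hit]),
      carrier = ifelse(a_car[hit], calls$ind_a[hit], calls$ind_b[hit]),
      score = calls$score[hit])
  }
  if (length(out) == 0L)
    return(data.table::data.table(gene = character(),
                                  individual = character(),
                                  carrier = character(), score = numeric()))
  data.table::rbindlist(out)
}

#' Decile-thresholded LoF-segment burden vectors
#'
#' For each gene, segment scores define decile cutoffs (empirical
#' quantiles `(d-1)/10`, `d = 1..10`, with `d = 1` unbounded below);
#' `burden_d` for an individual is the sum of that individual's segment
#' scores at or above cutoff `d`. Stricter cutoffs never increase the
#' burden. Genes without segments are skipped (they do not count toward
#' multiple testing).
#'
#' @param segments output of [lof_segments()].
#' @param individuals ids to report (default: all individuals appearing).
#' @param n_deciles number of transformations (default 10).
#' @param pooled when `TRUE`, cutoffs come from all genes' segments
#'   pooled rather than per gene.
#' @return `data.table` in long format: `gene`, `individual`, `decile`,
#'   `burden`.
#' @export
burden_vectors <- function(segments, individuals = NULL, n_deciles = 10L,
                           pooled = FALSE) {
  segments <- data.table::as.data.table(segments)
  if (nrow(segments) == 0L)
    return(data.table::data.table(gene = character(),
                                  individual = character(),
                                  decile = integer(), burden = numeric()))
  if (is.null(individuals)) individuals <- unique(segments$individual)
  pooled_cuts <- if (pooled)
    stats::quantile(segments$score, probs = (seq_len(n_deciles) - 1L) /
                      n_deciles, names = FALSE, type = 7)
  out <- list()
  for (g in unique(segments$gene)) {
    sub <- segments[segments$gene == g]
    cuts <- if (pooled) pooled_cuts else
      stats::quantile(sub$score, probs = (seq_len(n_deciles) - 1L) /
                        n_deciles, names = FALSE, type = 7)
    cuts[1L] <- -Inf
    for (d in seq_len(n_deciles)) {
      qual <- sub[sub$score >= cuts[d]]
      agg <- qual[, list(burden = sum(score)), by = "individual"]
      miss <- setdiff(individuals, agg$individual)
      out[[length(out) + 1L]] <- rbind(
        data.table::data.table(gene = g, individual = agg$individual,
                               decile = d, burden = agg$burden),
        data.table::data.table(gene = g, individual = miss, decile = d,
                               burden = 0))
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, gene, individual, decile)
  res[]
}

#' Rank-based inverse normal transform
#'
#' Maps values to `qnorm((rank - 0.5) / n)` with average ranks for ties.
#'
#' @param values numeric vector (`n >= 2`, not all identical).
#' @return transformed vector (approximately standard normal).
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2L) stop("need n >= 2")
  if (stats::sd(values) == 0) stop("all values identical; cannot rank")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Linear-regression burden association test
#'
#' Ordinary least squares of the phenotype on the burden plus covariates
#' (and optional tag-SNP dosage columns); the reported p-value is the
#' two-sided t-test on the burden coefficient.
#'
#' @param burden numeric burden vector.
#' @param phenotype numeric phenotype (same length).
#' @param covariates optional data.frame/matrix of covariates.
#' @param snp_covariates optional matrix of up to 3 SNP dosage columns
#'   (the SNP-adjusted mode).
#' @return list: `beta`, `se`, `p`, `t`, `n`, `covariate_names`.
#' @export
burden_test <- function(burden, phenotype, covariates = NULL,
                        snp_covariates = NULL) {
  X <- cbind(burden = burden)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (!is.null(snp_covariates)) {
    snp_covariates <- as.matrix(snp_covariates)
    if (ncol(snp_covariates) > 3L)
      stop("at most 3 SNP covariates are supported")
    colnames(snp_covariates) <- paste0("snp", seq_len(ncol(snp_covariates)))
    X <- cbind(X, snp_covariates)
  }
  keep <- stats::complete.cases(X, phenotype)
  X <- X[keep, , drop = FALSE]; y <- phenotype[keep]
  df <- as.data.frame(X)
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  list(beta = sm["burden", 1L], se = sm["burden", 2L],
       t = sm["burden", 3L], p = sm["burden", 4L], n = length(y),
       covariate_names = setdiff(colnames(df), "burden"))
}

#' Exome-wide scan over genes and burden transformations
#'
#' Runs [burden_test()] for each gene and each of the decile
#' transformations, takes the per-gene minimum p-value, and flags results
#' against the replication threshold `0.05/10` and the exome-wide
#' threshold `0.05 / (n_genes x n_transformations)` (conservative
#' independence assumption across transformations).
#'
#' @param burdens long burden table from [burden_vectors()].
#' @param phenotype named numeric vector (names = individual ids), already
#'   inverse-normal transformed (or use `transform_phenotype = TRUE`).
#' @param covariates optional data.frame with rownames = individual ids.
#' @param snp_covariates optional named list: gene -> dosage matrix with
#'   rownames = individual ids.
#' @param alpha family-wise target (default 0.05).
#' @param transform_phenotype apply [inverse_normal_transform()] first.
#' @return list with `results` (per gene x decile), `genes` (per-gene
#'   min-p with flags), `exome_threshold`, `replication_threshold`.
#' @export
gene_scan <- function(burdens, phenotype, covariates = NULL,
                      snp_covariates = NULL, alpha = 0.05,
                      transform_phenotype = FALSE) {
  burdens <- data.table::as.data.table(burdens)
  if (nrow(burdens) == 0L) stop("no testable genes")
  if (transform_phenotype)
    phenotype <- stats::setNames(inverse_normal_transform(phenotype),
                                 names(phenotype))
  genes <- unique(burdens$gene)
  n_trans <- length(unique(burdens$decile))
  exome_thr <- alpha / (length(genes) * n_trans)
  repl_thr <- alpha / n_trans
  rows <- list()
  for (g in genes) {
    snp <- if (!is.null(snp_covariates)) snp_covariates[[g]]
    for (d in sort(unique(burdens$decile))) {
      sub <- burdens[burdens$gene == g & burdens$decile == d]
      ids <- sub$individual
      y <- phenotype[ids]
      cv <- if (!is.null(covariates))
        covariates[match(ids, rownames(covariates)), , drop = FALSE]
      sn <- if (!is.null(snp)) snp[match(ids, rownames(snp)), , drop = FALSE]
      tst <- burden_test(sub$burden, y, covariates = cv,
                         snp_covariates = sn)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene = g, decile = d, beta = tst$beta, se = tst$se, p = tst$p,
        n = tst$n)
    }
  }
  results <- data.table::rbindlist(rows)
  gtab <- results[, list(min_p = min(p), best_decile = decile[which.min(p)]),
                  by = "gene"]
  gtab$replication_significant <- gtab$min_p < repl_thr
  gtab$exome_wide_significant <- gtab$min_p < exome_thr
  list(results = results[], genes = gtab[],
       exome_threshold = exome_thr, replication_threshold = repl_thr)
}

#' Direct whole-exome-sequencing LoF burden test
#'
#' Same regression framework as [burden_test()], with the burden equal to
#' the per-individual LoF allele count within the gene (a carrier
#' indicator when only carrier lists are available).
#'
#' @param lof_counts named numeric vector of per-individual LoF counts
#'   (or 0/1 carrier indicator).
#' @param phenotype numeric phenotype aligned to `lof_counts`.
#' @param covariates optional covariate data.
#' @return as [burden_test()].
#' @export
wes_lof_burden <- function(lof_counts, phenotype, covariates = NULL) {
  burden_test(lof_counts, phenotype, covariates = covariates)
}

#' Ratio of covariate-residualized variance explained
#'
#' Reporting utility contrasting the indirect (IBD-based) and direct
#' (sequencing-based) burden tests: the ratio of the incremental R2 of
#' each burden after residualizing phenotype and burden on covariates.
#'
#' @param burden_indirect,burden_direct numeric burdens.
#' @param phenotype numeric phenotype.
#' @param covariates optional covariates.
#' @return scalar ratio (indirect / direct), in percent.
#' @export
r2_proportion <- function(burden_indirect, burden_direct, phenotype,
                          covariates = NULL) {
  resid_on <- function(v) {
    if (is.null(covariates)) v - mean(v)
    else stats::resid(stats::lm(v ~ ., data = as.data.frame(covariates)))
  }
  y <- resid_on(phenotype)
  r2 <- function(b) {
    br <- resid_on(b)
    if (stats::sd(br) == 0) return(0)
    stats::cor(y, br)^2
  }
  100 * r2(burden_indirect) / r2(burden_direct)
}

#' Synthesize a hybrid sequenced/non-sequenced cohort for burden testing
#'
#' Generates, for one gene: a sequenced cohort with LoF carriers at
#' `carrier_freq`; IBD-like shared segments from each carrier to a
#' Poisson number of non-sequenced individuals with Beta-distributed
#' quality scores; a latent LoF transmitted with probability
#' `score / 2` (the factor 1/2 reflects phase uncertainty); and a
#' phenotype `beta * latent + covariate effects + N(0, 1)` noise.
#'
#' @param n_seq,n_nonseq cohort sizes.
#' @param beta effect size of the latent LoF (phenotype SD units).
#' @param carrier_freq carrier frequency among sequenced individuals.
#' @param segments_per_carrier Poisson mean of segments per carrier
#'   (default 5).
#' @param seed RNG seed.
#' @param gene gene id (default "GENE1").
#' @return list: `carriers` (gene table for [lof_segments()]), `calls`
#'   (IBD-like segment table), `phenotype` (named), `covariates`
#'   (data.frame, rownames = ids), `latent` (named 0/1),
#'   `sequenced_ids`, `nonsequenced_ids`, `tag_snp` (dosage correlated
#'   with the latent LoF, for SNP-adjustment experiments).
#' @export
synthesize_cohort <- function(n_seq, n_nonseq, beta = 0,
                              carrier_freq = 0.02,
                              segments_per_carrier = 5, seed = NULL,
                              gene = "GENE1") {
  if (n_seq < 1 || n_nonseq < 1) stop("cohort sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  seq_ids <- sprintf("seq%05d", seq_len(n_seq))
  non_ids <- sprintf("non%05d", seq_len(n_nonseq))
  carriers <- seq_ids[stats::runif(n_seq) < carrier_freq]
  if (length(carriers) == 0L) carriers <- seq_ids[1L]
  gene_start <- 5e6; gene_end <- 5.05e6
  calls <- list()
  latent <- stats::setNames(rep(0L, n_nonseq), non_ids)
  for (cr in carriers) {
    n_seg <- stats::rpois(1, segments_per_carrier)
    if (n_seg == 0L) next
    partners <- sample(non_ids, min(n_seg, n_nonseq))
    sc <- stats::rbeta(length(partners), 2, 2)
    calls[[length(calls) + 1L]] <- data.table::data.table(
      ind_a = cr, ind_b = partners,
      start_bp = gene_start - round(stats::runif(length(partners), 0, 4e5)),
      end_bp = gene_end + round(stats::runif(length(partners), 0, 4e5)),
      score = sc)
    transmitted <- stats::runif(length(partners)) < sc / 2
    latent[partners[transmitted]] <- 1L
  }
  calls <- if (length(calls)) data.table::rbindlist(calls) else
    data.table::data.table(ind_a = character(), ind_b = character(),
                           start_bp = numeric(), end_bp = numeric(),
                           score = numeric())
  age <- stats::rnorm(n_nonseq, 55, 8)
  sex <- stats::rbinom(n_nonseq, 1, 0.5)
  covariates <- data.frame(age = age, sex = sex, row.names = non_ids)
  ## tag SNP: exact proxy of latent carriage ("fully tagged"); any
  ## background noise would leave genuine partial signal after
  ## conditioning (b and the burden become dependent given the tag)
  tag <- as.numeric(latent)
  phenotype <- stats::setNames(
    beta * latent + 0.01 * (age - 55) + 0.1 * sex +
      stats::rnorm(n_nonseq), non_ids)
  list(carriers = data.frame(gene = gene, start_bp = gene_start,
                             end_bp = gene_end,
                             carrier_ids = I(list(carriers))),
       calls = calls, phenotype = phenotype, covariates = covariates,
       latent = latent, sequenced_ids = seq_ids,
       nonsequenced_ids = non_ids,
       tag_snp = matrix(tag, ncol = 1,
                        dimnames = list(non_ids, "tag")))
}
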