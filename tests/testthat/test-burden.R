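test_that("lof_segments applies the qualification rules", {
  carriers <- data.frame(gene = "G1", start_bp = 100, end_bp = 200,
                         carrier_ids = I(list(c("s1", "s2"))))
  calls <- data.table::data.table(
    ind_a = c("s1", "s1", "s3", "n2", "s2"),
    ind_b = c("n1", "n2", "n1", "s2", "s1"),
    start_bp = c(150, 300, 120, 100, 150),
    end_bp = c(250, 400, 180, 220, 160),
    score = c(0.8, 0.9, 0.7, 0.6, 0.5))
  seg <- lof_segments(calls, carriers, c("s1", "s2", "s3"),
                      c("n1", "n2"))
  ## row1: carrier-nonseq, overlaps -> yes (0.8)
  ## row2: carrier-nonseq but no overlap -> no
  ## row3: s3 not a carrier -> no
  ## row4: n2-s2 carrier on other side, overlaps -> yes (0.6)
  ## row5: both sequenced -> no
  expect_equal(nrow(seg), 2L)
  expect_setequal(seg$score, c(0.8, 0.6))
  expect_equal(seg$individual[seg$score == 0.6], "n2")
  ## no carriers -> empty
  none <- data.frame(gene = "G1", start_bp = 100, end_bp = 200,
                     carrier_ids = I(list(character())))
  expect_equal(nrow(lof_segments(calls, none, c("s1"), c("n1"))), 0L)
  expect_error(lof_segments(calls, carriers, c("s1", "x"), c("x", "n1")),
               "both cohorts")
})

test_that("burden_vectors builds monotone decile burdens", {
  ## scores 0.1..1.0, one per individual
  seg <- data.table::data.table(
    gene = "G1", individual = sprintf("n%02d", 1:10),
    carrier = "s1", score = seq(0.1, 1, by = 0.1))
  bv <- burden_vectors(seg)
  top <- bv[bv$individual == "n10"]
  expect_equal(top$burden[top$decile == 10], 1.0)
  bot <- bv[bv$individual == "n01"]
  expect_equal(bot$burden[bot$decile == 1], 0.1)
  expect_true(all(bot$burden[bot$decile >= 2] == 0))
  ## monotone in d for every individual
  for (ind in unique(bv$individual)) {
    b <- bv$burden[bv$individual == ind][order(bv$decile[bv$individual == ind])]
    expect_true(all(diff(b) <= 1e-12))
  }
  ## equal scores -> identical burden across deciles
  seg2 <- data.table::data.table(gene = "G1",
                                 individual = c("n1", "n1", "n2"),
                                 carrier = "s1", score = 0.5)
  bv2 <- burden_vectors(seg2)
  n1 <- bv2[bv2$individual == "n1"]
  expect_true(all(n1$burden == 1.0))
  ## monotonicity holds on random inputs
  set.seed(3)
  seg3 <- data.table::data.table(
    gene = sample(c("A", "B"), 60, TRUE),
    individual = sample(sprintf("n%02d", 1:12), 60, TRUE),
    carrier = "s", score = runif(60))
  bv3 <- burden_vectors(seg3)
  mono <- bv3[, list(ok = all(diff(burden[order(decile)]) <= 1e-12)),
              by = c("gene", "individual")]
  expect_true(all(mono$ok))
})

test_that("inverse normal transform hits closed-form quantiles", {
  v <- inverse_normal_transform(c(3, 10))
  expect_equal(sort(v), qnorm(c(0.25, 0.75)), tolerance = 1e-12)
  expect_equal(round(qnorm(0.75), 4), 0.6745)
  ## rank-preserving and reversing
  x <- c(5, 1, 3)
  expect_equal(order(inverse_normal_transform(x)), order(x))
  ## near-normal input stays highly correlated
  set.seed(5)
  z <- rnorm(1000)
  expect_gt(cor(z, inverse_normal_transform(z)), 0.99)
  expect_error(inverse_normal_transform(rep(1, 5)), "identical")
})

test_that("burden_test matches textbook OLS on a hand dataset", {
  ## 6 rows, one covariate; verified against closed-form OLS
  b <- c(0, 1, 2, 3, 4, 5)
  cv <- c(1, 0, 1, 0, 1, 0)
  y <- c(0.2, 1.1, 1.9, 3.3, 4.1, 4.8)
  X <- cbind(1, b, cv)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (6 - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tval <- bh[2] / se
  pval <- 2 * pt(-abs(tval), df = 3)
  got <- burden_test(b, y, covariates = data.frame(cv = cv))
  expect_equal(got$beta, bh[2], tolerance = 1e-12)
  expect_equal(got$se, se, tolerance = 1e-12)
  expect_equal(got$p, pval, tolerance = 1e-12)
  ## perfect fit: p collapses toward zero, beta 1 (R warns about the
  ## unreliable summary, which is the point of the case)
  perfect <- suppressWarnings(burden_test(b, b))
  expect_equal(perfect$beta, 1, tolerance = 1e-9)
  expect_lt(perfect$p, 1e-12)
  ## rank deficiency errors with the collinear column named
  expect_error(burden_test(b, y, covariates = data.frame(dup = b)),
               "collinear.*dup|dup")
})

test_that("burden_test is calibrated under the null", {
  set.seed(7)
  p_vals <- vapply(1:400, function(i) {
    n <- 60
    b <- rpois(n, 1) * runif(n)
    y <- rnorm(n)
    burden_test(b, y)$p
  }, numeric(1))
  ## type-I error at 0.05 within binomial 3 SD
  rate <- mean(p_vals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  ## p-values roughly uniform
  ks <- suppressWarnings(ks.test(p_vals, punif))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene_scan reports the published threshold arithmetic", {
  expect_equal(signif(0.05 / (14249 * 10), 3), 3.51e-7)
  expect_equal(0.05 / 10, 0.005)
  set.seed(8)
  seg <- data.table::data.table(
    gene = rep(c("G1", "G2"), each = 20),
    individual = rep(sprintf("n%02d", 1:20), 2),
    carrier = "s", score = runif(40))
  bv <- burden_vectors(seg)
  pheno <- setNames(rnorm(20), sprintf("n%02d", 1:20))
  gs <- gene_scan(bv, pheno)
  expect_equal(gs$exome_threshold, 0.05 / (2 * 10))
  expect_equal(gs$replication_threshold, 0.005)
  expect_equal(nrow(gs$genes), 2L)
  expect_true(all(gs$genes$min_p <= 1))
  ## single gene, single transformation -> threshold alpha
  bv1 <- bv[bv$gene == "G1" & bv$decile == 1]
  gs1 <- gene_scan(bv1, pheno)
  expect_equal(gs1$exome_threshold, 0.05)
})

test_that("wes burden mirrors burden_test with count burdens", {
  set.seed(9)
  n <- 50
  counts <- rbinom(n, 2, 0.05)
  y <- 0.8 * counts + rnorm(n)
  direct <- wes_lof_burden(counts, y)
  ref <- burden_test(counts, y)
  expect_identical(direct, ref)
  expect_lt(direct$p, 0.05)
})

test_that("synthetic cohorts are reproducible and power behaves", {
  s1 <- synthesize_cohort(200, 500, beta = 0.5, seed = 11)
  s2 <- synthesize_cohort(200, 500, beta = 0.5, seed = 11)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$phenotype, s2$phenotype)
  ## null calibration of the full pipeline at beta = 0
  set.seed(12)
  null_p <- vapply(1:40, function(i) {
    s <- synthesize_cohort(100, 400, beta = 0, seed = 1000 + i)
    seg <- lof_segments(s$calls, s$carriers, s$sequenced_ids,
                        s$nonsequenced_ids)
    if (nrow(seg) == 0) return(NA_real_)
    bv <- burden_vectors(seg, individuals = s$nonsequenced_ids)
    gs <- gene_scan(bv, s$phenotype, covariates = s$covariates)
    gs$genes$min_p[1]
  }, numeric(1))
  ## min over 10 correlated transformations with Bonferroni-10: conservative
  expect_lte(mean(null_p < 0.005, na.rm = TRUE),
             0.05 + 3 * sqrt(0.05 * 0.95 / 40))
  ## strong effect detected at the replication threshold in most seeds
  hits <- vapply(1:15, function(i) {
    s <- synthesize_cohort(1000, 5000, beta = 0.8, carrier_freq = 0.05,
                           segments_per_carrier = 10, seed = 2000 + i)
    seg <- lof_segments(s$calls, s$carriers, s$sequenced_ids,
                        s$nonsequenced_ids)
    if (nrow(seg) == 0) return(FALSE)
    bv <- burden_vectors(seg, individuals = s$nonsequenced_ids)
    gs <- gene_scan(bv, s$phenotype, covariates = s$covariates)
    gs$genes$replication_significant[1]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("a perfect tag SNP covariate removes the burden signal", {
  set.seed(13)
  p_unadj <- c(); p_adj <- c()
  for (i in 1:12) {
    s <- synthesize_cohort(1000, 5000, beta = 0.8, carrier_freq = 0.05,
                           segments_per_carrier = 10, seed = 3000 + i)
    seg <- lof_segments(s$calls, s$carriers, s$sequenced_ids,
                        s$nonsequenced_ids)
    if (nrow(seg) == 0) next
    bv <- burden_vectors(seg, individuals = s$nonsequenced_ids)
    b10 <- bv[bv$decile == 1]
    y <- s$phenotype[b10$individual]
    p_unadj <- c(p_unadj, burden_test(b10$burden, y)$p)
    p_adj <- c(p_adj, burden_test(
      b10$burden, y,
      snp_covariates = s$tag_snp[b10$individual, , drop = FALSE])$p)
  }
  ## unadjusted strongly significant; adjusted reverts toward null
  expect_lt(median(p_unadj), 1e-4)
  expect_gt(median(p_adj), 0.05)
})

test_that("r2_proportion contrasts the two burdens sensibly", {
  set.seed(14)
  n <- 300
  direct <- rbinom(n, 1, 0.1)
  indirect <- direct * rbinom(n, 1, 0.5) + rnorm(n, 0, 0.2)
  y <- direct + rnorm(n)
  r <- r2_proportion(indirect, direct, y)
  expect_gt(r, 0); expect_lt(r, 100)
})
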