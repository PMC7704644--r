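test_that("haplotype_panel enforces its invariants", {
  al <- matrix(c(0, 1, 1, 0, 0, 1, 1, 1), nrow = 4)
  p <- haplotype_panel(al, "1", c(100, 200), c(0.1, 0.2))
  expect_s3_class(p, "haplotype_panel")
  expect_equal(p$sites$derived_freq, c(0.5, 0.75))
  ## monomorphic column rejected
  expect_error(haplotype_panel(cbind(al[, 1], c(1, 1, 1, 1)), "1",
                               c(100, 200), c(0.1, 0.2)), "monomorphic")
  ## decreasing physical positions rejected
  expect_error(haplotype_panel(al, "1", c(200, 100), c(0.1, 0.2)),
               "strictly increasing")
  ## decreasing genetic positions rejected
  expect_error(haplotype_panel(al, "1", c(100, 200), c(0.2, 0.1)),
               "non-decreasing")
  expect_error(haplotype_panel(matrix(c(0, 1, 2, 1), 2), "1", c(1, 2),
                               c(0, 0)), "0/1")
})

test_that("VCF reading builds the expected panel and errors are specific", {
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|0",
           "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
           "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1|1\t0|1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  p <- read_haplotype_panel(f, "vcf")
  expect_equal(n_haplotypes(p), 4L)
  expect_equal(n_sites(p), 3L)
  expect_equal(p$individual_ids, c("s1", "s1", "s2", "s2"))
  expect_equal(unname(p$alleles[, 1]), c(0L, 1L, 1L, 0L))

  ## unphased -> error naming the record
  bad <- vcf; bad[3] <- "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|0"
  writeLines(bad, f)
  expect_error(read_haplotype_panel(f, "vcf"), "unphased.*1:100")
  ## multiallelic -> error
  bad <- vcf; bad[4] <- "1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT\t0|0\t0|1"
  writeLines(bad, f)
  expect_error(read_haplotype_panel(f, "vcf"), "multiallelic")
  ## missing genotype -> error, no imputation
  bad <- vcf; bad[5] <- "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t.|.\t0|1"
  writeLines(bad, f)
  expect_error(read_haplotype_panel(f, "vcf"), "missing genotype")
  ## monomorphic sites are dropped with a message
  mono <- c(vcf, "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t0|0\t0|0")
  writeLines(mono, f)
  expect_message(p2 <- read_haplotype_panel(f, "vcf"), "1 monomorphic")
  expect_equal(n_sites(p2), 3L)
})

test_that("panel round-trips through VCF and haps/sample", {
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|0",
           "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  p <- read_haplotype_panel(f, "vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_haplotype_panel(p, f2, "vcf")
  ## byte-identical modulo the provenance header line
  orig <- readLines(f); rt <- readLines(f2)
  expect_identical(orig[-1], rt[-(1:2)])
  expect_identical(grep("^##source", rt, value = TRUE), "##source=ibdcoal")
  ## and a second round trip is exactly stable
  p2 <- read_haplotype_panel(f2, "vcf")
  expect_identical(p2$alleles, p$alleles)
  expect_identical(p2$sites, p$sites)

  fh <- withr::local_tempfile(fileext = ".haps")
  write_haplotype_panel(p, fh, "hapssample")
  p3 <- read_haplotype_panel(fh, "hapssample")
  expect_identical(p3$alleles, p$alleles)
  expect_equal(p3$individual_ids, p$individual_ids)
})

test_that("genetic map interpolation is exact at anchors and monotone", {
  m <- genetic_map(c(100, 1000, 5000), c(0, 1, 1.5))
  expect_equal(interpolate_cM(m, c(100, 1000, 5000)), c(0, 1, 1.5))
  x <- sort(sample(100:5000, 50))
  g <- interpolate_cM(m, x)
  expect_true(all(diff(g) >= 0))
  expect_equal(m$total_cM, 1.5)
  expect_error(genetic_map(c(100, 50), c(0, 1)), "strictly increasing")
  expect_error(genetic_map(c(100, 200), c(1, 0)), "non-decreasing")
  ## file readers: PLINK and HapMap styles
  fp <- withr::local_tempfile()
  writeLines(c("1 rs1 0.0 100", "1 rs2 1.0 1000"), fp)
  expect_equal(read_genetic_map(fp)$gen_pos, c(0, 1))
  writeLines(c("position rate cM", "100 1.1 0.0", "1000 1.1 1.0"), fp)
  expect_equal(read_genetic_map(fp, "hapmap")$phys_pos, c(100, 1000))
})

test_that("coalescent prior matches closed forms", {
  m <- demographic_model(0, 5000)
  pr <- coalescent_prior(m, c(0, 50, Inf))
  expect_equal(pr$probs[1], 1 - exp(-50 / 5000), tolerance = 1e-12)
  ## degenerate single interval
  pr1 <- coalescent_prior(m, c(0, Inf))
  expect_equal(pr1$probs, 1)
  expect_equal(pr1$representatives, 5000, tolerance = 1e-9)
  ## piecewise model: survival continuous and prior sums to 1
  m2 <- demographic_model(c(0, 100, 500), c(10000, 3000, 1500))
  b <- c(0, 50, 100, 200, 500, 1000, Inf)
  pr2 <- coalescent_prior(m2, b)
  expect_equal(sum(pr2$probs), 1, tolerance = 1e-12)
  expect_true(all(pr2$probs > 0))
  expect_true(all(pr2$representatives > head(b, -1) &
                    pr2$representatives < tail(b, -1)))
  expect_true(all(diff(coalescent_survival(m2, seq(0, 2000, 10))) < 0))
  expect_error(demographic_model(0, -5), "positive")
})

test_that("prior matches an empirical TMRCA histogram from the simulator", {
  m <- demographic_model(c(0, 100), c(2000, 1000))
  disc <- make_quantile_discretization(m, 5)
  set.seed(11)
  n <- 4000
  draws <- vapply(seq_len(n), function(i)
    simulate_pair_path(0.5, m)$tmrca[1], numeric(1))
  emp <- as.numeric(table(cut(draws, disc$boundaries,
                              include.lowest = TRUE))) / n
  mc_sd <- sqrt(disc$probs * (1 - disc$probs) / n)
  expect_true(all(abs(emp - disc$probs) < 3 * mc_sd + 1e-9))
})

test_that("quantile discretization honors pins and equal masses", {
  m <- demographic_model(0, 4000)
  d <- make_quantile_discretization(m, 2)
  expect_equal(d$boundaries[2], 4000 * log(2), tolerance = 1e-9)
  d2 <- make_quantile_discretization(m, 10, pinned = 50)
  expect_true(50 %in% d2$boundaries)
  d3 <- make_quantile_discretization(m, 8)
  expect_true(all(abs(d3$probs - 1 / 8) < 1e-9))
  expect_error(make_quantile_discretization(m, 1), "K")
  expect_error(make_quantile_discretization(m, 5, pinned = -1), "> 0")
  ## piecewise model quantiles still exact
  m2 <- demographic_model(c(0, 200), c(8000, 1000))
  d4 <- make_quantile_discretization(m2, 12)
  expect_true(all(abs(d4$probs - 1 / 12) < 1e-9))
})

test_that("partition_jobs covers every pair exactly once", {
  jobs <- partition_jobs(4, 3)  # S = 2
  pairs <- do.call(rbind, lapply(jobs, job_pairs))
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  expect_equal(sort(key),
               sort(apply(t(combn(4, 2)), 1, paste, collapse = " ")))
  ## degenerate single job
  j1 <- partition_jobs(5, 1)
  expect_length(j1, 1)
  expect_equal(nrow(job_pairs(j1[[1]])), choose(5, 2))
  ## non-triangular K errors and names nearest valid values
  expect_error(partition_jobs(10, 4), "nearest valid K: 3 or 6")
  ## exhaustive coverage for a grid of n and all valid K
  for (n in c(7, 12, 25, 50)) {
    for (S in 1:4) {
      K <- S * (S + 1) / 2
      jobs <- partition_jobs(n, K)
      sets <- lapply(jobs, function(j) unique(c(j$set_a, j$set_b)))
      sizes <- lengths(unique(lapply(jobs, `[[`, "set_a")))
      expect_lte(diff(range(sizes)), 1)
      pairs <- do.call(rbind, lapply(jobs, job_pairs))
      key <- paste(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
      expect_equal(length(key), choose(n, 2))
      expect_equal(anyDuplicated(key), 0L)
    }
  }
})

test_that("demography and discretization files round-trip", {
  m <- demographic_model(c(0, 300), c(10000, 2500))
  f <- withr::local_tempfile()
  write_demography(m, f)
  m2 <- read_demography(f)
  expect_equal(m2$start, m$start)
  expect_equal(m2$ne, m$ne)
  fd <- withr::local_tempfile()
  writeLines(c("50", "100", "400"), fd)
  d <- read_discretization(m, fd)
  expect_equal(d$boundaries, c(0, 50, 100, 400, Inf))
})
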