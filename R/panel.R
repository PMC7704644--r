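#' Phased haplotype panel
#'
#' The central container for phased biallelic data: an
#' `n_haplotypes x n_sites` matrix of 0/1 alleles plus per-site metadata
#' (chromosome, physical position in bp, genetic position in cM, derived
#' allele frequency). Haplotypes are identified by an individual id plus a
#' haplotype index (0/1 for diploid sources, 0 for haploid data).
#'
#' Invariants enforced: physical positions strictly increasing within the
#' chromosome; genetic positions non-decreasing; every retained site
#' polymorphic (0 < derived frequency < 1). Monomorphic sites must be
#' dropped by the caller (readers do this and report the count).
#'
#' @param alleles integer matrix of 0/1, haplotypes in rows, sites in
#'   columns.
#' @param chrom chromosome label (single value or per-site vector).
#' @param phys_pos per-site physical positions (bp, 1-based).
#' @param gen_pos per-site genetic positions (cM).
#' @param individual_ids per-haplotype individual ids.
#' @param hap_index per-haplotype haplotype index (0/1); defaults to
#'   alternating 0/1 when ids come in diploid pairs, else all 0.
#' @param id,ref,alt optional per-site variant id and REF/ALT alleles,
#'   preserved on round-trips through VCF.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, chrom, phys_pos, gen_pos,
                            individual_ids = NULL, hap_index = NULL,
                            id = NULL, ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_hap <- nrow(alleles); n_sites <- ncol(alleles)
  if (n_sites < 1L || n_hap < 2L)
    stop("panel needs >= 2 haplotypes and >= 1 site")
  if (any(is.na(alleles)) || !all(alleles %in% c(0L, 1L)))
    stop("alleles must be 0/1 with no missing values")
  if (length(phys_pos) != n_sites || length(gen_pos) != n_sites)
    stop("site coordinate vectors must match the number of allele columns")
  if (is.unsorted(phys_pos, strictly = TRUE))
    stop("phys_pos must be strictly increasing")
  if (is.unsorted(gen_pos))
    stop("gen_pos must be non-decreasing")
  freq <- colMeans(alleles)
  if (any(freq <= 0 | freq >= 1))
    stop("monomorphic site(s) at column(s): ",
         paste(utils::head(which(freq <= 0 | freq >= 1), 5), collapse = ", "),
         "; drop them before constructing the panel")
  if (is.null(individual_ids))
    individual_ids <- sprintf("hap%d", seq_len(n_hap))
  if (is.null(hap_index)) {
    dup <- anyDuplicated(individual_ids) > 0L
    hap_index <- if (dup) rep_len(c(0L, 1L), n_hap) else rep(0L, n_hap)
  }
  if (length(individual_ids) != n_hap || length(hap_index) != n_hap)
    stop("haplotype id vectors must match the number of allele rows")
  sites <- data.frame(
    chrom = rep_len(as.character(chrom), n_sites),
    phys_pos = as.numeric(phys_pos),
    gen_pos = as.numeric(gen_pos),
    derived_freq = freq,
    id = rep_len(if (is.null(id)) "." else as.character(id), n_sites),
    ref = rep_len(if (is.null(ref)) "A" else as.character(ref), n_sites),
    alt = rep_len(if (is.null(alt)) "G" else as.character(alt), n_sites),
    stringsAsFactors = FALSE
  )
  structure(list(alleles = alleles, sites = sites,
                 individual_ids = as.character(individual_ids),
                 hap_index = as.integer(hap_index)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites\n")
  cat("  chrom", x$sites$chrom[1L], ", span",
      sprintf("%.0f-%.0f bp (%.3f-%.3f cM)\n",
              min(x$sites$phys_pos), max(x$sites$phys_pos),
              min(x$sites$gen_pos), max(x$sites$gen_pos)))
  invisible(x)
}

#' @rdname haplotype_panel
#' @param x a `haplotype_panel`.
#' @export
n_haplotypes <- function(x) nrow(x$alleles)

#' @rdname haplotype_panel
#' @export
n_sites <- function(x) ncol(x$alleles)

#' Haplotype display labels (`individual_hapindex`)
#' @param panel a [haplotype_panel()].
#' @return character vector of labels.
#' @export
haplotype_labels <- function(panel) {
  paste0(panel$individual_ids, "_", panel$hap_index)
}
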