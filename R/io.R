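#' Read a phased haplotype panel
#'
#' Reads phased biallelic haplotypes from a plain-text VCF (phased `GT`
#' with `|` separators) or an Oxford haps/sample pair. Monomorphic sites
#' are dropped (the count is reported with a message); unphased, missing
#' or multiallelic genotypes are errors, never imputed.
#'
#' @param path file path; for `format = "hapssample"` the `.haps` file
#'   (a `.sample` file with the same stem, or `sample_path`, supplies ids).
#' @param format `"vcf"` or `"hapssample"`.
#' @param map optional [genetic_map()] used to assign genetic positions;
#'   when `NULL` a uniform 1 cM/Mb map is assumed.
#' @param sample_path optional explicit path to the Oxford sample file.
#' @return a [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path, format = c("vcf", "hapssample"),
                                 map = NULL, sample_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "vcf") .read_vcf_panel(path, map)
  else .read_haps_panel(path, map, sample_path)
}

.assign_gen_pos <- function(phys_pos, map) {
  if (is.null(map)) (phys_pos - 1) / 1e6 else interpolate_cM(map, phys_pos)
}

.read_vcf_panel <- function(path, map) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("no #CHROM header line in VCF: ", path)
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 10L) stop("VCF has no sample columns: ", path)
  samples <- header[-(1:9)]
  recs <- lines[-seq_len(hdr)]
  recs <- recs[nzchar(recs)]
  if (length(recs) == 0L) stop("VCF has no variant records: ", path)
  fields <- strsplit(recs, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stop("malformed VCF record at line ", hdr + which(nf != length(header))[1L])
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  chrom <- m[, 1L]; pos <- as.numeric(m[, 2L]); vid <- m[, 3L]
  ref <- m[, 4L]; alt <- m[, 5L]
  bad_alt <- grepl(",", alt, fixed = TRUE)
  if (any(bad_alt))
    stop("multiallelic record at ", chrom[bad_alt][1L], ":",
         pos[bad_alt][1L], " (ALT = ", alt[bad_alt][1L], ")")
  gt_idx <- vapply(strsplit(m[, 9L], ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (any(is.na(gt_idx))) stop("FORMAT without GT field")
  gts <- m[, -(1:9), drop = FALSE]
  if (any(gt_idx != 1L)) {
    pick <- function(x, i) vapply(strsplit(x, ":", fixed = TRUE), `[`, "", i)
    for (r in which(gt_idx != 1L)) gts[r, ] <- pick(gts[r, ], gt_idx[r])
  }
  unphased <- matrix(grepl("/", gts, fixed = TRUE), nrow = nrow(gts))
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1L, ]
    stop("unphased genotype '", gts[w[1L], w[2L]], "' for sample ",
         samples[w[2L]], " at record ", chrom[w[1L]], ":", pos[w[1L]],
         "; phased '|' genotypes are required")
  }
  missing <- matrix(grepl(".", gts, fixed = TRUE), nrow = nrow(gts))
  if (any(missing)) {
    w <- which(missing, arr.ind = TRUE)[1L, ]
    stop("missing genotype for sample ", samples[w[2L]], " at record ",
         chrom[w[1L]], ":", pos[w[1L]], "; no imputation is performed")
  }
  sp <- strsplit(gts, "|", fixed = TRUE)
  if (any(lengths(sp) != 2L)) stop("genotypes must be diploid 'a|b'")
  al <- suppressWarnings(as.integer(unlist(sp)))
  if (any(is.na(al)) || any(al > 1L))
    stop("genotype alleles must be 0 or 1 (biallelic)")
  ## gts is n_rec x n_sample (column-major): unlist order is site-major per
  ## column; rebuild as haplotype rows.
  n_rec <- length(recs); n_s <- length(samples)
  alleles <- matrix(0L, nrow = 2L * n_s, ncol = n_rec)
  al <- matrix(al, nrow = 2L)  # 2 x (n_rec * n_s), sample-major blocks
  for (s in seq_len(n_s)) {
    cols <- ((s - 1L) * n_rec + 1L):(s * n_rec)
    alleles[2L * s - 1L, ] <- al[1L, cols]
    alleles[2L * s, ] <- al[2L, cols]
  }
  keep <- colMeans(alleles) > 0 & colMeans(alleles) < 1
  if (any(!keep))
    message("dropped ", sum(!keep), " monomorphic site(s)")
  if (!any(keep)) stop("no polymorphic sites remain")
  haplotype_panel(alleles[, keep, drop = FALSE], chrom = chrom[keep],
                  phys_pos = pos[keep],
                  gen_pos = .assign_gen_pos(pos[keep], map),
                  individual_ids = rep(samples, each = 2L),
                  hap_index = rep_len(c(0L, 1L), 2L * n_s),
                  id = vid[keep], ref = ref[keep], alt = alt[keep])
}

.read_haps_panel <- function(path, map, sample_path) {
  if (is.null(sample_path))
    sample_path <- sub("\\.haps(\\.gz)?$", ".sample", path)
  dt <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(dt) < 7L) stop("haps file needs >= 7 columns")
  meta <- dt[, 1:5]
  alleles <- t(as.matrix(dt[, -(1:5), drop = FALSE]))
  dimnames(alleles) <- NULL
  if (any(is.na(alleles)) || !all(alleles %in% c(0, 1)))
    stop("haps alleles must be 0/1 with no missing values")
  n_hap <- nrow(alleles)
  if (file.exists(sample_path)) {
    sm <- utils::read.table(sample_path, header = TRUE,
                            stringsAsFactors = FALSE)
    sm <- sm[-1L, , drop = FALSE]  # Oxford type row
    ids <- rep(as.character(sm[[1L]]), each = 2L)
    if (length(ids) != n_hap)
      stop("sample file lists ", length(ids) / 2L,
           " individuals but haps has ", n_hap, " haplotype columns")
  } else {
    ids <- rep(sprintf("ind%d", seq_len(n_hap / 2L)), each = 2L)
  }
  keep <- colMeans(alleles) > 0 & colMeans(alleles) < 1
  if (any(!keep)) message("dropped ", sum(!keep), " monomorphic site(s)")
  if (!any(keep)) stop("no polymorphic sites remain")
  pos <- as.numeric(meta[[3L]])
  haplotype_panel(alleles[, keep, drop = FALSE], chrom = meta[[1L]][keep],
                  phys_pos = pos[keep],
                  gen_pos = .assign_gen_pos(pos[keep], map),
                  individual_ids = ids,
                  hap_index = rep_len(c(0L, 1L), n_hap),
                  id = meta[[2L]][keep], ref = meta[[4L]][keep],
                  alt = meta[[5L]][keep])
}

#' Write a haplotype panel
#'
#' Writing then re-reading reproduces the panel exactly; a VCF written by
#' this function re-read and re-written is byte-identical apart from the
#' provenance header line.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (`.haps` stem for Oxford format; the `.sample`
#'   companion is written next to it).
#' @param format `"vcf"` or `"hapssample"`.
#' @return `path`, invisibly.
#' @export
write_haplotype_panel <- function(panel, path,
                                  format = c("vcf", "hapssample")) {
  format <- match.arg(format)
  st <- panel$sites
  if (format == "vcf") {
    if (n_haplotypes(panel) %% 2L != 0L)
      stop("VCF output requires an even number of haplotypes")
    samples <- panel$individual_ids[seq(1L, n_haplotypes(panel), by = 2L)]
    gt <- matrix("", nrow = n_sites(panel), ncol = length(samples))
    for (s in seq_along(samples)) {
      gt[, s] <- paste0(panel$alleles[2L * s - 1L, ], "|",
                        panel$alleles[2L * s, ])
    }
    body <- cbind(st$chrom, format(st$phys_pos, scientific = FALSE,
                                   trim = TRUE),
                  st$id, st$ref, st$alt, ".", "PASS", ".", "GT", gt)
    lines <- c("##fileformat=VCFv4.2",
               "##source=ibdcoal",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               apply(body, 1L, paste, collapse = "\t"))
    writeLines(lines, path)
  } else {
    body <- cbind(st$chrom, st$id,
                  format(st$phys_pos, scientific = FALSE, trim = TRUE),
                  st$ref, st$alt, t(panel$alleles))
    writeLines(apply(body, 1L, paste, collapse = " "), path)
    sample_path <- sub("\\.haps$", ".sample", path)
    if (sample_path == path) sample_path <- paste0(path, ".sample")
    ids <- panel$individual_ids[seq(1L, n_haplotypes(panel), by = 2L)]
    writeLines(c("ID_1 ID_2 missing", "0 0 0",
                 paste(ids, ids, "0")), sample_path)
  }
  invisible(path)
}

#' Write an IBD segment table
#'
#' Fixed file contract: tab-separated with header, scores printed with 4
#' decimals and age estimates with 2.
#'
#' @param segments a data.frame/data.table of verified IBD segments as
#'   produced by [detect_ibd()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ibd <- function(segments, path) {
  seg <- data.table::as.data.table(segments)
  out <- data.table::data.table(
    ind_a = seg$ind_a, hap_a = seg$hap_a,
    ind_b = seg$ind_b, hap_b = seg$hap_b,
    chrom = seg$chrom,
    start_bp = format(seg$start_bp, scientific = FALSE, trim = TRUE),
    end_bp = format(seg$end_bp, scientific = FALSE, trim = TRUE),
    length_cM = sprintf("%.6f", seg$length_cM),
    score = sprintf("%.4f", seg$score),
    age_est = sprintf("%.2f", seg$age_est),
    n_mismatch_windows = seg$n_mismatch_windows
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an IBD segment table written by [write_ibd()]
#' @param path file path.
#' @return a `data.table` of segments.
#' @export
read_ibd <- function(path) {
  if (!file.exists(path)) stop("IBD file not found: ", path)
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("ind_a", "ind_b", "chrom")))
}
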