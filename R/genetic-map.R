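#' Genetic map with piecewise-linear interpolation
#'
#' Maps physical positions (bp, 1-based) to genetic positions (cM).
#' Interpolation is piecewise linear between anchors; positions outside the
#' anchor range are extrapolated with the flanking segment's rate (clamped
#' to constant beyond a single anchor).
#'
#' @param phys_pos integer-like vector of physical positions (bp), strictly
#'   increasing.
#' @param gen_pos numeric vector of genetic positions (cM), non-decreasing.
#' @return object of class `genetic_map` with fields `phys_pos`, `gen_pos`,
#'   `total_cM`.
#' @export
genetic_map <- function(phys_pos, gen_pos) {
  phys_pos <- as.numeric(phys_pos)
  gen_pos <- as.numeric(gen_pos)
  if (length(phys_pos) != length(gen_pos) || length(phys_pos) < 1L)
    stop("phys_pos and gen_pos must have equal, positive length")
  if (is.unsorted(phys_pos, strictly = TRUE))
    stop("phys_pos must be strictly increasing")
  if (is.unsorted(gen_pos))
    stop("gen_pos must be non-decreasing")
  structure(list(phys_pos = phys_pos, gen_pos = gen_pos,
                 total_cM = gen_pos[length(gen_pos)] - gen_pos[1L]),
            class = "genetic_map")
}

#' Uniform-rate genetic map
#'
#' @param length_bp chromosome length in bp.
#' @param cM_per_Mb constant recombination rate (default 1 cM/Mb).
#' @return a [genetic_map()].
#' @export
uniform_genetic_map <- function(length_bp, cM_per_Mb = 1) {
  genetic_map(c(1, length_bp), c(0, (length_bp - 1) * cM_per_Mb / 1e6))
}

#' Interpolate genetic position
#'
#' @param map a [genetic_map()].
#' @param phys_pos physical positions (bp).
#' @return genetic positions (cM); exact at anchors, monotone in `phys_pos`.
#' @export
interpolate_cM <- function(map, phys_pos) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(map$phys_pos) == 1L)
    return(rep(map$gen_pos, length(phys_pos)))
  stats::approx(map$phys_pos, map$gen_pos, xout = phys_pos,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Interpolate physical position from genetic position
#'
#' Inverse lookup of [interpolate_cM()]. Where the map is flat in cM the
#' left-most physical position is returned.
#'
#' @param map a [genetic_map()].
#' @param gen_pos genetic positions (cM).
#' @return physical positions (bp).
#' @export
interpolate_bp <- function(map, gen_pos) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(map$phys_pos) == 1L)
    return(rep(map$phys_pos, length(gen_pos)))
  stats::approx(map$gen_pos, map$phys_pos, xout = gen_pos,
                method = "linear", rule = 2, ties = min)$y
}

#' Read a genetic map file
#'
#' Accepts PLINK-style maps (4 whitespace-separated columns: chrom, id,
#' genetic position in cM, physical position in bp) and HapMap-style maps
#' (3 columns: position, rate in cM/Mb, cumulative cM, with an optional
#' header line).
#'
#' @param path file path.
#' @param format `"plink"`, `"hapmap"`, or `"auto"` (sniff by column count).
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, format = c("auto", "plink", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("map file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]{2,}", first) && !grepl("^\\s*(chr)?[0-9XY]+\\s", first)
  dt <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (format == "auto") format <- if (ncol(dt) >= 4L) "plink" else "hapmap"
  if (format == "plink") {
    if (ncol(dt) < 4L) stop("PLINK map needs 4 columns (chrom id cM bp)")
    genetic_map(dt[[4L]], dt[[3L]])
  } else {
    if (ncol(dt) < 3L) stop("HapMap map needs 3 columns (pos rate cM)")
    genetic_map(dt[[1L]], dt[[3L]])
  }
}

#' Read a demographic model file
#'
#' Two whitespace-delimited columns: epoch start generation and Ne
#' (pairwise-coalescent scale, see [demographic_model()]); `#` comments.
#'
#' @param path file path.
#' @return a [demographic_model()].
#' @export
read_demography <- function(path) {
  if (!file.exists(path)) stop("demography file not found: ", path)
  dt <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(dt) < 2L) stop("demography file needs 2 columns (generation Ne)")
  demographic_model(dt[[1L]], dt[[2L]])
}

#' Write a demographic model file
#' @param model a [demographic_model()].
#' @param path output path.
#' @export
write_demography <- function(model, path) {
  lines <- c("# generation_start Ne (pairwise coalescence rate 1/Ne per generation)",
             sprintf("%g %g", model$start, model$ne))
  writeLines(lines, path)
  invisible(path)
}

#' Read a time-discretization file (one boundary per line)
#' @param model a [demographic_model()] for priors/representatives.
#' @param path file path; `0` and `Inf` are added if absent.
#' @return a `time_discretization`.
#' @export
read_discretization <- function(model, path) {
  if (!file.exists(path)) stop("discretization file not found: ", path)
  b <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  time_discretization(model, b)
}
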