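#' Genetic map with per-chromosome bp/cM anchors
#'
#' A `genome_map` stores, per chromosome, a table of anchor points pairing a
#' physical position (bp) with a cumulative genetic position (cM). All genetic
#' length arithmetic in the package (tract lengths, the 0.6 cM gap rule, the
#' 2 cM IBD threshold) is interpolated through this object.
#'
#' @param anchors A data frame with columns `chrom`, `bp`, `cm`. Within each
#'   chromosome `bp` must be strictly increasing and `cm` non-decreasing,
#'   with at least two anchors.
#' @return An object of class `genome_map`: a named list of per-chromosome
#'   anchor data frames.
#' @examples
#' gm <- genome_map(data.frame(chrom = "1", bp = c(0, 1e6), cm = c(0, 1)))
#' interpolate_cm(gm, "1", 5e5)
#' @export
genome_map <- function(anchors) {
  stopifnot(is.data.frame(anchors))
  need <- c("chrom", "bp", "cm")
  if (!all(need %in% names(anchors))) {
    stop("`anchors` must have columns chrom, bp, cm")
  }
  anchors$chrom <- as.character(anchors$chrom)
  by_chrom <- split(anchors[, c("bp", "cm")], anchors$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$bp), , drop = FALSE]
    rownames(d) <- NULL
    if (nrow(d) < 2L) stop("each chromosome needs at least 2 anchors")
    if (any(diff(d$bp) <= 0)) stop("bp anchors must be strictly increasing")
    if (any(diff(d$cm) < 0)) stop("cM anchors must be non-decreasing")
    d
  })
  structure(by_chrom, class = "genome_map")
}

#' Build a uniform-rate genetic map
#'
#' Convenience constructor for simulated genomes: each chromosome gets two
#' anchors at a constant recombination rate.
#'
#' @param chrom_cm Named numeric vector of chromosome genetic lengths (cM).
#' @param rate_cm_per_mb Constant rate used to place the physical end
#'   (default 1 cM/Mb).
#' @return A `genome_map`.
#' @export
uniform_genome_map <- function(chrom_cm, rate_cm_per_mb = 1) {
  stopifnot(is.numeric(chrom_cm), length(chrom_cm) >= 1L, all(chrom_cm > 0))
  if (is.null(names(chrom_cm))) names(chrom_cm) <- as.character(seq_along(chrom_cm))
  anchors <- do.call(rbind, lapply(names(chrom_cm), function(cn) {
    data.frame(chrom = cn,
               bp = c(0, chrom_cm[[cn]] / rate_cm_per_mb * 1e6),
               cm = c(0, chrom_cm[[cn]]))
  }))
  genome_map(anchors)
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosome(s), total %.1f cM / %.1f Mb\n",
              length(x), sum(chrom_lengths_cm(x)),
              sum(chrom_lengths_bp(x)) / 1e6))
  invisible(x)
}

#' Chromosome names of a genome map
#' @param map A `genome_map`.
#' @return Character vector.
#' @export
map_chroms <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  names(map)
}

#' Chromosome genetic lengths (cM)
#' @param map A `genome_map`.
#' @return Named numeric vector of genetic spans per chromosome.
#' @export
chrom_lengths_cm <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  vapply(map, function(d) d$cm[nrow(d)] - d$cm[1L], numeric(1))
}

#' Chromosome physical lengths (bp)
#' @param map A `genome_map`.
#' @return Named numeric vector of physical spans per chromosome.
#' @export
chrom_lengths_bp <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  vapply(map, function(d) d$bp[nrow(d)] - d$bp[1L], numeric(1))
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Piecewise-linear interpolation between the flanking anchors. Positions
#' outside the anchored range are clamped to the first/last anchor with a
#' warning; the map is never extrapolated.
#'
#' @param map A `genome_map`.
#' @param chrom Chromosome name (scalar).
#' @param bp Numeric vector of physical positions.
#' @return Numeric vector of genetic positions (cM).
#' @export
interpolate_cm <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genome_map"))
  chrom <- as.character(chrom)
  d <- map[[chrom]]
  if (is.null(d)) stop(sprintf("chromosome '%s' not in map", chrom))
  lo <- d$bp[1L]
  hi <- d$bp[nrow(d)]
  if (any(bp < lo | bp > hi, na.rm = TRUE)) {
    warning(sprintf("position(s) outside anchors on chromosome %s clamped to [%g, %g]",
                    chrom, lo, hi))
    bp <- pmin(pmax(bp, lo), hi)
  }
  stats::approx(d$bp, d$cm, xout = bp, method = "linear", ties = "ordered")$y
}

#' Interpolate physical position (bp) at genetic positions
#'
#' Inverse lookup of [interpolate_cm()]; requires strictly increasing cM
#' anchors on the queried chromosome (no zero-recombination plateaus).
#'
#' @param map A `genome_map`.
#' @param chrom Chromosome name (scalar).
#' @param cm Numeric vector of genetic positions (cM).
#' @return Numeric vector of physical positions (bp).
#' @export
interpolate_bp <- function(map, chrom, cm) {
  stopifnot(inherits(map, "genome_map"))
  chrom <- as.character(chrom)
  d <- map[[chrom]]
  if (is.null(d)) stop(sprintf("chromosome '%s' not in map", chrom))
  if (any(diff(d$cm) <= 0)) {
    stop("inverse interpolation requires strictly increasing cM anchors")
  }
  lo <- d$cm[1L]
  hi <- d$cm[nrow(d)]
  if (any(cm < lo | cm > hi, na.rm = TRUE)) {
    warning(sprintf("genetic position(s) outside anchors on chromosome %s clamped", chrom))
    cm <- pmin(pmax(cm, lo), hi)
  }
  stats::approx(d$cm, d$bp, xout = cm, method = "linear", ties = "ordered")$y
}

#' Genetic length of a physical interval
#'
#' @param map A `genome_map`.
#' @param chrom Chromosome name (scalar).
#' @param start,end Physical interval bounds (0-based half-open), vectors.
#' @return Genetic lengths in cM.
#' @export
interval_cm <- function(map, chrom, start, end) {
  interpolate_cm(map, chrom, end) - interpolate_cm(map, chrom, start)
}

#' Read a genetic map file
#'
#' Supports the 4-column map format (`chrom id cm bp`, no header) and the
#' HapMap-style format (`chrom bp rate cm`, with header).
#'
#' @param path File path.
#' @param format One of `"map4"` or `"hapmap"`.
#' @return A `genome_map`.
#' @export
read_genetic_map <- function(path, format = c("map4", "hapmap")) {
  format <- match.arg(format)
  if (format == "map4") {
    d <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "id", "cm", "bp"),
                           colClasses = c("character", "character", "numeric", "numeric"))
    genome_map(data.frame(chrom = d$chrom, bp = d$bp, cm = d$cm))
  } else {
    d <- utils::read.table(path, header = TRUE, sep = "\t")
    names(d) <- tolower(names(d))
    genome_map(data.frame(chrom = as.character(d[[1L]]), bp = d[[2L]], cm = d[[4L]]))
  }
}

#' Write a genetic map in 4-column format
#'
#' @param map A `genome_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genome_map"))
  rows <- do.call(rbind, lapply(names(map), function(cn) {
    d <- map[[cn]]
    data.frame(chrom = cn, id = sprintf("%s_%d", cn, seq_len(nrow(d))),
               cm = d$cm, bp = d$bp)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
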