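#' Haplotype-level local-ancestry tracts
#'
#' Labelled intervals assigning each stretch of each haplotype to one
#' ancestral source population. Coordinates are 0-based half-open; per
#' haplotype the tracts must partition every chromosome exactly (no gaps,
#' no overlaps). This is the substrate for every ancestry-specific
#' computation in the package.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `individual`,
#'   `haplotype` (0 or 1), `ancestry`.
#' @return An object of class `ancestry_tracts` (a validated data frame).
#' @export
ancestry_tracts <- function(df) {
  need <- c("chrom", "start", "end", "individual", "haplotype", "ancestry")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop("tracts need columns chrom, start, end, individual, haplotype, ancestry")
  }
  df <- df[, need]
  df$chrom <- as.character(df$chrom)
  df$individual <- as.character(df$individual)
  df$haplotype <- as.integer(df$haplotype)
  df$ancestry <- as.character(df$ancestry)
  if (!all(df$haplotype %in% c(0L, 1L))) stop("haplotype must be 0 or 1")
  if (any(df$start >= df$end)) stop("tract start must be < end")
  df <- df[order(df$individual, df$haplotype, df$chrom, df$start), ]
  rownames(df) <- NULL
  class(df) <- c("ancestry_tracts", "data.frame")
  df
}

#' Check that tracts partition each chromosome of a genome map
#'
#' @param tracts An `ancestry_tracts` object.
#' @param map A `genome_map`; each haplotype present must tile every map
#'   chromosome from first to last anchor exactly.
#' @return `TRUE` invisibly; errors describing the first violation otherwise.
#' @export
validate_tracts <- function(tracts, map) {
  stopifnot(inherits(tracts, "ancestry_tracts"), inherits(map, "genome_map"))
  key <- interaction(tracts$individual, tracts$haplotype, drop = TRUE)
  for (k in levels(key)) {
    sub <- tracts[key == k, , drop = FALSE]
    for (cn in map_chroms(map)) {
      d <- map[[cn]]
      cs <- sub[sub$chrom == cn, , drop = FALSE]
      if (nrow(cs) == 0L) stop(sprintf("haplotype %s missing chromosome %s", k, cn))
      cs <- cs[order(cs$start), ]
      if (cs$start[1L] != d$bp[1L] || cs$end[nrow(cs)] != d$bp[nrow(d)]) {
        stop(sprintf("haplotype %s does not span chromosome %s", k, cn))
      }
      if (nrow(cs) > 1L && any(cs$start[-1L] != cs$end[-nrow(cs)])) {
        stop(sprintf("haplotype %s has gaps/overlaps on chromosome %s", k, cn))
      }
    }
  }
  invisible(TRUE)
}

# Interval matrix (start, end) of one haplotype on one chromosome,
# optionally restricted to a single ancestry label.
haplotype_intervals <- function(tracts, individual, haplotype, chrom,
                                ancestry = NULL) {
  sel <- tracts$individual == individual & tracts$haplotype == haplotype &
    tracts$chrom == chrom
  if (!is.null(ancestry)) sel <- sel & tracts$ancestry == ancestry
  sub <- tracts[sel, , drop = FALSE]
  sub <- sub[order(sub$start), , drop = FALSE]
  cbind(start = sub$start, end = sub$end)
}

#' Per-individual global ancestry proportions from tracts
#'
#' Genetic-length-weighted fraction of each individual's two haplotypes
#' carrying each ancestry label.
#'
#' @param tracts An `ancestry_tracts` object.
#' @param map A `genome_map`.
#' @return Matrix (individuals x ancestries) of fractions summing to 1 by row.
#' @export
tract_ancestry_proportions <- function(tracts, map) {
  stopifnot(inherits(tracts, "ancestry_tracts"))
  len <- numeric(nrow(tracts))
  for (cn in unique(tracts$chrom)) {
    idx <- which(tracts$chrom == cn)
    len[idx] <- interval_cm(map, cn, tracts$start[idx], tracts$end[idx])
  }
  tab <- tapply(len, list(tracts$individual, tracts$ancestry), sum, default = 0)
  sweep(tab, 1L, rowSums(tab), "/")
}

#' Read/write ancestry tracts as BED-like TSV
#'
#' Columns: chrom, start, end, individual, haplotype, ancestry (with header);
#' 0-based half-open coordinates.
#'
#' @param path File path.
#' @return For `read_tracts`, an `ancestry_tracts`.
#' @export
read_tracts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "integer", "character"))
  ancestry_tracts(d)
}

#' @rdname read_tracts
#' @param tracts An `ancestry_tracts` object.
#' @export
write_tracts <- function(tracts, path) {
  stopifnot(inherits(tracts, "ancestry_tracts"))
  utils::write.table(as.data.frame(tracts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
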