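#' Genomic segment tables (ROH and IBD)
#'
#' A segment is a half-open genomic interval attached either to one
#' individual (a run of homozygosity) or to an ordered pair of haplotype ids
#' (an IBD segment; haplotype ids are `"individual|0"` / `"individual|1"`).
#' `segment_table()` validates the frame and [add_segment_lengths()] attaches
#' physical and map-interpolated genetic lengths.
#'
#' @param df Data frame with columns `chrom`, `start`, `end` and either
#'   `individual` (ROH) or `hap1`, `hap2` (IBD).
#' @param type `"roh"` or `"ibd"`.
#' @return A `segment_table` data frame with a `type` attribute.
#' @export
segment_table <- function(df, type = c("roh", "ibd")) {
  type <- match.arg(type)
  need <- c("chrom", "start", "end",
            if (type == "roh") "individual" else c("hap1", "hap2"))
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop(sprintf("%s segments need columns %s", type, paste(need, collapse = ", ")))
  }
  keep <- c(need, intersect(c("length_bp", "length_cm", "ancestry"), names(df)))
  df <- df[, keep, drop = FALSE]
  df$chrom <- as.character(df$chrom)
  if (nrow(df) && any(df$start >= df$end)) stop("segment start must be < end")
  rownames(df) <- NULL
  structure(df, class = c("segment_table", "data.frame"), type = type)
}

#' @rdname segment_table
#' @param segments A `segment_table`.
#' @param map A `genome_map` used for genetic lengths.
#' @export
add_segment_lengths <- function(segments, map) {
  stopifnot(inherits(segments, "segment_table"), inherits(map, "genome_map"))
  segments$length_bp <- segments$end - segments$start
  segments$length_cm <- rep(NA_real_, nrow(segments))
  for (cn in unique(segments$chrom)) {
    idx <- which(segments$chrom == cn)
    segments$length_cm[idx] <-
      interval_cm(map, cn, segments$start[idx], segments$end[idx])
  }
  segments
}

# Individual id carried by each haplotype id "ind|h".
hap_individual <- function(hap_id) sub("\\|[01]$", "", hap_id)

# Haplotype index (0/1) of a haplotype id.
hap_index <- function(hap_id) as.integer(sub("^.*\\|", "", hap_id))

#' Read/write segment tables as TSV
#'
#' ROH columns: chrom, start, end, individual; IBD columns: chrom, start,
#' end, hap1, hap2; plus optional length_bp, length_cm, ancestry. 0-based
#' half-open coordinates; header row present.
#'
#' @param path File path.
#' @param type `"roh"` or `"ibd"`.
#' @return For `read_segments`, a `segment_table`.
#' @export
read_segments <- function(path, type = c("roh", "ibd")) {
  type <- match.arg(type)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  segment_table(d, type = type)
}

#' @rdname read_segments
#' @param segments A `segment_table`.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_table"))
  utils::write.table(as.data.frame(segments), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
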