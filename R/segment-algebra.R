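#' Detect runs of homozygosity from hard-called genotypes
#'
#' Scans each individual's sorted genotypes chromosome by chromosome for
#' maximal runs of homozygous calls containing at most `max_het`
#' heterozygous and `max_missing` missing calls, spanning at least
#' `min_length_kb` kilobases and `min_snps` markers. Runs start and end at
#' homozygous calls; extension is greedy left-to-right, ties broken toward
#' the longer run. Defaults approximate common array-data practice with a
#' 1 Mb minimum length.
#'
#' @param geno A `genotype_matrix`; positions must be sorted within
#'   chromosome (unsorted input is an error).
#' @param min_length_kb Minimum run span in kb (default 1000, i.e. 1 Mb).
#' @param min_snps Minimum number of markers in the run (default 50).
#' @param max_het Maximum heterozygous calls tolerated inside a run.
#' @param max_missing Maximum missing calls tolerated inside a run.
#' @return A `segment_table` of type `"roh"` (0-based half-open; a run ends
#'   just past its last homozygous marker).
#' @export
detect_roh <- function(geno, min_length_kb = 1000, min_snps = 50,
                       max_het = 1, max_missing = 2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  out <- list()
  for (cn in unique(geno$variants$chrom)) {
    vi <- which(geno$variants$chrom == cn)
    pos <- geno$variants$pos[vi]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop(sprintf("variant positions unsorted on chromosome %s", cn))
    }
    d <- geno$dosage[vi, , drop = FALSE]
    for (ind in geno$individuals) {
      g <- d[, ind]
      runs <- find_homozygous_runs(g, pos, max_het, max_missing)
      if (nrow(runs) == 0L) next
      span <- pos[runs[, 2L]] + 1 - pos[runs[, 1L]]
      nsnp <- runs[, 2L] - runs[, 1L] + 1L
      keep <- span >= min_length_kb * 1000 & nsnp >= min_snps
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn,
          start = pos[runs[keep, 1L]],
          end = pos[runs[keep, 2L]] + 1,
          individual = ind,
          n_snps = nsnp[keep])
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               individual = character(0), n_snps = integer(0))
  seg <- segment_table(df[, c("chrom", "start", "end", "individual")], "roh")
  seg$n_snps <- df$n_snps
  seg
}

# Greedy left-to-right homozygous-run finder; returns matrix of
# (first index, last index) over one individual's calls on one chromosome.
find_homozygous_runs <- function(g, pos, max_het, max_missing) {
  n <- length(g)
  is_hom <- !is.na(g) & (g == 0L | g == 2L)
  is_het <- !is.na(g) & g == 1L
  runs <- matrix(integer(0), ncol = 2L)
  i <- 1L
  while (i <= n) {
    if (!is_hom[i]) {
      i <- i + 1L
      next
    }
    j <- i
    het <- 0L
    mis <- 0L
    k <- i + 1L
    while (k <= n) {
      if (is_hom[k]) {
        j <- k
      } else if (is_het[k]) {
        if (het + 1L > max_het) break
        het <- het + 1L
      } else {
        if (mis + 1L > max_missing) break
        mis <- mis + 1L
      }
      k <- k + 1L
    }
    runs <- rbind(runs, c(i, j))
    i <- j + 1L
  }
  runs
}

#' ROH length-class configuration
#'
#' Ordered cutpoints defining small/medium/large ROH as half-open bins
#' `[b1, b2)`, `[b2, b3)`, `[b3, Inf)`. The defaults (1, 8, 16 Mb) treat
#' runs under 8 Mb as "small" -- shorter than expected from recent
#' consanguinity, reflecting older coalescence.
#'
#' @param boundaries Strictly increasing numeric cutpoints (length 3).
#' @param unit `"mb"` (physical) or `"cm"` (genetic) lengths.
#' @return A `roh_class_config` list.
#' @export
roh_class_config <- function(boundaries = c(1, 8, 16), unit = c("mb", "cm")) {
  unit <- match.arg(unit)
  stopifnot(length(boundaries) == 3L, all(diff(boundaries) > 0))
  structure(list(boundaries = boundaries, unit = unit),
            class = "roh_class_config")
}

#' Classify ROH into small/medium/large
#'
#' @param segments A `segment_table` of ROH with lengths attached
#'   ([add_segment_lengths()]).
#' @param cfg A [roh_class_config()].
#' @return Factor of labels `small`/`medium`/`large`, one per segment. A
#'   length below the lowest boundary is an error (such a run should not
#'   have passed detection).
#' @export
classify_roh <- function(segments, cfg = roh_class_config()) {
  stopifnot(inherits(segments, "segment_table"),
            inherits(cfg, "roh_class_config"))
  len <- if (cfg$unit == "mb") (segments$end - segments$start) / 1e6
         else segments$length_cm
  if (is.null(len) || anyNA(len)) stop("segment lengths unavailable")
  b <- cfg$boundaries
  if (any(len < b[1L])) stop("segment shorter than the detection minimum")
  cut(len, breaks = c(b, Inf), right = FALSE,
      labels = c("small", "medium", "large"))
}

#' Homozygous-ancestry blocks of one individual
#'
#' Maximal intervals where both haplotypes of an individual carry the same
#' ancestry label; the complement is labelled heterozygous-ancestry
#' (`homozygous = FALSE`, `ancestry = NA`).
#'
#' @param tracts An `ancestry_tracts` object containing both haplotypes of
#'   `individual`.
#' @param individual Individual id.
#' @return Data frame with columns `chrom`, `start`, `end`, `ancestry`,
#'   `homozygous`, sorted, tiling each chromosome.
#' @export
homozygous_ancestry_blocks <- function(tracts, individual) {
  stopifnot(inherits(tracts, "ancestry_tracts"))
  sub <- tracts[tracts$individual == individual, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("no tracts for individual '%s'", individual))
  out <- list()
  for (cn in unique(sub$chrom)) {
    h0 <- sub[sub$chrom == cn & sub$haplotype == 0L, , drop = FALSE]
    h1 <- sub[sub$chrom == cn & sub$haplotype == 1L, , drop = FALSE]
    if (nrow(h0) == 0L || nrow(h1) == 0L) {
      stop(sprintf("individual '%s' missing a haplotype on chromosome %s",
                   individual, cn))
    }
    h0 <- h0[order(h0$start), ]
    h1 <- h1[order(h1$start), ]
    if (h0$start[1L] != h1$start[1L] || h0$end[nrow(h0)] != h1$end[nrow(h1)]) {
      stop(sprintf("haplotype partitions disagree on extent of chromosome %s", cn))
    }
    cuts <- sort(unique(c(h0$start, h0$end, h1$start, h1$end)))
    s <- cuts[-length(cuts)]
    e <- cuts[-1L]
    lab0 <- h0$ancestry[findInterval(s, h0$start)]
    lab1 <- h1$ancestry[findInterval(s, h1$start)]
    hom <- lab0 == lab1
    anc <- ifelse(hom, lab0, NA_character_)
    # merge adjacent atoms with identical state
    state <- paste(hom, anc)
    grp <- cumsum(c(TRUE, state[-1L] != state[-length(state)]))
    out[[length(out) + 1L]] <- data.frame(
      chrom = cn,
      start = tapply(s, grp, min),
      end = tapply(e, grp, max),
      ancestry = tapply(anc, grp, `[`, 1L),
      homozygous = tapply(hom, grp, `[`, 1L),
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' Assign ROH to an ancestry via homozygous-ancestry blocks
#'
#' A run is `assigned` to an ancestry only when it is fully contained in a
#' single homozygous-ancestry block; a run touching at least one homozygous
#' block but crossing a block boundary is `spans_switch`; a run touching no
#' homozygous block is `no_homozygous_overlap`. Only `assigned` runs enter
#' ancestry-specific summaries; the other two statuses are excluded, kept
#' for bookkeeping.
#'
#' @param segments A `segment_table` of ROH.
#' @param tracts An `ancestry_tracts` covering the segments' carriers.
#' @return `segments` with added columns `status` and `ancestry`.
#' @export
assign_roh_ancestry <- function(segments, tracts) {
  stopifnot(inherits(segments, "segment_table"),
            attr(segments, "type") == "roh")
  status <- character(nrow(segments))
  ancestry <- rep(NA_character_, nrow(segments))
  blocks_cache <- list()
  for (i in seq_len(nrow(segments))) {
    ind <- segments$individual[i]
    if (is.null(blocks_cache[[ind]])) {
      blocks_cache[[ind]] <- homozygous_ancestry_blocks(tracts, ind)
    }
    b <- blocks_cache[[ind]]
    b <- b[b$chrom == segments$chrom[i] & b$homozygous, , drop = FALSE]
    ov <- b$start < segments$end[i] & b$end > segments$start[i]
    if (!any(ov)) {
      status[i] <- "no_homozygous_overlap"
    } else {
      contained <- ov & b$start <= segments$start[i] & b$end >= segments$end[i]
      if (any(contained)) {
        status[i] <- "assigned"
        ancestry[i] <- b$ancestry[which(contained)[1L]]
      } else {
        status[i] <- "spans_switch"
      }
    }
  }
  segments$status <- status
  segments$ancestry <- ancestry
  segments
}

#' Merge short gaps between IBD segments
#'
#' Adjacent segments of the same haplotype pair on the same chromosome are
#' merged when the gap between them is shorter than `max_gap_cm` in genetic
#' length and contains at most `max_discordant` discordant homozygous sites
#' (sites where the two carrier individuals are opposite homozygotes, which
#' would contradict shared descent). The rule is applied transitively:
#' merging continues left-to-right over the already-merged segment until a
#' fixed point. Overlapping same-pair segments are merged unconditionally
#' with a warning.
#'
#' @param segments A `segment_table` of type `"ibd"`.
#' @param geno Optional `genotype_matrix` used to count discordant
#'   homozygotes; with `NULL` every gap counts zero.
#' @param map A `genome_map` for gap genetic lengths.
#' @param max_gap_cm Maximum gap genetic length (default 0.6 cM).
#' @param max_discordant Maximum discordant homozygotes in a gap (default 1).
#' @return A merged `segment_table` of type `"ibd"`.
#' @export
merge_ibd_gaps <- function(segments, geno = NULL, map,
                           max_gap_cm = 0.6, max_discordant = 1) {
  stopifnot(inherits(segments, "segment_table"),
            attr(segments, "type") == "ibd")
  if (nrow(segments) == 0L) return(segments)
  key <- paste(segments$hap1, segments$hap2, segments$chrom, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(segments)), key), function(idx) {
    sub <- segments[idx, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cn <- sub$chrom[1L]
    ind1 <- hap_individual(sub$hap1[1L])
    ind2 <- hap_individual(sub$hap2[1L])
    cur <- sub[1L, , drop = FALSE]
    acc <- list()
    for (r in seq_len(nrow(sub))[-1L]) {
      nxt <- sub[r, , drop = FALSE]
      if (nxt$start <= cur$end) {
        warning("overlapping same-pair IBD segments merged unconditionally")
        cur$end <- max(cur$end, nxt$end)
        next
      }
      gap_cm <- interval_cm(map, cn, cur$end, nxt$start)
      disc <- count_discordant_homozygotes(geno, cn, cur$end, nxt$start,
                                           ind1, ind2)
      if (gap_cm < max_gap_cm && disc <= max_discordant) {
        cur$end <- nxt$end
      } else {
        acc[[length(acc) + 1L]] <- cur
        cur <- nxt
      }
    }
    acc[[length(acc) + 1L]] <- cur
    do.call(rbind, acc)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$hap1, out$hap2, out$chrom, out$start), , drop = FALSE]
  out$length_bp <- NULL
  out$length_cm <- NULL
  segment_table(out, "ibd")
}

count_discordant_homozygotes <- function(geno, chrom, start, end, ind1, ind2) {
  if (is.null(geno)) return(0L)
  vi <- geno$variants$chrom == chrom & geno$variants$pos >= start &
    geno$variants$pos < end
  if (!any(vi)) return(0L)
  g1 <- geno$dosage[vi, ind1]
  g2 <- geno$dosage[vi, ind2]
  sum((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L), na.rm = TRUE)
}

#' Mask IBD segments to one ancestry
#'
#' Intersects each IBD segment with the regions where both carrier
#' haplotypes are labelled with the query ancestry, and discards resulting
#' sub-segments shorter than `min_cm` (applied to the post-intersection
#' genetic length, matching the ancestry-specific analysis intent).
#'
#' @param segments A `segment_table` of type `"ibd"`.
#' @param tracts An `ancestry_tracts` covering both carrier haplotypes.
#' @param map A `genome_map`.
#' @param ancestry Query ancestry label.
#' @param min_cm Minimum sub-segment genetic length (default 2 cM).
#' @return A `segment_table` of type `"ibd"` with lengths and an `ancestry`
#'   column attached.
#' @export
ancestry_specific_ibd <- function(segments, tracts, map, ancestry,
                                  min_cm = 2.0) {
  stopifnot(inherits(segments, "segment_table"),
            attr(segments, "type") == "ibd",
            inherits(tracts, "ancestry_tracts"))
  out <- list()
  for (i in seq_len(nrow(segments))) {
    cn <- segments$chrom[i]
    a1 <- haplotype_intervals(tracts, hap_individual(segments$hap1[i]),
                              hap_index(segments$hap1[i]), cn, ancestry)
    a2 <- haplotype_intervals(tracts, hap_individual(segments$hap2[i]),
                              hap_index(segments$hap2[i]), cn, ancestry)
    shared <- intersect_intervals(a1, a2)
    pieces <- intersect_intervals(shared,
                                  cbind(segments$start[i], segments$end[i]))
    if (nrow(pieces) == 0L) next
    cm <- interval_cm(map, cn, pieces[, 1L], pieces[, 2L])
    keep <- cm >= min_cm
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = cn, start = pieces[keep, 1L], end = pieces[keep, 2L],
      hap1 = segments$hap1[i], hap2 = segments$hap2[i],
      ancestry = ancestry)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               hap1 = character(0), hap2 = character(0),
               ancestry = character(0))
  add_segment_lengths(segment_table(df, "ibd"), map)
}
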