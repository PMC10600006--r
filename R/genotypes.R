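#' Genotype dosage container
#'
#' A light container for hard-called biallelic genotypes: an integer dosage
#' matrix (variants x individuals, counting ALT alleles, `NA` = missing) plus
#' a variant table carrying positions and the inferred ancestral allele.
#'
#' @param dosage Integer matrix, variants in rows, individuals in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (0-based bp),
#'   `ref`, `alt`, `ancestral` (one of `"ref"`, `"alt"`, `"unknown"`).
#' @param individuals Character vector of individual ids (defaults to the
#'   dosage column names).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, individuals = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(dosage)))
  need <- c("id", "chrom", "pos", "ref", "alt", "ancestral")
  if (!is.data.frame(variants) || !all(need %in% names(variants))) {
    stop("variants need columns id, chrom, pos, ref, alt, ancestral")
  }
  if (nrow(variants) != nrow(dosage)) {
    stop("variants and dosage row counts differ")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be in {0, 1, 2, NA}")
  variants$chrom <- as.character(variants$chrom)
  variants$ancestral <- as.character(variants$ancestral)
  if (!all(variants$ancestral %in% c("ref", "alt", "unknown"))) {
    stop("ancestral must be 'ref', 'alt' or 'unknown'")
  }
  colnames(dosage) <- individuals
  rownames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants,
                 individuals = as.character(individuals)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d individuals (%d chromosome(s))\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$chrom))))
  invisible(x)
}

#' ALT allele frequencies
#'
#' @param geno A `genotype_matrix`.
#' @return Per-variant ALT allele frequency over non-missing calls.
#' @export
alt_frequency <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  rowMeans(geno$dosage, na.rm = TRUE) / 2
}

# Subset variants of a genotype_matrix by row index.
subset_variants <- function(geno, idx) {
  genotype_matrix(geno$dosage[idx, , drop = FALSE],
                  geno$variants[idx, , drop = FALSE],
                  geno$individuals)
}
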