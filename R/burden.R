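#' Polarize genotypes to derived-allele dosages and compute DAF
#'
#' Using the inferred ancestral allele of each variant, the derived dosage
#' is the ALT dosage where the ancestral allele is REF, and `2 - ALT`
#' dosage where the ancestral allele is ALT. Variants with an unknown
#' ancestral allele are excluded (assuming them ref-ancestral would
#' systematically inflate burdens). The derived allele frequency (DAF) is
#' computed cohort-wide over non-missing calls.
#'
#' @param geno A `genotype_matrix` with `ancestral` annotation, or the
#'   annotation can be overridden by `annotations`.
#' @param annotations Optional data frame with columns `id`, `ancestral`
#'   replacing the genotype matrix's ancestral calls.
#' @return List with `derived` (dosage matrix over the retained variants),
#'   `daf` (per-variant derived allele frequency), `variants` (retained
#'   variant table) and `n_excluded` (unknown-ancestral count).
#' @export
polarize_and_daf <- function(geno, annotations = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  anc <- geno$variants$ancestral
  if (!is.null(annotations)) {
    stopifnot(all(c("id", "ancestral") %in% names(annotations)))
    m <- match(geno$variants$id, annotations$id)
    anc <- ifelse(is.na(m), "unknown", annotations$ancestral[m])
  }
  keep <- anc %in% c("ref", "alt")
  if (!any(keep)) stop("no variant has a known ancestral allele")
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("excluding %d variant(s) with unknown ancestral allele",
                    n_excluded))
  }
  d <- geno$dosage[keep, , drop = FALSE]
  flip <- anc[keep] == "alt"
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  daf <- rowMeans(d, na.rm = TRUE) / 2
  list(derived = d, daf = daf,
       variants = geno$variants[keep, , drop = FALSE],
       n_excluded = n_excluded)
}

#' Classify variant consequences into burden classes
#'
#' Maps controlled-vocabulary consequence terms into the burden classes
#' `intergenic`, `synonymous`, `nonsynonymous_deleterious`, `lof`, `other`.
#' Loss-of-function comprises splice acceptor/donor, stop gained, stop
#' lost and start lost. Missense variants count as deleterious only when
#' flagged damaging by the upstream predictor; unflagged missense maps to
#' `other` and is excluded from summaries.
#'
#' @param consequence Character vector of consequence terms
#'   (e.g. `"missense_variant"`).
#' @param damaging Logical vector: predicted-damaging flag for missense
#'   variants (`NA` treated as not damaging).
#' @return Character vector of class labels.
#' @export
classify_consequence <- function(consequence, damaging = NULL) {
  lof_terms <- c("splice_acceptor_variant", "splice_donor_variant",
                 "stop_gained", "stop_lost", "start_lost")
  if (is.null(damaging)) damaging <- rep(FALSE, length(consequence))
  damaging <- !is.na(damaging) & damaging
  out <- rep("other", length(consequence))
  out[consequence %in% lof_terms] <- "lof"
  out[consequence == "synonymous_variant"] <- "synonymous"
  out[consequence == "intergenic_variant"] <- "intergenic"
  out[consequence == "missense_variant" & damaging] <- "nonsynonymous_deleterious"
  out
}

#' Per-individual derived-allele burden by class and frequency stratum
#'
#' Burden is the sum of derived allele copies carried by an individual over
#' a variant class, computed for the rare stratum (DAF <= `tau`) and for
#' all frequencies. Missing genotypes contribute zero and decrement the
#' individual's callable-variant count for the class.
#'
#' @param derived Derived-dosage matrix (variants x individuals), e.g. from
#'   [polarize_and_daf()].
#' @param daf Per-variant derived allele frequencies.
#' @param classes Per-variant class labels from [classify_consequence()];
#'   `"other"` is excluded.
#' @param tau Rare-variant DAF threshold in (0, 1] (default 0.05).
#' @return A long data frame (class `burden_table`) with columns
#'   `individual`, `class`, `stratum` (`rare`/`all`), `burden`, `callable`.
#' @export
compute_burden <- function(derived, daf, classes, tau = 0.05) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    stop("tau must be in (0, 1]")
  }
  stopifnot(nrow(derived) == length(daf), length(daf) == length(classes))
  inds <- colnames(derived)
  if (is.null(inds)) inds <- paste0("ind", seq_len(ncol(derived)))
  out <- list()
  for (cl in setdiff(unique(classes), "other")) {
    in_class <- classes == cl
    for (stratum in c("rare", "all")) {
      idx <- in_class & (if (stratum == "rare") daf <= tau else TRUE)
      d <- derived[idx, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        individual = inds, class = cl, stratum = stratum,
        burden = colSums(d, na.rm = TRUE),
        callable = colSums(!is.na(d)),
        row.names = NULL)
    }
  }
  df <- do.call(rbind, out)
  class(df) <- c("burden_table", "data.frame")
  df
}

#' Spearman correlation of burden with ancestry proportions
#'
#' For every combination of ancestry, variant class and frequency stratum,
#' computes Spearman's rank correlation (mean ranks for ties) between the
#' per-individual burden and the individual's ancestry proportion, with a
#' two-sided p-value from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)).
#'
#' @param burden A `burden_table` from [compute_burden()].
#' @param proportions Matrix (individuals x ancestries) of ancestry
#'   fractions, rownames = individual ids.
#' @return Data frame with columns `ancestry`, `class`, `stratum`, `n`,
#'   `rho`, `p`; `rho`/`p` are `NA` when either vector is constant.
#' @export
correlate_burden <- function(burden, proportions) {
  stopifnot(inherits(burden, "burden_table"), is.matrix(proportions))
  combos <- unique(burden[, c("class", "stratum")])
  out <- list()
  for (anc in colnames(proportions)) {
    for (r in seq_len(nrow(combos))) {
      sub <- burden[burden$class == combos$class[r] &
                    burden$stratum == combos$stratum[r], , drop = FALSE]
      keep <- sub$individual %in% rownames(proportions)
      sub <- sub[keep, , drop = FALSE]
      x <- proportions[sub$individual, anc]
      y <- sub$burden
      n <- length(x)
      if (n < 10L) stop("need at least 10 individuals for correlation")
      st <- spearman_t(x, y)
      out[[length(out) + 1L]] <- data.frame(
        ancestry = anc, class = combos$class[r], stratum = combos$stratum[r],
        n = n, rho = st$rho, p = st$p)
    }
  }
  do.call(rbind, out)
}

# Spearman rho with mean-rank ties and two-sided t-approximation p-value.
spearman_t <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Estimate global ancestry proportions from genotypes
#'
#' Non-negative least squares of each individual's dosage/2 on the
#' per-ancestry reference allele-frequency matrix, renormalized to sum
#' to one. A fast supervised stand-in for model-based global ancestry
#' estimation, adequate when the reference frequencies are well
#' differentiated.
#'
#' @param geno A `genotype_matrix` (>= 100 variants recommended).
#' @param ref_freq Matrix (variants x ancestries) of ALT allele frequencies
#'   per ancestry; must have full column rank.
#' @return Matrix (individuals x ancestries) of proportions.
#' @export
estimate_ancestry_proportions <- function(geno, ref_freq) {
  stopifnot(inherits(geno, "genotype_matrix"), is.matrix(ref_freq))
  if (nrow(ref_freq) != nrow(geno$dosage)) {
    stop("ref_freq rows must match variants")
  }
  if (qr(ref_freq)$rank < ncol(ref_freq)) {
    stop("ancestry frequency matrix is rank-deficient")
  }
  out <- matrix(NA_real_, nrow = ncol(geno$dosage), ncol = ncol(ref_freq),
                dimnames = list(geno$individuals, colnames(ref_freq)))
  for (j in seq_len(ncol(geno$dosage))) {
    y <- geno$dosage[, j] / 2
    ok <- !is.na(y)
    fit <- pracma::lsqnonneg(ref_freq[ok, , drop = FALSE], y[ok])
    w <- fit$x
    if (sum(w) <= 0) w <- rep(1 / length(w), length(w))
    out[j, ] <- w / sum(w)
  }
  out
}
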