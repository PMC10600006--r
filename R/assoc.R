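#' LD pruning by sliding-window dosage correlation
#'
#' Deterministic left-to-right scan over position-sorted variants: a
#' variant is dropped when any already-kept variant within `window_kb`
#' upstream has squared dosage correlation above `r2` with it; the window
#' then advances by one variant.
#'
#' @param geno A `genotype_matrix`, sorted by position within chromosome.
#' @param r2 Squared-correlation threshold (default 0.1).
#' @param window_kb Window size in kb (default 50).
#' @return Logical vector: `TRUE` for kept variants.
#' @export
ld_prune <- function(geno, r2 = 0.1, window_kb = 50) {
  stopifnot(inherits(geno, "genotype_matrix"))
  keep <- logical(nrow(geno$dosage))
  for (cn in unique(geno$variants$chrom)) {
    vi <- which(geno$variants$chrom == cn)
    pos <- geno$variants$pos[vi]
    if (is.unsorted(pos)) stop("variant positions must be sorted")
    kept_local <- integer(0)
    for (k in seq_along(vi)) {
      in_window <- kept_local[pos[kept_local] >= pos[k] - window_kb * 1000]
      g <- geno$dosage[vi[k], ]
      drop <- FALSE
      for (j in in_window) {
        r <- suppressWarnings(stats::cor(g, geno$dosage[vi[j], ],
                                         use = "complete.obs"))
        if (!is.na(r) && r^2 > r2) {
          drop <- TRUE
          break
        }
      }
      if (!drop) {
        kept_local <- c(kept_local, k)
        keep[vi[k]] <- TRUE
      }
    }
  }
  keep
}

#' Genetic relationship matrix with standard variant filters
#'
#' Removes rare variants (MAF below `maf_min`), variants inside supplied
#' long-range-LD exclusion regions, and (optionally) variants in high LD
#' via [ld_prune()]; then computes the standardized GRM
#' K = (1/m) sum_v (x_v - 2 p_v)(x_v - 2 p_v)' / (2 p_v (1 - p_v))
#' with missing dosages mean-imputed, and its leading principal
#' components.
#'
#' @param geno A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param exclude_regions Optional data frame (`chrom`, `start`, `end`) of
#'   regions to exclude (half-open).
#' @param prune Apply LD pruning (default TRUE).
#' @param ld_r2,window_kb Pruning parameters (defaults 0.1, 50).
#' @param n_pcs Number of principal components to return (default 10).
#' @return List with `K` (n x n), `pcs` (n x n_pcs), `eigenvalues`, and
#'   `variants_used` (logical over input variants).
#' @export
compute_grm <- function(geno, maf_min = 0.05, exclude_regions = NULL,
                        prune = TRUE, ld_r2 = 0.1, window_kb = 50,
                        n_pcs = 10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- alt_frequency(geno)
  maf <- pmin(p, 1 - p)
  use <- !is.na(maf) & maf >= maf_min
  if (!is.null(exclude_regions)) {
    for (r in seq_len(nrow(exclude_regions))) {
      inside <- geno$variants$chrom == as.character(exclude_regions$chrom[r]) &
        geno$variants$pos >= exclude_regions$start[r] &
        geno$variants$pos < exclude_regions$end[r]
      use <- use & !inside
    }
  }
  if (prune && any(use)) {
    sub <- subset_variants(geno, which(use))
    kept <- ld_prune(sub, r2 = ld_r2, window_kb = window_kb)
    use[which(use)] <- kept
  }
  m <- sum(use)
  if (m == 0L) stop("no variants remain after GRM filters")
  X <- geno$dosage[use, , drop = FALSE]
  pv <- p[use]
  Z <- (X - 2 * pv) / sqrt(2 * pv * (1 - pv))
  Z[is.na(Z)] <- 0  # mean imputation of missing dosages
  K <- crossprod(Z) / m
  dimnames(K) <- list(geno$individuals, geno$individuals)
  eig <- eigen(K, symmetric = TRUE)
  n_pcs <- min(n_pcs, ncol(K))
  pcs <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- geno$individuals
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  list(K = K, pcs = pcs, eigenvalues = eig$values, variants_used = use)
}

#' Per-variant association scan by ordinary least squares
#'
#' Regresses an (inverse-normal transformed) trait on each variant's
#' dosage with fixed covariates, via the Frisch-Waugh residualization so
#' estimates equal the full per-variant OLS fit. Missing dosages are
#' mean-imputed; variants with no residual dosage variance are skipped
#' (`NA` row).
#'
#' @param geno A `genotype_matrix`.
#' @param trait Numeric response, one value per individual.
#' @param covariates Optional numeric matrix/data frame of covariates (an
#'   intercept is always included).
#' @return Data frame `id`, `beta`, `se`, `t`, `p`.
#' @export
assoc_scan <- function(geno, trait, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"),
            length(trait) == ncol(geno$dosage))
  X <- cbind(`(Intercept)` = rep(1, length(trait)),
             if (!is.null(covariates)) as.matrix(covariates))
  ok <- stats::complete.cases(trait, X)
  y <- trait[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  df <- n - ncol(X) - 1L
  if (df <= 0) stop("too few individuals for the covariate set")
  out <- data.frame(id = geno$variants$id, beta = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_)
  G <- geno$dosage[, ok, drop = FALSE]
  for (v in seq_len(nrow(G))) {
    g <- G[v, ]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    rg <- qr.resid(qrX, g)
    sg2 <- sum(rg^2)
    if (sg2 < 1e-12) next
    beta <- sum(rg * ry) / sg2
    rss <- sum((ry - beta * rg)^2)
    se <- sqrt(rss / df / sg2)
    tstat <- beta / se
    out$beta[v] <- beta
    out$se[v] <- se
    out$t[v] <- tstat
    out$p[v] <- 2 * stats::pt(-abs(tstat), df = df)
  }
  out
}

#' Polygenic score configuration
#'
#' @param clump_r2 LD-clumping squared-correlation threshold (default 0.1).
#' @param clump_window_kb Clumping window (default 250 kb; a conventional
#'   choice, configurable).
#' @param p_thresholds P-value thresholds at which scores are computed.
#' @return A `pgs_config` list.
#' @export
pgs_config <- function(clump_r2 = 0.1, clump_window_kb = 250,
                       p_thresholds = c(0.1, 0.01, 0.001, 1e-5, 1e-8)) {
  stopifnot(all(p_thresholds > 0), all(p_thresholds <= 1))
  structure(list(clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 p_thresholds = sort(p_thresholds, decreasing = TRUE)),
            class = "pgs_config")
}

#' Clump-and-threshold polygenic scores
#'
#' Greedy LD clumping by ascending p-value (the index variant is retained;
#' variants within the window whose dosage r-squared with it exceeds the
#' threshold are removed), then for each p-value threshold the score is
#' the effect-size-weighted sum of effect-allele dosages over retained
#' variants passing the threshold.
#'
#' @param stats_df Summary statistics with columns `id`, `beta`, `p` and
#'   optionally `effect_allele` (`"ref"`/`"alt"`, default `"alt"`).
#' @param geno A `genotype_matrix` sharing variant ids with `stats_df`.
#' @param cfg A [pgs_config()].
#' @return Matrix (individuals x thresholds) of scores; attribute
#'   `retained` gives the clumped variant ids. A threshold passed by no
#'   variant yields a zero column with a warning.
#' @export
clump_and_score <- function(stats_df, geno, cfg = pgs_config()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            all(c("id", "beta", "p") %in% names(stats_df)))
  m <- match(stats_df$id, geno$variants$id)
  stats_df <- stats_df[!is.na(m) & !is.na(stats_df$p), , drop = FALSE]
  vidx <- match(stats_df$id, geno$variants$id)
  ord <- order(stats_df$p)
  removed <- rep(FALSE, nrow(stats_df))
  retained <- logical(nrow(stats_df))
  pos <- geno$variants$pos[vidx]
  chrom <- geno$variants$chrom[vidx]
  for (i in ord) {
    if (removed[i]) next
    retained[i] <- TRUE
    near <- which(!removed & !retained & chrom == chrom[i] &
                  abs(pos - pos[i]) <= cfg$clump_window_kb * 1000)
    for (j in near) {
      r <- suppressWarnings(stats::cor(geno$dosage[vidx[i], ],
                                       geno$dosage[vidx[j], ],
                                       use = "complete.obs"))
      if (!is.na(r) && r^2 > cfg$clump_r2) removed[j] <- TRUE
    }
  }
  scores <- matrix(0, nrow = ncol(geno$dosage), ncol = length(cfg$p_thresholds),
                   dimnames = list(geno$individuals,
                                   paste0("p", cfg$p_thresholds)))
  for (k in seq_along(cfg$p_thresholds)) {
    sel <- retained & stats_df$p <= cfg$p_thresholds[k]
    if (!any(sel)) {
      warning(sprintf("no variant passes threshold %g; zero scores",
                      cfg$p_thresholds[k]))
      next
    }
    for (i in which(sel)) {
      dos <- geno$dosage[vidx[i], ]
      if (anyNA(dos)) dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      if (!is.null(stats_df$effect_allele) &&
          stats_df$effect_allele[i] == "ref") {
        dos <- 2 - dos
      }
      scores[, k] <- scores[, k] + stats_df$beta[i] * dos
    }
  }
  attr(scores, "retained") <- stats_df$id[retained]
  scores
}

#' Incremental r-squared of a polygenic score
#'
#' Difference between the r-squared of the covariates-plus-score model and
#' the covariates-only null model; also reports the Pearson correlation of
#' score and trait.
#'
#' @param trait Numeric response.
#' @param score Polygenic score vector.
#' @param covariates Matrix/data frame of covariates (e.g. age, sex and
#'   principal components).
#' @return List with `delta_r2`, `r2_full`, `r2_null`, `pearson_r`, `n`.
#' @export
incremental_r2 <- function(trait, score, covariates) {
  covariates <- as.matrix(covariates)
  ok <- stats::complete.cases(trait, score, covariates)
  y <- trait[ok]
  s <- score[ok]
  C <- covariates[ok, , drop = FALSE]
  if (length(y) <= ncol(C) + 2L) stop("too few complete cases")
  r2 <- function(X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  r2_null <- r2(C)
  r2_full <- r2(cbind(C, s))
  list(delta_r2 = r2_full - r2_null, r2_full = r2_full, r2_null = r2_null,
       pearson_r = stats::cor(s, y), n = length(y))
}
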