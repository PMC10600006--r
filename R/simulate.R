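#' Configuration for a synthetic admixed cohort
#'
#' Defines the study conditions for the generator: cohort size, admixture
#' model (single pulse `g_admix` generations ago with stationary ancestry
#' proportions), genome map, variant count, the ancestral allele-frequency
#' spectrum and optional per-ancestry bottlenecks, the true effective
#' population size trajectories driving IBD, implanted-autozygosity
#' settings, and phenotype effect coefficients.
#'
#' @param n_individuals Number of diploid individuals.
#' @param ancestries Ancestry labels.
#' @param proportions Admixture proportions (non-negative, summing to 1
#'   within 1e-12).
#' @param g_admix Generations since the admixture pulse (>= 1).
#' @param map A `genome_map`.
#' @param n_variants Number of simulated biallelic variants.
#' @param n0 Ancestral diploid size setting the lower frequency bound
#'   1/(4 n0) of the 1/x spectrum.
#' @param maf_ascertain Array-style ascertainment floor: ancestral derived
#'   frequencies are drawn above this value (default 0.01), emulating a
#'   genotyping array's bias toward non-private variants.
#' @param bottleneck Named list per bottlenecked ancestry:
#'   `list(n_b = diploid size, t_b = generations)`.
#' @param ne_truth Named list of [ne_trajectory()] per ancestry (used by
#'   [simulate_ibd()]).
#' @param roh_per_individual Expected number of implanted autozygous runs
#'   per individual (Poisson).
#' @param roh_length_mb Length-2 range (Mb) of implanted run lengths.
#' @param prop_ancestral_alt Fraction of variants whose ancestral allele is
#'   the ALT allele (exercises polarization).
#' @param missing_rate Genotype missingness rate.
#' @param n_localities Number of sampling localities.
#' @param phenotype_effects Named list of coefficients `beta_pgs`,
#'   `beta_ancestry`, `beta_roh`, `beta_env`, `sigma_g`, `sigma_loc`,
#'   `sigma_e` (betas are per-SD of the predictor).
#' @param n_causal Number of causal variants behind the true polygenic
#'   score.
#' @param seed Global seed; per-stage child seeds are derived from it
#'   deterministically and recorded in the manifest.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 200,
                       ancestries = c("AMR", "EUR", "AFR"),
                       proportions = c(0.5, 0.4, 0.1),
                       g_admix = 15,
                       map = uniform_genome_map(c(`1` = 150, `2` = 120)),
                       n_variants = 2000,
                       n0 = 10000,
                       maf_ascertain = 0.01,
                       bottleneck = list(AMR = list(n_b = 300, t_b = 15)),
                       ne_truth = NULL,
                       roh_per_individual = 1,
                       roh_length_mb = c(1.5, 6),
                       prop_ancestral_alt = 0.3,
                       missing_rate = 0,
                       n_localities = 10,
                       phenotype_effects = list(beta_pgs = 0.5,
                                                beta_ancestry = 0.3,
                                                beta_roh = -0.3,
                                                beta_env = 0.3,
                                                sigma_g = 0.5,
                                                sigma_loc = 0.4,
                                                sigma_e = 0.7),
                       n_causal = 50,
                       seed = 1) {
  stopifnot(n_individuals >= 1, n_variants >= 1, n0 >= 1, n_localities >= 1)
  if (g_admix < 1) stop("g_admix must be >= 1")
  if (length(ancestries) != length(proportions)) {
    stop("ancestries and proportions must have equal length")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-12) {
    stop("proportions must be non-negative and sum to 1")
  }
  if (sum(chrom_lengths_cm(map)) <= 0) stop("zero-length genome")
  if (is.null(ne_truth)) {
    ne_truth <- stats::setNames(
      lapply(ancestries, function(a) ne_trajectory(rep(10000, 60))),
      ancestries)
  }
  cfg <- list(n_individuals = n_individuals, ancestries = ancestries,
              proportions = proportions, g_admix = g_admix, map = map,
              n_variants = n_variants, n0 = n0,
              maf_ascertain = maf_ascertain, bottleneck = bottleneck,
              ne_truth = ne_truth, roh_per_individual = roh_per_individual,
              roh_length_mb = roh_length_mb,
              prop_ancestral_alt = prop_ancestral_alt,
              missing_rate = missing_rate, n_localities = n_localities,
              phenotype_effects = phenotype_effects, n_causal = n_causal,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate pulse-admixture ancestry tracts
#'
#' Per haplotype and chromosome, recombination breakpoints follow a
#' homogeneous process at rate `g_admix` per Morgan along the genetic map
#' (the exponential tract-length signature of a single admixture pulse);
#' each breakpoint-delimited tract draws its ancestry independently with
#' the configured proportions. Tracts partition each chromosome exactly.
#'
#' @param config A [sim_config()].
#' @return An `ancestry_tracts` object.
#' @export
simulate_tracts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- config$map
  with_seed(child_seed(config$seed, "tracts"), {
    rows <- list()
    for (ind in cohort_ids(config)) {
      for (h in 0:1) {
        for (cn in map_chroms(map)) {
          d <- map[[cn]]
          cm0 <- d$cm[1L]
          cm1 <- d$cm[nrow(d)]
          len_m <- (cm1 - cm0) / 100
          n_break <- stats::rpois(1L, config$g_admix * len_m)
          bk <- sort(stats::runif(n_break, cm0, cm1))
          cuts_cm <- c(cm0, bk, cm1)
          cuts_bp <- interpolate_bp(map, cn, cuts_cm)
          cuts_bp[1L] <- d$bp[1L]
          cuts_bp[length(cuts_bp)] <- d$bp[nrow(d)]
          keep <- c(TRUE, diff(cuts_bp) > 0)
          cuts_bp <- cuts_bp[keep]
          k <- length(cuts_bp) - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = cn, start = cuts_bp[-length(cuts_bp)], end = cuts_bp[-1L],
            individual = ind, haplotype = h,
            ancestry = sample(config$ancestries, k, replace = TRUE,
                              prob = config$proportions))
        }
      }
    }
    ancestry_tracts(do.call(rbind, rows))
  })
}

cohort_ids <- function(config) {
  sprintf("ind%03d", seq_len(config$n_individuals))
}

#' Simulate genotypes on ancestry tracts
#'
#' Ancestral derived-allele frequencies are drawn from a truncated neutral
#' spectrum (density proportional to 1/x on [1/(4 n0), 0.5]); each
#' bottlenecked ancestry pushes those frequencies through `t_b` generations
#' of Wright-Fisher binomial resampling with 2 `n_b` gametes, reproducing
#' the loss of rare variants. Each haplotype's allele is drawn from the
#' frequency of the ancestry covering that position. Autozygous runs are
#' implanted (haplotype 1 copied from haplotype 0 over the run) and
#' recorded as ground-truth ROH.
#'
#' @param config A [sim_config()].
#' @param tracts Tracts from [simulate_tracts()] covering all variant
#'   positions.
#' @return List with `geno` (a `genotype_matrix` of ALT dosages with
#'   ancestral-allele annotation), `freqs` (variants x ancestries derived
#'   frequencies), `roh_truth` (implanted runs as a `segment_table`), and
#'   `monomorphic` (logical flag per variant).
#' @export
simulate_genotypes <- function(config, tracts) {
  stopifnot(inherits(config, "sim_config"), inherits(tracts, "ancestry_tracts"))
  map <- config$map
  with_seed(child_seed(config$seed, "genotypes"), {
    bp_len <- chrom_lengths_bp(map)
    n_per <- round(config$n_variants * bp_len / sum(bp_len))
    n_per[n_per < 1] <- 1
    vrows <- list()
    for (cn in map_chroms(map)) {
      d <- map[[cn]]
      step <- (d$bp[nrow(d)] - d$bp[1L]) / n_per[[cn]]
      pos <- d$bp[1L] + round((seq_len(n_per[[cn]]) - 0.5) * step)
      vrows[[length(vrows) + 1L]] <- data.frame(chrom = cn, pos = pos)
    }
    vt <- do.call(rbind, vrows)
    n_v <- nrow(vt)
    for (cn in unique(vt$chrom)) {
      d <- map[[cn]]
      bad <- vt$chrom == cn & (vt$pos < d$bp[1L] | vt$pos >= d$bp[nrow(d)])
      if (any(bad)) stop("variant position outside genome")
    }
    a <- max(1 / (4 * config$n0), config$maf_ascertain)
    f0 <- a * (0.5 / a)^stats::runif(n_v)
    freqs <- matrix(rep(f0, length(config$ancestries)), ncol = length(config$ancestries),
                    dimnames = list(NULL, config$ancestries))
    for (anc in names(config$bottleneck)) {
      bn <- config$bottleneck[[anc]]
      f <- freqs[, anc]
      for (t in seq_len(bn$t_b)) {
        f <- stats::rbinom(n_v, 2 * bn$n_b, f) / (2 * bn$n_b)
      }
      freqs[, anc] <- f
    }
    ids <- cohort_ids(config)
    # ancestry index of the tract covering each variant, per haplotype
    haps <- array(0L, dim = c(n_v, length(ids), 2L))
    for (j in seq_along(ids)) {
      for (h in 0:1) {
        anc_at <- character(n_v)
        for (cn in unique(vt$chrom)) {
          vi <- which(vt$chrom == cn)
          sub <- tracts[tracts$individual == ids[j] & tracts$haplotype == h &
                        tracts$chrom == cn, , drop = FALSE]
          sub <- sub[order(sub$start), ]
          anc_at[vi] <- sub$ancestry[findInterval(vt$pos[vi], sub$start)]
        }
        fh <- freqs[cbind(seq_len(n_v), match(anc_at, config$ancestries))]
        haps[, j, h + 1L] <- stats::rbinom(n_v, 1L, fh)
      }
    }
    # implant autozygous runs: copy haplotype 0 over haplotype 1
    roh_rows <- list()
    for (j in seq_along(ids)) {
      k <- stats::rpois(1L, config$roh_per_individual)
      if (k == 0L) next
      for (r in seq_len(k)) {
        cn <- sample(map_chroms(map), 1L, prob = bp_len / sum(bp_len))
        d <- map[[cn]]
        len <- stats::runif(1L, config$roh_length_mb[1L],
                            config$roh_length_mb[2L]) * 1e6
        len <- min(len, d$bp[nrow(d)] - d$bp[1L])
        s <- stats::runif(1L, d$bp[1L], d$bp[nrow(d)] - len)
        vi <- which(vt$chrom == cn & vt$pos >= s & vt$pos < s + len)
        if (length(vi)) haps[vi, j, 2L] <- haps[vi, j, 1L]
        roh_rows[[length(roh_rows) + 1L]] <- data.frame(
          chrom = cn, start = floor(s), end = floor(s + len),
          individual = ids[j])
      }
    }
    derived <- haps[, , 1L] + haps[, , 2L]
    anc_allele <- ifelse(stats::runif(n_v) < config$prop_ancestral_alt,
                         "alt", "ref")
    dosage <- derived
    flip <- anc_allele == "alt"
    dosage[flip, ] <- 2L - dosage[flip, , drop = FALSE]
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(dosage)) < config$missing_rate,
                     nrow = n_v)
      dosage[miss] <- NA_integer_
    }
    variants <- data.frame(
      id = sprintf("v%05d", seq_len(n_v)), chrom = vt$chrom, pos = vt$pos,
      ref = "A", alt = "G", ancestral = anc_allele)
    geno <- genotype_matrix(dosage, variants, ids)
    roh_truth <- segment_table(
      if (length(roh_rows)) do.call(rbind, roh_rows) else
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), individual = character(0)),
      "roh")
    list(geno = geno, freqs = freqs, roh_truth = roh_truth,
         monomorphic = apply(dosage, 1L, function(g) {
           u <- unique(g[!is.na(g)])
           length(u) <= 1L
         }))
  })
}

#' Simulate an IBD length spectrum from the forward model
#'
#' Draws per-pair, per-bin segment counts as Poisson with the means given
#' by [expected_spectrum()] on each pair's shared-ancestry genome length.
#' This is the exact forward model of [fit_ne()], making parameter
#' recovery a true oracle test.
#'
#' @param traj True [ne_trajectory()].
#' @param edges_cm Length-bin edges (cM), lowest = detection threshold.
#' @param pair_L Per-pair shared-ancestry genome lengths (Morgans).
#' @param seed Seed.
#' @param g_max Generation cap of the forward model.
#' @return An [ibd_spectrum()] with per-pair counts attached.
#' @export
simulate_ibd_spectrum <- function(traj, edges_cm = c(default_ibd_bins(), Inf),
                                  pair_L, seed = 1, g_max = 500) {
  stopifnot(inherits(traj, "ne_trajectory"), all(pair_L >= 0))
  with_seed(seed, {
    mu_unit <- expected_spectrum(traj, edges_cm, 1, g_max = g_max)
    pair_counts <- t(vapply(pair_L, function(L) {
      stats::rpois(length(mu_unit), mu_unit * L)
    }, numeric(length(mu_unit))))
    counts <- colSums(pair_counts)
    sp <- ibd_spectrum(numeric(0), edges_cm, L_total = sum(pair_L),
                       pair_counts = pair_counts, pair_L = pair_L)
    sp$counts <- counts
    sp
  })
}

#' Simulate placed IBD segments on a cohort's tracts
#'
#' For each sampled cross-individual haplotype pair and the query
#' ancestry, bin counts are Poisson under the forward model evaluated on
#' the pair's shared-ancestry genome length; segment lengths are drawn
#' from the within-bin coalescent mixture density, and positions are
#' placed uniformly within shared-ancestry regions (a segment longer than
#' its host region keeps its drawn `length_cm` but its coordinates are
#' clipped; edge effects are ignored by the model).
#'
#' @param config A [sim_config()] with `ne_truth` for the ancestry.
#' @param tracts Tracts from [simulate_tracts()].
#' @param ancestry Ancestry label to simulate (default first configured).
#' @param edges_cm Length-bin edges (cM).
#' @param max_pairs Maximum number of haplotype pairs sampled (default
#'   500); pairs are drawn deterministically under the stage seed.
#' @param g_max Generation cap.
#' @return A `segment_table` of type `"ibd"` with `length_cm` the drawn
#'   lengths and attributes `pair_L` (per-pair Morgans) and `pairs`.
#' @export
simulate_ibd <- function(config, tracts, ancestry = config$ancestries[1L],
                         edges_cm = c(default_ibd_bins(), Inf),
                         max_pairs = 500, g_max = 500) {
  stopifnot(inherits(config, "sim_config"), inherits(tracts, "ancestry_tracts"))
  traj <- config$ne_truth[[ancestry]]
  if (is.null(traj)) stop(sprintf("no ne_truth for ancestry '%s'", ancestry))
  map <- config$map
  ids <- cohort_ids(config)
  with_seed(child_seed(config$seed, paste0("ibd_", ancestry)), {
    hap_ids <- as.vector(outer(ids, 0:1, paste, sep = "|"))
    pairs <- t(utils::combn(hap_ids, 2L))
    cross <- hap_individual(pairs[, 1L]) != hap_individual(pairs[, 2L])
    pairs <- pairs[cross, , drop = FALSE]
    if (nrow(pairs) > max_pairs) {
      pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
    }
    mu_unit <- expected_spectrum(traj, edges_cm, 1, g_max = g_max)
    pm <- coalescence_pmf(traj, g_max)
    K <- spectrum_kernel(edges_cm / 100, g_max)  # g x bins weights
    rows <- list()
    pair_L <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      shared <- list()
      for (cn in map_chroms(map)) {
        a1 <- haplotype_intervals(tracts, hap_individual(pairs[i, 1L]),
                                  hap_index(pairs[i, 1L]), cn, ancestry)
        a2 <- haplotype_intervals(tracts, hap_individual(pairs[i, 2L]),
                                  hap_index(pairs[i, 2L]), cn, ancestry)
        sh <- intersect_intervals(a1, a2)
        if (nrow(sh)) {
          shared[[cn]] <- cbind(sh,
                                cm = interval_cm(map, cn, sh[, 1L], sh[, 2L]))
        }
      }
      if (length(shared) == 0L) next
      all_sh <- do.call(rbind, lapply(names(shared), function(cn) {
        data.frame(chrom = cn, start = shared[[cn]][, 1L],
                   end = shared[[cn]][, 2L], cm = shared[[cn]][, "cm"])
      }))
      L <- sum(all_sh$cm) / 100
      pair_L[i] <- L
      counts <- stats::rpois(length(mu_unit), mu_unit * L)
      for (b in which(counts > 0)) {
        for (s in seq_len(counts[b])) {
          w <- pm$p * K[, b]
          g <- sample.int(g_max, 1L, prob = w)
          l1 <- edges_cm[b] / 100
          l2 <- edges_cm[b + 1L] / 100
          u <- stats::runif(1L)
          # inverse-CDF draw from Exp(2g) truncated to [l1, l2]
          len_m <- -log(exp(-2 * g * l1) -
                          u * (exp(-2 * g * l1) -
                               (if (is.infinite(l2)) 0 else exp(-2 * g * l2)))) /
            (2 * g)
          host <- sample.int(nrow(all_sh), 1L, prob = all_sh$cm)
          cn <- all_sh$chrom[host]
          cm_a <- interpolate_cm(map, cn, all_sh$start[host])
          cm_b <- interpolate_cm(map, cn, all_sh$end[host])
          len_cm <- len_m * 100
          if (cm_b - cm_a > len_cm) {
            s_cm <- stats::runif(1L, cm_a, cm_b - len_cm)
            e_cm <- s_cm + len_cm
          } else {
            s_cm <- cm_a
            e_cm <- cm_b
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = cn,
            start = floor(interpolate_bp(map, cn, s_cm)),
            end = ceiling(interpolate_bp(map, cn, e_cm)),
            hap1 = pairs[i, 1L], hap2 = pairs[i, 2L],
            ancestry = ancestry, length_cm = len_cm)
        }
      }
    }
    if (all(pair_L == 0)) {
      warning("shared-ancestry genome is empty for every pair")
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 hap1 = character(0), hap2 = character(0),
                 ancestry = character(0), length_cm = numeric(0))
    seg <- segment_table(df, "ibd")
    seg$length_cm <- df$length_cm
    attr(seg, "pair_L") <- pair_L
    attr(seg, "pairs") <- data.frame(hap1 = pairs[, 1L], hap2 = pairs[, 2L])
    seg
  })
}

#' Simulate phenotypes with genetic and environmental structure
#'
#' Builds y = b_pgs PGS + b_anc A + b_roh ROH + b_env urban + u + c + e
#' where PGS is a true polygenic score over randomly chosen causal
#' variants, A the focal-ancestry proportion, ROH the total implanted run
#' length, all standardized to unit SD before applying their per-SD
#' coefficients; u ~ N(0, sigma_g^2 K) for the cohort GRM K,
#' c ~ N(0, sigma_loc^2) per locality, e ~ N(0, sigma_e^2). Covariates
#' (sex, birth year, urban/rural, educational attainment, locality,
#' Indigenous-language flag) are simulated alongside.
#'
#' @param config A [sim_config()] (all `phenotype_effects` must be
#'   present).
#' @param geno A `genotype_matrix` from [simulate_genotypes()].
#' @param tracts Matching tracts.
#' @param roh_truth Implanted-run `segment_table`.
#' @param K Optional precomputed GRM; computed from `geno` when `NULL`.
#' @return Data frame (class `phenotype_table`): `individual`, `trait`,
#'   covariates, `locality`, plus attributes `truth` (the standardized
#'   predictors and random draws) and `causal` (causal variant ids).
#' @export
simulate_phenotypes <- function(config, geno, tracts, roh_truth, K = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "genotype_matrix"))
  fx <- config$phenotype_effects
  need <- c("beta_pgs", "beta_ancestry", "beta_roh", "beta_env",
            "sigma_g", "sigma_loc", "sigma_e")
  if (!all(need %in% names(fx))) {
    stop(sprintf("missing phenotype effect(s): %s",
                 paste(setdiff(need, names(fx)), collapse = ", ")))
  }
  ids <- cohort_ids(config)
  n <- length(ids)
  with_seed(child_seed(config$seed, "phenotypes"), {
    std <- function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    n_causal <- min(config$n_causal, nrow(geno$dosage))
    causal <- sample.int(nrow(geno$dosage), n_causal)
    b <- stats::rnorm(n_causal)
    dos <- geno$dosage[causal, , drop = FALSE]
    dos[is.na(dos)] <- 0
    pgs_true <- as.numeric(crossprod(dos, b))
    prop <- tract_ancestry_proportions(tracts, config$map)
    anc_prop <- prop[ids, config$ancestries[1L]]
    sroh <- stats::setNames(rep(0, n), ids)
    if (nrow(roh_truth)) {
      agg <- tapply(roh_truth$end - roh_truth$start, roh_truth$individual, sum)
      sroh[names(agg)] <- agg
    }
    locality <- sample.int(config$n_localities, n, replace = TRUE)
    urban <- as.integer(stats::runif(n) < 0.3)
    sex <- as.integer(stats::runif(n) < 0.5)
    birth_year <- sample(1910:1980, n, replace = TRUE)
    edu <- sample(0:8, n, replace = TRUE)
    language <- as.integer(stats::runif(n) < 0.2)
    if (is.null(K)) K <- compute_grm(geno, prune = FALSE)$K
    eig <- eigen(K, symmetric = TRUE)
    L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
    u <- fx$sigma_g * as.numeric(L %*% stats::rnorm(n))
    c_loc <- fx$sigma_loc * stats::rnorm(config$n_localities)[locality]
    e <- fx$sigma_e * stats::rnorm(n)
    y <- fx$beta_pgs * std(pgs_true) + fx$beta_ancestry * std(anc_prop) +
      fx$beta_roh * std(sroh) + fx$beta_env * std(urban) + u + c_loc + e
    out <- data.frame(individual = ids, trait = y, sex = sex,
                      birth_year = birth_year, age = 2000 - birth_year,
                      urban = urban, edu = edu, language = language,
                      locality = locality,
                      ancestry_prop = anc_prop, sum_roh_bp = sroh,
                      pgs_true = pgs_true, row.names = NULL)
    attr(out, "truth") <- list(u = u, c_loc = c_loc, e = e,
                               std_pgs = std(pgs_true),
                               std_anc = std(anc_prop),
                               std_roh = std(sroh), std_urban = std(urban))
    attr(out, "causal") <- geno$variants$id[causal]
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}

#' Simulate a full cohort bundle
#'
#' Runs tracts, genotypes, IBD and phenotypes in order and assembles a
#' `cohort_bundle` with a manifest recording the config hash and all
#' derived stage seeds, so identical configs reproduce identical bundles.
#'
#' @param config A [sim_config()].
#' @param ibd_ancestry Ancestry whose IBD is simulated (default first).
#' @param max_ibd_pairs Passed to [simulate_ibd()].
#' @return A `cohort_bundle` list: `config`, `tracts`, `geno`, `freqs`,
#'   `ibd`, `roh_truth`, `phenotypes`, `manifest`.
#' @export
simulate_cohort <- function(config, ibd_ancestry = config$ancestries[1L],
                            max_ibd_pairs = 200) {
  stopifnot(inherits(config, "sim_config"))
  tracts <- simulate_tracts(config)
  gt <- simulate_genotypes(config, tracts)
  ibd <- simulate_ibd(config, tracts, ancestry = ibd_ancestry,
                      max_pairs = max_ibd_pairs)
  phen <- simulate_phenotypes(config, gt$geno, tracts, gt$roh_truth)
  manifest <- list(
    config_hash = hash_object(config),
    seed = config$seed,
    stage_seeds = list(tracts = child_seed(config$seed, "tracts"),
                       genotypes = child_seed(config$seed, "genotypes"),
                       ibd = child_seed(config$seed, paste0("ibd_", ibd_ancestry)),
                       phenotypes = child_seed(config$seed, "phenotypes")),
    n_individuals = config$n_individuals,
    n_variants = nrow(gt$geno$dosage),
    n_ibd_segments = nrow(ibd),
    n_roh_truth = nrow(gt$roh_truth))
  structure(list(config = config, tracts = tracts, geno = gt$geno,
                 freqs = gt$freqs, roh_truth = gt$roh_truth, ibd = ibd,
                 phenotypes = phen, manifest = manifest),
            class = "cohort_bundle")
}

# Deterministic md5 of an R object via its serialized bytes on disk.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Simulate variant consequence annotations
#'
#' Assigns each variant a consequence term with genome-like proportions
#' (mostly intergenic, some synonymous/missense, rare loss of function)
#' and a predicted-damaging flag for half of the missense variants, for
#' exercising the burden classification downstream.
#'
#' @param config A [sim_config()].
#' @param geno A `genotype_matrix`.
#' @return Data frame `id`, `consequence`, `damaging`, `ancestral`.
#' @export
simulate_annotations <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "genotype_matrix"))
  with_seed(child_seed(config$seed, "annotations"), {
    n <- nrow(geno$dosage)
    cons <- sample(c("intergenic_variant", "synonymous_variant",
                     "missense_variant", "stop_gained",
                     "splice_acceptor_variant"),
                   n, replace = TRUE,
                   prob = c(0.60, 0.18, 0.18, 0.02, 0.02))
    damaging <- cons == "missense_variant" & stats::runif(n) < 0.5
    data.frame(id = geno$variants$id, consequence = cons,
               damaging = damaging, ancestral = geno$variants$ancestral)
  })
}
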