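#' Effective population size trajectory
#'
#' Piecewise-constant diploid effective size per past generation, with a
#' constant tail beyond the last specified generation. Generation 1 is the
#' parental generation.
#'
#' @param ne Positive numeric vector, `ne[g]` the diploid size at
#'   generation `g`.
#' @param generation_years Calendar-scaling convention, 20 or 30 years per
#'   generation (metadata only; used when exporting plot-ready tables).
#' @return An object of class `ne_trajectory`.
#' @export
ne_trajectory <- function(ne, generation_years = 30) {
  stopifnot(is.numeric(ne), length(ne) >= 1L, all(ne > 0))
  if (!generation_years %in% c(20, 30)) {
    stop("generation_years must be 20 or 30")
  }
  structure(list(ne = as.numeric(ne), generation_years = generation_years),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("ne_trajectory: %d generation(s), Ne range [%.0f, %.0f], %d yr/gen\n",
              length(x$ne), min(x$ne), max(x$ne), x$generation_years))
  invisible(x)
}

# Ne at generations 1..g_max with constant extension beyond the trajectory.
extend_ne <- function(traj, g_max) {
  ne <- traj$ne
  if (g_max <= length(ne)) return(ne[seq_len(g_max)])
  c(ne, rep(ne[length(ne)], g_max - length(ne)))
}

#' Per-generation coalescence probabilities for a haplotype pair
#'
#' Under piecewise-constant diploid size N_g, two haplotypes coalesce in
#' generation g with probability
#' P(g) = (1 / (2 N_g)) * prod_{k < g} (1 - 1 / (2 N_k)).
#' The mass not yet coalesced by `g_max` (a geometric tail at the final
#' size) is returned as `tail_mass`, so `sum(p) + tail_mass == 1` exactly.
#'
#' @param traj An [ne_trajectory()].
#' @param g_max Number of generations to evaluate explicitly.
#' @return List with `p` (length `g_max`) and `tail_mass`.
#' @export
coalescence_pmf <- function(traj, g_max) {
  stopifnot(inherits(traj, "ne_trajectory"), g_max >= 1)
  ne <- extend_ne(traj, g_max)
  if (any(2 * ne < 1)) stop("2N must be >= 1 in every generation")
  rate <- 1 / (2 * ne)
  surv_before <- cumprod(c(1, 1 - rate))[seq_len(g_max)]
  p <- rate * surv_before
  list(p = p, tail_mass = surv_before[g_max] * (1 - rate[g_max]))
}

# Bin contribution matrix: E[g, b] = 2g (exp(-2 g l1_b) - exp(-2 g l2_b))
# for lengths in Morgans; the per-generation expected count in bin b per
# unit of pair-genome length. Precomputable: independent of the trajectory.
spectrum_kernel <- function(edges_morgan, g_max) {
  g <- seq_len(g_max)
  l1 <- edges_morgan[-length(edges_morgan)]
  l2 <- edges_morgan[-1L]
  E1 <- exp(-2 * outer(g, l1))
  E2 <- exp(-2 * outer(g, l2))
  E2[, is.infinite(l2)] <- 0
  (E1 - E2) * (2 * g)
}

#' Expected IBD segment counts per length bin
#'
#' Forward model: conditional on coalescence g generations ago, segment
#' lengths (in Morgans) around a point follow density (2g)^2 exp(-2 g l)
#' per unit pair-genome length, so the expected count in a bin (l1, l2) is
#' L_total * sum_g P(g) * 2g * (exp(-2 g l1) - exp(-2 g l2)). Generations
#' beyond `g_max` are summed analytically under the trajectory's constant
#' tail size. Chromosome-edge effects are ignored.
#'
#' @param traj An [ne_trajectory()].
#' @param edges_cm Strictly increasing bin edges in cM (last may be `Inf`).
#' @param L_total Total analysed pair-genome length in Morgans.
#' @param g_max Explicit generation cap (default 500).
#' @return Numeric vector of expected counts, one per bin.
#' @export
expected_spectrum <- function(traj, edges_cm, L_total, g_max = 500) {
  stopifnot(inherits(traj, "ne_trajectory"), L_total > 0)
  if (any(diff(edges_cm) <= 0)) stop("bin edges must be strictly increasing")
  edges <- edges_cm / 100
  pm <- coalescence_pmf(traj, g_max)
  K <- spectrum_kernel(edges, g_max)
  mu <- as.numeric(crossprod(K, pm$p)) * L_total
  mu + spectrum_tail(traj, edges, L_total, g_max, pm$tail_mass)
}

# Analytic sum over generations > g_max at the constant tail size:
# sum_{g>m} S r (1-r)^{g-m-1} * 2g * exp(-2 g l), via the arithmetico-
# geometric identity sum_{g>=m} g y^g = y^m (m - (m-1) y) / (1-y)^2.
spectrum_tail <- function(traj, edges_morgan, L_total, g_max, tail_mass) {
  n_last <- traj$ne[length(traj$ne)]
  r <- 1 / (2 * n_last)
  m <- g_max + 1
  if (tail_mass <= 0 || r >= 1) {
    # all mass already explicit (or coalescence certain at m with r = 1)
    Tfun <- function(l) {
      if (is.infinite(l) || tail_mass <= 0) return(0)
      tail_mass * 2 * m * exp(-2 * m * l)
    }
    l1 <- edges_morgan[-length(edges_morgan)]
    l2 <- edges_morgan[-1L]
    return(L_total * (vapply(l1, Tfun, numeric(1)) -
                        vapply(l2, Tfun, numeric(1))))
  }
  Tfun <- function(l) {
    if (is.infinite(l)) return(0)
    y <- (1 - r) * exp(-2 * l)
    # y^m / (1-r)^m collapses to exp(-2 l m), avoiding under/overflow
    s_scaled <- exp(m * (-2 * l)) * (m - (m - 1) * y) / (1 - y)^2
    2 * tail_mass * r * s_scaled
  }
  l1 <- edges_morgan[-length(edges_morgan)]
  l2 <- edges_morgan[-1L]
  L_total * (vapply(l1, Tfun, numeric(1)) - vapply(l2, Tfun, numeric(1)))
}

#' Default IBD length bins
#'
#' Multiplicatively widening bins from the detection threshold, with an
#' open top bin.
#'
#' @param min_cm Detection threshold in cM (default 2).
#' @return Numeric vector of bin edges in cM ending at `Inf`.
#' @export
default_ibd_bins <- function(min_cm = 2) {
  min_cm * c(1, 1.25, 1.5, 1.75, 2, 2.5, 3, 4, 5, 7, 10, 15, 25) / 1
}

#' Observed IBD length spectrum
#'
#' Bins ancestry-masked IBD segment lengths and records the analysed
#' pair-genome length, the sufficient statistics for [fit_ne()]. Optional
#' per-pair matrices enable pair-resampling bootstrap.
#'
#' @param lengths_cm Segment genetic lengths in cM.
#' @param edges_cm Bin edges in cM; lowest edge is the detection threshold.
#' @param L_total Total analysed pair-genome length in Morgans.
#' @param pair_counts Optional matrix (pairs x bins) of per-pair counts.
#' @param pair_L Optional per-pair genome lengths (Morgans).
#' @return An `ibd_spectrum` list.
#' @export
ibd_spectrum <- function(lengths_cm, edges_cm = c(default_ibd_bins(), Inf),
                         L_total, pair_counts = NULL, pair_L = NULL) {
  stopifnot(L_total > 0, all(diff(edges_cm) > 0))
  lengths_cm <- lengths_cm[lengths_cm >= edges_cm[1L]]
  counts <- as.numeric(table(cut(lengths_cm, breaks = edges_cm, right = FALSE)))
  structure(list(edges_cm = edges_cm, counts = counts, L_total = L_total,
                 pair_counts = pair_counts, pair_L = pair_L),
            class = "ibd_spectrum")
}

#' Fit an effective population size trajectory to an IBD length spectrum
#'
#' Maximizes the penalized Poisson log-likelihood
#' sum_b (n_b log mu_b - mu_b) - lambda sum_g (delta log N_g)^2
#' over per-generation log sizes, with a constant tail beyond generation
#' `G`. Optimization is bounded L-BFGS on log N with three fixed constant
#' starts (1e3, 1e4, 1e5) to guard against local optima; the best
#' converged start is returned. With `n_bootstrap > 0` and per-pair counts
#' available, percentile confidence bands are computed by resampling
#' carrier pairs (respecting within-pair dependence).
#'
#' @param spectrum An [ibd_spectrum()] with at least two non-empty bins.
#' @param G Number of free generations (default 60).
#' @param lambda Smoothness penalty weight on squared first differences of
#'   log Ne (default 1).
#' @param g_max Explicit generation cap in the forward model (default 500).
#' @param n_bootstrap Number of pair-resampling bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @param reltol Convergence tolerance passed to the optimizer.
#' @return An `ne_fit` list: `trajectory` (an [ne_trajectory()]), `loglik`,
#'   `penalty`, `convergence`, `expected` counts at the optimum, and
#'   optional `ci_lo`/`ci_hi` bands.
#' @export
fit_ne <- function(spectrum, G = 60, lambda = 1, g_max = 500,
                   n_bootstrap = 0, seed = 1, reltol = 1e-10) {
  stopifnot(inherits(spectrum, "ibd_spectrum"), G >= 2, lambda >= 0)
  counts <- spectrum$counts
  if (sum(counts > 0) < 2L) stop("need at least two non-empty length bins")
  est <- fit_ne_once(counts, spectrum$edges_cm, spectrum$L_total,
                     G, lambda, g_max, reltol)
  fit <- list(trajectory = ne_trajectory(est$ne),
              loglik = est$loglik, penalty = est$penalty,
              convergence = est$convergence,
              expected = est$expected, counts = counts,
              edges_cm = spectrum$edges_cm, G = G, lambda = lambda)
  if (n_bootstrap > 0) {
    if (is.null(spectrum$pair_counts) || is.null(spectrum$pair_L)) {
      stop("bootstrap requires per-pair counts and lengths in the spectrum")
    }
    boots <- with_seed(seed, {
      n_pairs <- nrow(spectrum$pair_counts)
      replicate(n_bootstrap, {
        idx <- sample.int(n_pairs, n_pairs, replace = TRUE)
        cb <- colSums(spectrum$pair_counts[idx, , drop = FALSE])
        Lb <- sum(spectrum$pair_L[idx])
        fit_ne_once(cb, spectrum$edges_cm, Lb, G, lambda, g_max, reltol)$ne
      })
    })
    fit$ci_lo <- apply(boots, 1L, stats::quantile, probs = 0.025)
    fit$ci_hi <- apply(boots, 1L, stats::quantile, probs = 0.975)
  }
  class(fit) <- "ne_fit"
  fit
}

fit_ne_once <- function(counts, edges_cm, L_total, G, lambda, g_max, reltol) {
  edges <- edges_cm / 100
  K <- spectrum_kernel(edges, g_max)
  negobj <- function(theta) {
    ne <- exp(theta)
    traj <- ne_trajectory(ne)
    pm <- coalescence_pmf(traj, g_max)
    mu <- as.numeric(crossprod(K, pm$p)) * L_total +
      spectrum_tail(traj, edges, L_total, g_max, pm$tail_mass)
    mu <- pmax(mu, 1e-300)
    ll <- sum(counts * log(mu) - mu)
    pen <- lambda * sum(diff(theta)^2)
    val <- -(ll - pen)
    if (!is.finite(val)) 1e12 else val
  }
  starts <- log(c(1e3, 1e4, 1e5))
  best <- NULL
  for (s in starts) {
    op <- stats::optim(rep(s, G), negobj, method = "L-BFGS-B",
                       lower = log(0.5) + 1e-9, upper = log(1e9),
                       control = list(maxit = 500, factr = reltol / .Machine$double.eps))
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (best$convergence != 0 && best$convergence != 1) {
    stop(sprintf("Ne optimization failed to converge (code %d): %s",
                 best$convergence, best$message))
  }
  ne <- exp(best$par)
  traj <- ne_trajectory(ne)
  pm <- coalescence_pmf(traj, g_max)
  mu <- as.numeric(crossprod(K, pm$p)) * L_total +
    spectrum_tail(traj, edges, L_total, g_max, pm$tail_mass)
  list(ne = ne,
       loglik = sum(counts * log(pmax(mu, 1e-300)) - mu),
       penalty = lambda * sum(diff(best$par)^2),
       convergence = best$convergence,
       expected = mu)
}

#' Total shared-ancestry pair-genome length
#'
#' Sum over haplotype pairs of the genetic length (in Morgans) where both
#' haplotypes carry the query ancestry: the exposure term `L_total` of the
#' IBD spectrum model.
#'
#' @param tracts An `ancestry_tracts`.
#' @param map A `genome_map`.
#' @param ancestry Query ancestry label.
#' @param pairs Data frame with columns `hap1`, `hap2` (haplotype ids
#'   `"ind|0"`); must be non-empty.
#' @return Scalar length in Morgans.
#' @export
ancestry_pair_length <- function(tracts, map, ancestry, pairs) {
  stopifnot(inherits(tracts, "ancestry_tracts"), inherits(map, "genome_map"))
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop("`pairs` must be a non-empty data frame with hap1, hap2")
  }
  total_cm <- 0
  for (i in seq_len(nrow(pairs))) {
    for (cn in map_chroms(map)) {
      a1 <- haplotype_intervals(tracts, hap_individual(pairs$hap1[i]),
                                hap_index(pairs$hap1[i]), cn, ancestry)
      a2 <- haplotype_intervals(tracts, hap_individual(pairs$hap2[i]),
                                hap_index(pairs$hap2[i]), cn, ancestry)
      shared <- intersect_intervals(a1, a2)
      if (nrow(shared)) {
        total_cm <- total_cm +
          sum(interval_cm(map, cn, shared[, 1L], shared[, 2L]))
      }
    }
  }
  total_cm / 100
}

#' Export an Ne fit as a plot-ready long table
#'
#' @param fit An `ne_fit` from [fit_ne()].
#' @param generation_years 20 or 30 years per generation.
#' @return Data frame with generation, years before present, Ne and
#'   optional bootstrap bands.
#' @export
ne_fit_table <- function(fit, generation_years = 30) {
  stopifnot(inherits(fit, "ne_fit"))
  g <- seq_along(fit$trajectory$ne)
  data.frame(generation = g,
             years_bp = g * generation_years,
             generation_years = generation_years,
             ne = fit$trajectory$ne,
             lo = if (is.null(fit$ci_lo)) NA_real_ else fit$ci_lo,
             hi = if (is.null(fit$ci_hi)) NA_real_ else fit$ci_hi)
}
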