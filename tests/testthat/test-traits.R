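# Phenotype QC ---------------------------------------------------------------

test_that("QC removes out-of-bounds values with reason codes, losslessly", {
  raw <- data.frame(individual = c("a", "b", "c", "d"),
                    height = c(99, 150, 201, 170),
                    weight = c(70, 20, 80, 310),
                    glucose = c(5, -1, 6, 7),
                    sbp1 = c(120, 120, 90, 400),
                    sbp2 = c(150, 122, 92, 118),
                    dbp1 = c(80, 80, 95, 70),
                    dbp2 = c(82, 81, 60, 72))
  qc <- phenotype_qc(raw)
  log <- attr(qc, "qc_log")
  expect_true(is.na(qc$height[1]))
  expect_equal(log$reason[log$individual == "a" & log$field == "height"],
               "bounds")
  expect_true(all(is.na(qc$weight[c(2, 4)])))
  expect_true(is.na(qc$glucose[2]))
  # SBP pair (120, 150): second reading removed as discordant
  expect_true(is.na(qc$sbp2[1]))
  expect_equal(qc$sbp[1], 120)
  # DBP 95 > SBP 90: both parts of reading 1 flagged; falls back to reading 2
  expect_true(is.na(qc$sbp1[3]) && is.na(qc$dbp1[3]))
  expect_equal(qc$sbp[3], 92)
  # SBP 400 outside bounds: first reading dropped, second used
  expect_equal(qc$sbp[4], 118)
  # lossless-with-provenance: every removal is logged
  for (f in c("height", "weight", "glucose", "sbp1", "sbp2", "dbp1", "dbp2")) {
    expect_equal(sum(is.na(qc[[f]])) - sum(is.na(raw[[f]])),
                 sum(log$field == f))
  }
})

test_that("hypertension outcomes and treated-BP adjustment follow the case rules", {
  tab <- data.frame(individual = c("a", "b", "c", "d"),
                    sbp = c(145, 130, 120, 130),
                    dbp = c(92, 80, 70, 80),
                    htn_diagnosis = c("no", "no", "prefer not to answer", "yes"),
                    bp_medication = c("no", "yes", "no", "no"))
  out <- define_outcomes(tab)
  # BP 145/92 above 140/90: case under definition 2, control under 1
  expect_true(out$hypertension_2[1])
  expect_false(out$hypertension_1[1])
  # medication alone makes a definition-2 case
  expect_true(out$hypertension_2[2])
  # non-response: status missing under definition 1
  expect_true(is.na(out$hypertension_1[3]))
  expect_true(out$hypertension_1[4])
  # treated individuals: +15 systolic, +10 diastolic
  expect_equal(out$sbp_adj[2], 145)
  expect_equal(out$dbp_adj[2], 90)
  expect_equal(out$sbp_adj[1], 145)  # untreated unchanged
})

# Transforms -----------------------------------------------------------------

test_that("inverse normal transform is rank-based and standardizing", {
  expect_equal(inverse_normal(c(10, 50, 20))[2], qnorm((3 - 0.5) / 3))
  expect_equal(inverse_normal(c(10, 50, 20))[3], 0)  # median rank -> 0
  set.seed(2)
  x <- rexp(1000)
  z <- inverse_normal(x)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(sd(z), 1, tolerance = 0.02)
  # invariance to monotone input transforms
  expect_equal(inverse_normal(log(x)), z)
  expect_error(inverse_normal(rep(1, 10)), "constant")
  expect_error(inverse_normal(c(1, 2)), "at least 3")
  # missing values preserved in place
  xm <- c(1, NA, 3, 2)
  expect_true(is.na(inverse_normal(xm)[2]))
})

test_that("2-SD standardization centres binaries and halves numeric scales", {
  out <- two_sd_standardize(cbind(b = c(0, 1, 1, 0)), "binary")
  expect_equal(as.numeric(out), c(-0.5, 0.5, 0.5, -0.5))
  out2 <- two_sd_standardize(cbind(x = c(0, 0, 2, 2)), "numeric")
  expect_equal(as.numeric(out2), c(-0.433, -0.433, 0.433, 0.433),
               tolerance = 1e-3)
  set.seed(1)
  out3 <- two_sd_standardize(cbind(x = rnorm(500, 3, 7)), "numeric")
  expect_equal(sd(out3), 0.5, tolerance = 1e-12)
  expect_error(two_sd_standardize(cbind(x = rep(2, 5)), "numeric"),
               "zero variance")
})

test_that("BH step-up matches the hand-computed thresholds", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  # step-up thresholds 0.0125 / 0.025 / 0.0375 / 0.05: first three rejected
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(diff(res$adjusted[order(c(0.01, 0.02, 0.03, 0.5))]) >= 0))
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  expect_length(bh_fdr(numeric(0))$reject, 0)
})

test_that("BH controls the FDR under the all-null simulation", {
  set.seed(8)
  m <- 20
  fdp <- replicate(1000, {
    p <- runif(m)
    mean(bh_fdr(p, q = 0.05)$reject)
  })
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * se)
})

# LD pruning and GRM ---------------------------------------------------------

test_that("LD pruning drops duplicates, keeps independents, satisfies the pair bound", {
  set.seed(6)
  g <- sample(0:2, 40, replace = TRUE)
  dup <- make_geno(rbind(g, g), pos = c(1e4, 1.1e4))
  expect_equal(ld_prune(dup), c(TRUE, FALSE))
  indep <- make_geno(t(vapply(1:5, function(i) sample(0:2, 200, TRUE),
                              numeric(200))), pos = (1:5) * 1e4)
  keep <- ld_prune(indep, r2 = 0.5)
  expect_true(all(keep))
  # property: no kept pair within the window exceeds r2
  for (rep in 1:10) {
    n <- 15
    base <- sample(0:2, 60, replace = TRUE)
    dos <- t(vapply(1:n, function(i) {
      if (runif(1) < 0.5) base else sample(0:2, 60, TRUE)
    }, numeric(60)))
    geno <- make_geno(dos, pos = sort(sample.int(2e5, n)))
    kept <- which(ld_prune(geno, r2 = 0.1, window_kb = 50))
    for (a in kept) for (b in kept) {
      if (a < b && abs(geno$variants$pos[a] - geno$variants$pos[b]) <= 5e4) {
        r <- suppressWarnings(cor(geno$dosage[a, ], geno$dosage[b, ]))
        if (!is.na(r)) expect_lte(r^2, 0.1 + 1e-12)
      }
    }
  }
})

test_that("the GRM matches the hand formula and flags", {
  # one variant, dosages (0, 2), p = 0.5: off-diagonal -2
  geno <- make_geno(matrix(c(0L, 2L), 1), pos = 1e4)
  grm <- compute_grm(geno, maf_min = 0.05, prune = FALSE, n_pcs = 1)
  expect_equal(grm$K[1, 2], -2)
  expect_true(isSymmetric(grm$K))
  # simulated unrelated cohort: trace/n near 1
  set.seed(12)
  m <- 400
  p <- runif(m, 0.1, 0.9)
  dos <- vapply(1:60, function(i) rbinom(m, 2, p), numeric(m))
  geno2 <- make_geno(dos, pos = sort(sample.int(1e8, m)))
  grm2 <- compute_grm(geno2, prune = FALSE)
  expect_equal(mean(diag(grm2$K)), 1, tolerance = 0.1)
  # duplicated individual: off-diagonal close to diagonal
  dos3 <- cbind(dos, dos[, 1])
  grm3 <- compute_grm(make_geno(dos3, pos = geno2$variants$pos), prune = FALSE)
  expect_equal(grm3$K[1, 61], grm3$K[1, 1], tolerance = 1e-9)
  expect_error(compute_grm(geno2, maf_min = 0.99), "no variants")
})

# Association and polygenic scores -------------------------------------------

test_that("the association scan equals per-variant least squares", {
  set.seed(13)
  n <- 60
  g <- sample(0:2, n, replace = TRUE)
  y <- 2 * g
  geno <- make_geno(matrix(g, 1), pos = 1e4)
  res <- assoc_scan(geno, y)
  expect_equal(res$beta, 2, tolerance = 1e-10)
  # with a confounder: equals lm() partial regression
  conf <- g * 0.5 + rnorm(n)
  y2 <- 1.5 * g + 2 * conf + rnorm(n)
  res2 <- assoc_scan(geno, y2, covariates = cbind(conf = conf))
  ref <- summary(lm(y2 ~ g + conf))$coefficients["g", ]
  expect_equal(res2$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(res2$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(res2$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("clump-and-score keeps index variants and weights dosages", {
  # single variant, weight 0.5, dosage 2 -> score 1
  geno <- make_geno(matrix(c(2L, 0L), 1), pos = 1e4)
  sc <- clump_and_score(data.frame(id = "v0001", beta = 0.5, p = 1e-9),
                        geno, pgs_config())
  expect_equal(unname(sc[, "p0.1"]), c(1, 0))
  # duplicate variants: only the smaller-p one contributes
  g <- sample(0:2, 30, replace = TRUE)
  geno2 <- make_geno(rbind(g, g), pos = c(1e4, 2e4))
  sc2 <- clump_and_score(data.frame(id = c("v0001", "v0002"),
                                    beta = c(1, 5), p = c(1e-10, 1e-9)),
                         geno2, pgs_config())
  expect_equal(unname(sc2[, "p0.1"]), g * 1)
  expect_equal(attr(sc2, "retained"), "v0001")
  expect_warning(
    clump_and_score(data.frame(id = "v0001", beta = 1, p = 0.5), geno2,
                    pgs_config(p_thresholds = 1e-8)),
    "no variant")
})

test_that("a true-effect score predicts the trait", {
  set.seed(14)
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 500; m <- 80
    dos <- t(vapply(1:m, function(i) rbinom(n, 2, runif(1, 0.2, 0.8)),
                    numeric(n)))
    beta <- rnorm(m, 0, 0.3)
    y <- as.numeric(crossprod(dos, beta)) + rnorm(n, 0, 2)
    geno <- make_geno(dos, pos = sort(sample.int(1e9, m)))
    stats_df <- assoc_scan(geno, y)
    sc <- clump_and_score(stats_df, geno, pgs_config(p_thresholds = 0.1))
    ct <- cor.test(sc[, 1], y)
    ct$estimate > 0 && ct$p.value < 0.01
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("incremental r2 isolates the score's contribution", {
  set.seed(15)
  n <- 200
  covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- covs[, 1] * 0.5 + rnorm(n)
  s_orth <- rnorm(n)
  expect_lt(incremental_r2(y, s_orth, covs)$delta_r2, 0.03)
  full <- incremental_r2(y, y, covs)
  expect_equal(full$delta_r2, 1 - full$r2_null, tolerance = 1e-10)
  # monotone in the true effect variance
  d <- vapply(c(0.2, 0.6, 1.4), function(b) {
    sc <- rnorm(n)
    yy <- covs[, 1] * 0.5 + b * sc + rnorm(n)
    incremental_r2(yy, sc, covs)$delta_r2
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_error(incremental_r2(y[1:3], s_orth[1:3], covs[1:3, ]), "few")
})
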