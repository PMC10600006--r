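test_that("polarization flips dosages by ancestral allele and computes DAF", {
  dosage <- cbind(c(2L, 1L, 2L, 2L), c(0L, 1L, 0L, 0L),
                  matrix(0L, 4, 8))
  geno <- make_geno(dosage, pos = (1:4) * 1e4,
                    ancestral = c("alt", "ref", "unknown", "ref"))
  expect_message(pol <- polarize_and_daf(geno), "excluding 1")
  expect_equal(nrow(pol$derived), 3L)
  expect_equal(unname(pol$derived[1, 1:2]), c(0L, 2L))  # ancestral = alt flips
  expect_equal(unname(pol$derived[2, 1:2]), c(1L, 1L))  # ancestral = ref keeps
  # DAF hand count: derived dosages (2,0,...,0) over 10 individuals -> 0.1
  expect_equal(unname(pol$daf[3]), sum(c(2, rep(0, 9))) / 20)
  expect_error(polarize_and_daf(make_geno(dosage[1:2, ], pos = c(1, 2),
                                          ancestral = "unknown")),
               "no variant")
})

test_that("polarization is an involution: flipping labels maps d to 2 - d", {
  set.seed(5)
  dosage <- matrix(sample(0:2, 60, replace = TRUE), nrow = 6)
  anc <- sample(c("ref", "alt"), 6, replace = TRUE)
  g1 <- make_geno(dosage, pos = (1:6) * 1e4, ancestral = anc)
  g2 <- make_geno(dosage, pos = (1:6) * 1e4,
                  ancestral = ifelse(anc == "ref", "alt", "ref"))
  d1 <- polarize_and_daf(g1)$derived
  d2 <- polarize_and_daf(g2)$derived
  expect_equal(unname(d1 + d2), matrix(2, 6, 10))
})

test_that("consequence classification follows the controlled vocabulary", {
  expect_equal(classify_consequence("stop_gained"), "lof")
  expect_equal(classify_consequence("splice_acceptor_variant"), "lof")
  expect_equal(classify_consequence("synonymous_variant"), "synonymous")
  expect_equal(classify_consequence("intergenic_variant"), "intergenic")
  expect_equal(classify_consequence("missense_variant", damaging = TRUE),
               "nonsynonymous_deleterious")
  expect_equal(classify_consequence("missense_variant", damaging = FALSE),
               "other")
  expect_equal(classify_consequence("weird_term"), "other")
})

test_that("burden sums derived alleles by class and stratum", {
  derived <- rbind(c(1, 0), c(2, 0), c(0, 1))
  colnames(derived) <- c("a", "b")
  daf <- c(0.02, 0.01, 0.04)
  bt <- compute_burden(derived, daf, rep("lof", 3), tau = 0.05)
  expect_equal(bt$burden[bt$individual == "a" & bt$stratum == "rare"], 3)
  # tau = 1 makes the rare stratum equal the all stratum
  bt1 <- compute_burden(derived, daf, rep("lof", 3), tau = 1)
  expect_equal(bt1$burden[bt1$stratum == "rare"],
               bt1$burden[bt1$stratum == "all"])
  # all-missing individual: burden 0, callable 0
  dm <- derived
  dm[, 2] <- NA
  btm <- compute_burden(dm, daf, rep("lof", 3))
  expect_equal(btm$burden[btm$individual == "b"], c(0, 0))
  expect_equal(btm$callable[btm$individual == "b"], c(0, 0))
  expect_error(compute_burden(derived, daf, rep("lof", 3), tau = 0), "tau")
})

test_that("burden is additive over a partition of classes", {
  set.seed(9)
  derived <- matrix(sample(0:2, 200, replace = TRUE), nrow = 20)
  colnames(derived) <- paste0("i", 1:10)
  daf <- runif(20, 0, 0.5)
  cls <- sample(c("lof", "synonymous"), 20, replace = TRUE)
  parts <- compute_burden(derived, daf, cls)
  union <- compute_burden(derived, daf, rep("lof", 20))
  for (ind in paste0("i", 1:10)) {
    for (str in c("rare", "all")) {
      expect_equal(sum(parts$burden[parts$individual == ind &
                                    parts$stratum == str]),
                   union$burden[union$individual == ind &
                                union$stratum == str])
    }
  }
})

test_that("Spearman correlation matches cor.test's t approximation", {
  set.seed(3)
  derived <- matrix(rpois(15 * 200, 0.2), nrow = 200)
  derived[derived > 2] <- 2
  colnames(derived) <- sprintf("i%02d", 1:15)
  daf <- runif(200, 0, 0.2)
  bt <- compute_burden(derived, daf, rep("intergenic", 200))
  prop <- cbind(A = runif(15))
  rownames(prop) <- sprintf("i%02d", 1:15)
  got <- correlate_burden(bt, prop)
  sub <- bt[bt$stratum == "all", ]
  ref <- suppressWarnings(
    stats::cor.test(prop[sub$individual, "A"], sub$burden,
                    method = "spearman", exact = FALSE))
  expect_equal(got$rho[got$stratum == "all"], unname(ref$estimate),
               tolerance = 1e-12)
  expect_equal(got$p[got$stratum == "all"], ref$p.value, tolerance = 1e-9)
  # perfectly decreasing burden -> rho = -1
  bt2 <- bt[bt$stratum == "all", ]
  bt2$burden <- 100 - seq_len(15)
  class(bt2) <- class(bt)
  prop2 <- cbind(A = as.numeric(seq_len(15)))
  rownames(prop2) <- bt2$individual
  got2 <- correlate_burden(bt2, prop2)
  expect_equal(got2$rho, -1)
})

test_that("the correlation test has nominal type-I error under the null", {
  set.seed(17)
  n <- 20
  hits <- replicate(1000, {
    x <- rnorm(n)
    y <- rnorm(n)
    r <- cor(rank(x), rank(y))
    p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
    p < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("ancestry proportions are recovered by non-negative least squares", {
  set.seed(31)
  m <- 300
  fA <- runif(m, 0.05, 0.95)
  fB <- pmin(pmax(fA + sample(c(-1, 1), m, TRUE) * runif(m, 0.3, 0.5),
                  0.01), 0.99)
  ref <- cbind(A = fA, B = fB)
  # 50 individuals drawn purely at ancestry-A frequencies
  dos <- vapply(1:50, function(i) rbinom(m, 2, fA), numeric(m))
  geno <- make_geno(dos, pos = (1:m) * 1e4)
  est <- estimate_ancestry_proportions(geno, ref)
  expect_lt(mean(abs(est[, "A"] - 1)), 0.05)
  # 50/50 admixture
  dos2 <- vapply(1:50, function(i) {
    rbinom(m, 1, fA) + rbinom(m, 1, fB)
  }, numeric(m))
  est2 <- estimate_ancestry_proportions(make_geno(dos2, pos = (1:m) * 1e4), ref)
  expect_equal(mean(est2[, "A"]), 0.5, tolerance = 0.05)
  expect_error(estimate_ancestry_proportions(geno, cbind(A = fA, B = fA)),
               "rank")
})
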