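# ROH detection ------------------------------------------------------------

test_that("an implanted homozygous run is detected as exactly one segment", {
  set.seed(1)
  # 600 SNPs every 10 kb; heterozygous background, 2 Mb homozygous implant
  pos <- seq(0, by = 1e4, length.out = 600)
  g <- sample(0:2, 600, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  implant <- which(pos >= 2e6 & pos < 4e6)   # 200 SNPs
  g[implant] <- sample(c(0, 2), length(implant), replace = TRUE)
  # guard: flank the implant with heterozygotes so the run is exactly it
  g[min(implant) - 1] <- 1
  g[min(implant) - 2] <- 1
  g[max(implant) + 1] <- 1
  g[max(implant) + 2] <- 1
  geno <- make_geno(matrix(g, ncol = 1), pos)
  seg <- detect_roh(geno, min_length_kb = 1000, min_snps = 50,
                    max_het = 0, max_missing = 0)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, pos[min(implant)])
  expect_equal(seg$end, pos[max(implant)] + 1)
  expect_equal(seg$n_snps, length(implant))
})

test_that("runs below the length threshold and heterozygous individuals yield nothing", {
  pos <- seq(0, by = 1e4, length.out = 100)
  g <- rep(1L, 100)
  g[30:34] <- 0L   # 50 kb homozygous run, far below 1 Mb
  expect_equal(nrow(detect_roh(make_geno(matrix(g, ncol = 1), pos))), 0L)
  expect_equal(nrow(detect_roh(make_geno(matrix(1L, 100, 1), pos))), 0L)
  expect_error(detect_roh(make_geno(matrix(0L, 3, 1), c(3, 1, 2) * 1e6)),
               "unsorted")
})

test_that("detected runs respect het/missing budgets against re-scanned truth", {
  set.seed(7)
  for (rep in 1:10) {
    pos <- seq(0, by = 5e4, length.out = 80)
    g <- sample(c(0L, 1L, 2L, NA), 80, replace = TRUE,
                prob = c(0.42, 0.12, 0.42, 0.04))
    geno <- make_geno(matrix(g, ncol = 1), pos)
    seg <- detect_roh(geno, min_length_kb = 500, min_snps = 5,
                      max_het = 1, max_missing = 2)
    for (i in seq_len(nrow(seg))) {
      inside <- pos >= seg$start[i] & pos < seg$end[i]
      expect_lte(sum(g[inside] == 1L, na.rm = TRUE), 1L)
      expect_lte(sum(is.na(g[inside])), 2L)
      ends <- g[inside][c(1, sum(inside))]
      expect_true(all(ends %in% c(0L, 2L)))  # runs start/end homozygous
      expect_gte(seg$end[i] - seg$start[i], 5e5)
      expect_gte(sum(inside), 5L)
    }
  }
})

# ROH classification --------------------------------------------------------

test_that("ROH classes use half-open Mb bins", {
  gm <- tiny_map(c(`1` = 100))
  mk <- function(mb) add_segment_lengths(segment_table(
    data.frame(chrom = "1", start = 0, end = mb * 1e6, individual = "i"),
    "roh"), gm)
  expect_equal(as.character(classify_roh(mk(5))), "small")
  expect_equal(as.character(classify_roh(mk(8))), "medium")  # boundary
  expect_equal(as.character(classify_roh(mk(20))), "large")
  expect_error(classify_roh(mk(0.5)), "shorter than")
})

# Homozygous-ancestry blocks -------------------------------------------------

test_that("identical and fully discordant haplotypes give the trivial blocks", {
  L <- 1e7
  tr <- two_hap_tracts(list(breaks = c(0, 4e6, L), labels = c("A", "B")),
                       list(breaks = c(0, 4e6, L), labels = c("A", "B")))
  b <- homozygous_ancestry_blocks(tr, "ind1")
  expect_equal(nrow(b), 2L)
  expect_true(all(b$homozygous))
  expect_equal(b$ancestry, c("A", "B"))
  tr2 <- two_hap_tracts(list(breaks = c(0, L), labels = "A"),
                        list(breaks = c(0, L), labels = "B"))
  b2 <- homozygous_ancestry_blocks(tr2, "ind1")
  expect_false(any(b2$homozygous))
})

test_that("blocks match the per-basepair grid oracle on random tract pairs", {
  set.seed(11)
  L <- 1e6
  for (rep in 1:15) {
    tr <- random_tract_pair(L)
    b <- homozygous_ancestry_blocks(tr, "ind1")
    # blocks tile the chromosome
    b <- b[order(b$start), ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], L)
    if (nrow(b) > 1) expect_equal(b$start[-1], b$end[-nrow(b)])
    oracle <- grid_hom_labels(tr, "ind1", "1", L)
    pts <- seq(0, L - 1, by = 1000)
    got <- rep(NA_character_, length(pts))
    for (i in seq_len(nrow(b))) {
      sel <- pts >= b$start[i] & pts < b$end[i]
      if (b$homozygous[i]) got[sel] <- b$ancestry[i]
    }
    expect_identical(got, oracle)
  }
})

# ROH ancestry assignment ----------------------------------------------------

test_that("ROH assignment distinguishes contained/switch/no-overlap and partitions", {
  L <- 1e7
  tr <- two_hap_tracts(list(breaks = c(0, 4e6, 8e6, L), labels = c("A", "B", "A")),
                       list(breaks = c(0, 4e6, 8e6, L), labels = c("A", "A", "B")))
  # homozygous blocks: [0,4e6)=A ; [4e6,8e6) het ; [8e6,L) het
  roh <- segment_table(data.frame(
    chrom = "1",
    start = c(1e6, 3e6, 5e6),
    end = c(2e6, 4.5e6, 6e6),
    individual = "ind1"), "roh")
  out <- assign_roh_ancestry(roh, tr)
  expect_equal(out$status,
               c("assigned", "spans_switch", "no_homozygous_overlap"))
  expect_equal(out$ancestry, c("A", NA, NA))
  # statuses partition the detected set
  expect_equal(sum(table(out$status)), nrow(roh))
})

# IBD gap merging ------------------------------------------------------------

test_that("gap merging follows the 0.6 cM / one-discordant-homozygote rule", {
  gm <- tiny_map(c(`1` = 100))  # 1 cM per Mb
  mkseg <- function(gaps_mb) {
    # consecutive 3 Mb segments separated by the given gaps
    s <- 0; rows <- list()
    for (i in seq_along(gaps_mb)) {
      rows[[i]] <- data.frame(chrom = "1", start = s, end = s + 3e6,
                              hap1 = "i1|0", hap2 = "i2|0")
      s <- s + 3e6 + gaps_mb[i] * 1e6
    }
    rows[[length(gaps_mb) + 1]] <- data.frame(chrom = "1", start = s,
                                              end = s + 3e6,
                                              hap1 = "i1|0", hap2 = "i2|0")
    segment_table(do.call(rbind, rows), "ibd")
  }
  # 0.5 cM gap, no genotypes (0 discordant): merged
  m1 <- merge_ibd_gaps(mkseg(0.5), NULL, gm)
  expect_equal(nrow(m1), 1L)
  # 0.7 cM gap: not merged
  m2 <- merge_ibd_gaps(mkseg(0.7), NULL, gm)
  expect_equal(nrow(m2), 2L)
  # 0.4 cM gap with 2 discordant homozygotes: not merged
  seg <- mkseg(0.4)
  pos <- c(3.1e6, 3.2e6)
  geno <- make_geno(cbind(c(0L, 2L), c(2L, 0L)), pos)
  colnames(geno$dosage) <- c("i1", "i2")
  geno$individuals <- c("i1", "i2")
  m3 <- merge_ibd_gaps(seg, geno, gm)
  expect_equal(nrow(m3), 2L)
  # one discordant homozygote: merged
  geno1 <- make_geno(cbind(c(0L, 0L), c(2L, 0L)), pos)
  colnames(geno1$dosage) <- c("i1", "i2")
  geno1$individuals <- c("i1", "i2")
  expect_equal(nrow(merge_ibd_gaps(seg, geno1, gm)), 1L)
})

test_that("gap merging is transitive, idempotent and never loses coverage", {
  gm <- tiny_map(c(`1` = 100))
  seg <- segment_table(data.frame(
    chrom = "1",
    start = c(0, 3.4e6, 6.8e6),
    end = c(3e6, 6.4e6, 9.8e6),
    hap1 = "a|0", hap2 = "b|1"), "ibd")
  m <- merge_ibd_gaps(seg, NULL, gm)   # both 0.4 cM gaps chain-merge
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0)
  expect_equal(m$end, 9.8e6)
  m2 <- merge_ibd_gaps(m, NULL, gm)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  expect_gte(sum(m$end - m$start), sum(seg$end - seg$start))
  expect_warning(merge_ibd_gaps(segment_table(data.frame(
    chrom = "1", start = c(0, 1e6), end = c(2e6, 3e6),
    hap1 = "a|0", hap2 = "b|1"), "ibd"), NULL, gm), "overlapping")
})

# Ancestry-specific IBD ------------------------------------------------------

test_that("ancestry masking intersects both haplotypes and applies the 2 cM floor", {
  gm <- tiny_map(c(`1` = 100))
  tr <- ancestry_tracts(rbind(
    data.frame(chrom = "1", start = c(0, 3e6), end = c(3e6, 1e8),
               individual = "i1", haplotype = 0, ancestry = c("A", "B")),
    data.frame(chrom = "1", start = 0, end = 1e8,
               individual = "i2", haplotype = 1, ancestry = "A")))
  seg <- segment_table(data.frame(chrom = "1", start = 0, end = 5e6,
                                  hap1 = "i1|0", hap2 = "i2|1"), "ibd")
  out <- ancestry_specific_ibd(seg, tr, gm, "A")
  expect_equal(nrow(out), 1L)          # 3 cM piece of the 5 cM segment
  expect_equal(out$length_cm, 3)
  expect_equal(out$end, 3e6)
  # identity when both haplotypes carry A everywhere
  tr2 <- ancestry_tracts(rbind(
    data.frame(chrom = "1", start = 0, end = 1e8, individual = "i1",
               haplotype = 0, ancestry = "A"),
    data.frame(chrom = "1", start = 0, end = 1e8, individual = "i2",
               haplotype = 1, ancestry = "A")))
  out2 <- ancestry_specific_ibd(seg, tr2, gm, "A")
  expect_equal(out2$start, 0)
  expect_equal(out2$end, 5e6)
  # below threshold: 1.5 cM shared region is dropped
  seg3 <- segment_table(data.frame(chrom = "1", start = 0, end = 1.5e6,
                                   hap1 = "i1|0", hap2 = "i2|1"), "ibd")
  expect_equal(nrow(ancestry_specific_ibd(seg3, tr, gm, "A")), 0L)
  # masked lengths never exceed the input length
  expect_lte(sum(out$length_cm), 5)
})

test_that("shared-ancestry pair length matches the grid oracle", {
  set.seed(23)
  gm <- tiny_map(c(`1` = 10))  # 10 Mb at 1 cM/Mb
  L <- 1e7
  for (rep in 1:10) {
    t1 <- random_tract_pair(L, individual = "i1")
    t2 <- random_tract_pair(L, individual = "i2")
    tr <- ancestry_tracts(rbind(as.data.frame(t1), as.data.frame(t2)))
    pairs <- data.frame(hap1 = "i1|0", hap2 = "i2|1")
    got <- ancestry_pair_length(tr, gm, "A", pairs) * 100  # cM
    oracle <- grid_shared_cm(tr, "i1|0", "i2|1", "A", "1", L)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
  expect_error(ancestry_pair_length(ancestry_tracts(as.data.frame(
    random_tract_pair(L))), gm, "A", data.frame()), "non-empty")
})
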