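# Shared fixtures and independent brute-force oracles.

tiny_map <- function(cm = c(`1` = 100), rate = 1) {
  uniform_genome_map(cm, rate_cm_per_mb = rate)
}

# Genotype matrix from an explicit dosage matrix and positions (one chrom).
make_geno <- function(dosage, pos, chrom = "1", ancestral = "ref") {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  genotype_matrix(
    dosage,
    data.frame(id = sprintf("v%04d", seq_len(n)), chrom = chrom, pos = pos,
               ref = "A", alt = "G",
               ancestral = rep_len(ancestral, n)),
    paste0("ind", seq_len(ncol(dosage))))
}

# Tracts for one individual, both haplotypes, from breakpoint/label specs:
# each of h0/h1 is list(breaks = c(0, ..., L), labels = c(...)).
two_hap_tracts <- function(h0, h1, individual = "ind1", chrom = "1") {
  mk <- function(h, hap) {
    data.frame(chrom = chrom, start = h$breaks[-length(h$breaks)],
               end = h$breaks[-1L], individual = individual,
               haplotype = hap, ancestry = h$labels)
  }
  ancestry_tracts(rbind(mk(h0, 0L), mk(h1, 1L)))
}

# Brute-force per-basepair (1 kb grid) homozygous-ancestry labels.
grid_hom_labels <- function(tracts, individual, chrom, L, step = 1000) {
  pts <- seq(0, L - 1, by = step)
  lab <- function(hap) {
    sub <- tracts[tracts$individual == individual &
                  tracts$haplotype == hap & tracts$chrom == chrom, ]
    sub <- sub[order(sub$start), ]
    sub$ancestry[findInterval(pts, sub$start)]
  }
  l0 <- lab(0L)
  l1 <- lab(1L)
  ifelse(l0 == l1, l0, NA_character_)
}

# Brute-force shared-ancestry genetic length on a 1 kb grid (uniform map).
grid_shared_cm <- function(tracts, hapA, hapB, ancestry, chrom, L,
                           rate_cm_per_bp = 1e-6, step = 1000) {
  pts <- seq(0, L - 1, by = step)
  lab <- function(hp) {
    ind <- sub("\\|[01]$", "", hp)
    h <- as.integer(sub("^.*\\|", "", hp))
    sub <- tracts[tracts$individual == ind & tracts$haplotype == h &
                  tracts$chrom == chrom, ]
    sub <- sub[order(sub$start), ]
    sub$ancestry[findInterval(pts, sub$start)]
  }
  sum(lab(hapA) == ancestry & lab(hapB) == ancestry) * step * rate_cm_per_bp
}

# Random tract pair on [0, L) with k breakpoints per haplotype.
random_tract_pair <- function(L, labels = c("A", "B", "C"), k = 5,
                              individual = "ind1") {
  hap <- function() {
    brk <- sort(sample(seq(1000, L - 1000, by = 1000), k))
    list(breaks = c(0, brk, L),
         labels = sample(labels, k + 1, replace = TRUE))
  }
  two_hap_tracts(hap(), hap(), individual = individual)
}

# Poisson goodness-of-fit p-value pooling bins to expected >= 5.
pooled_chisq_p <- function(obs, expected) {
  o <- numeric(0); e <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(expected)) {
    co <- co + obs[i]; ce <- ce + expected[i]
    if (ce >= 5) {
      o <- c(o, co); e <- c(e, ce); co <- 0; ce <- 0
    }
  }
  if (ce > 0 && length(e)) {
    e[length(e)] <- e[length(e)] + ce
    o[length(o)] <- o[length(o)] + co
  }
  if (length(e) < 2L) return(NA_real_)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(e) - 1, lower.tail = FALSE)
}
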