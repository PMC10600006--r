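---
title: "Models and methods behind tractpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tractpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tractpop)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic-cohort tests do and do not
establish about real data.

## Coordinates and genetic lengths

All intervals are 0-based half-open, on disk and in memory. Every
genetic-length computation — tract lengths, the 0.6 cM gap rule, the
2 cM IBD floor — flows through a `genome_map`, a per-chromosome table of
(bp, cM) anchors interpolated piecewise-linearly. Queries outside the
anchored range are clamped with a warning, never extrapolated: a genetic
map carries no information beyond its anchors, and silent extrapolation
is a classic source of corrupted length spectra.

## Segment algebra

**ROH detection** scans each individual's sorted calls left to right for
maximal homozygous runs tolerating at most `max_het` heterozygous and
`max_missing` missing calls, with minimum span and marker count. The
defaults (1 Mb, 50 markers, 1 het, 2 missing) approximate common
array-data practice; only the 1 Mb floor is load-bearing for the
package's own analyses, and all four are configuration keys. Runs start
and end at homozygous markers and ties break toward the longer run.
Detection quality depends strongly on marker density: at the sparse
densities of the bundled demos (a few markers per Mb), short chance runs
of homozygous common genotypes are called alongside true autozygosity.
This is a property of sparse data, not of the algorithm, and it is why
the generator *implants* autozygous runs and records them as ground
truth — implantation gives detection tests an exact expected answer,
where emergent autozygosity would not.

**Ancestry assignment of ROH** first computes homozygous-ancestry
blocks — maximal regions where both haplotypes carry the same label —
then requires *full containment* of a run in a single block for an
`assigned` status. A run that touches a homozygous block but crosses its
boundary is `spans_switch`; one touching no homozygous block is
`no_homozygous_overlap`. Whether partial overlap without a label change
should count as assigned is genuinely ambiguous; we chose containment
because it makes the three statuses a clean partition whose counts
always total the detected set, with switch-spanning runs isolated the
way ancestry-stratified ROH analyses isolate them. Only `assigned` runs
enter ancestry-specific summaries.

**IBD gap merging** joins same-pair segments when the intervening gap is
shorter than 0.6 cM *and* contains at most one discordant homozygote
(opposite homozygous genotypes contradict shared descent). The rule is
applied transitively — a merged segment can absorb the next gap — in a
single left-to-right pass whose fixed point we verify by idempotence
tests. Whether transitive application is the right reading of the
upstream convention is not documented anywhere we could check; we chose
transitivity because the alternative makes the result depend on
arbitrary segment ordering.

**Ancestry masking** intersects a segment with the regions where *both*
carrier haplotypes carry the query ancestry, and applies the 2 cM floor
to the post-intersection genetic length. Applying the floor after
masking matches the intent of ancestry-specific analyses: a 5 cM segment
with only 1.5 cM of shared-ancestry support carries less than the
detection threshold's worth of within-ancestry signal.

## Effective population size from IBD length spectra

The model is the standard Poisson coalescent mixture. Two haplotypes
coalesce at generation $g$ with probability
$P(g) = \frac{1}{2N_g}\prod_{k<g}\bigl(1-\frac{1}{2N_k}\bigr)$ under
piecewise-constant diploid sizes; conditional on $g$, segment lengths
$\ell$ (Morgans) contribute expected bin counts
$L\,2g\,(e^{-2g\ell_1}-e^{-2g\ell_2})$ per unit of analysed pair-genome
length $L$ (the total shared-ancestry genetic length summed over
haplotype pairs). Chromosome-edge effects are ignored, as is any error
model for IBD detection; both are second-order at the ≥ 2 cM lengths the
package analyses, and the simulator draws from exactly this forward
model, so parameter-recovery tests are true oracle tests of the
estimator rather than of the approximation.

`fit_ne()` maximizes the penalized Poisson log-likelihood
$\sum_b (n_b\log\mu_b-\mu_b) - \lambda\sum_g(\Delta\log N_g)^2$ over
$\log N_g$ for $G$ free generations (default 60), with a constant
analytic tail beyond $G$ and a hard floor $2N \ge 1$. Optimization is
bounded L-BFGS from three fixed constant starts ($10^3, 10^4, 10^5$);
the best converged start wins, making the fit deterministic. The
penalty weight defaults to $\lambda = 1$, which in the recovery
experiments shipped in the acceptance suite keeps the median absolute
error of a constant $N = 5{,}000$ trajectory under 20% over generations
5–50 (with 30 Morgans × 2,000 pairs of exposure) while still localizing
a 20-fold bottleneck at generations 10–15 to within a few generations.
Very large $\lambda$ provably flattens the fit to a constant, which the
tests assert as the limiting behaviour. Bin edges are not prescribed by
the analysis convention upstream; the default widens multiplicatively
from the 2 cM floor, and both edges and $G$ are arguments. The
bootstrap resamples carrier *pairs*, not segments, because segment
counts within a pair share the pair's coalescent history.

## Mutation burden

Burden is the per-individual sum of derived allele copies. Variants with
an unknown ancestral allele are excluded rather than assumed
ref-ancestral: mistaking even a small fraction of high-frequency
reference alleles for derived alleles inflates every individual's sum
systematically. The derived allele frequency is computed cohort-wide
(the natural choice when no external panel is attached; a per-ancestry
variant is exposed as a flag-level alternative through the frequency
table the generator returns). Missing genotypes contribute zero and
decrement a callable-variant count per individual and class, so
missingness is visible rather than silently absorbed; normalized
burdens (sum / callable) are a one-line division the caller can apply.
Spearman correlations use mean ranks for ties with the two-sided
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation, which the tests verify
against `cor.test` and calibrate under the null.

## Trait models

Phenotype QC is lossless-with-provenance: every removed value becomes
`NA` *and* a reason-coded log row, so removed + retained = input holds
field by field. For discordant blood-pressure reading pairs (difference
above 20 units) the second reading is removed — with two readings and no
third arbiter, the pair rule cannot identify the faulty one, and
preferring the first reading matches the "first valid reading, else
second" convention used to form the analysis values. Readings breaking
absolute bounds or with diastolic above systolic are identifiable
individually and removed individually. The two hypertension definitions
(diagnosis-only; diagnosis or medication or BP > 140/90) and the
+15/+10 treated-BP adjustment are implemented exactly as stated by the
QC rules object, and non-yes/no questionnaire responses leave
case-control status missing.

The inverse-normal transform maps mean ranks through
$\Phi^{-1}((r-0.5)/n)$ (the Blom offset is an option); the 2-SD
standardization divides numeric predictors by twice their standard
deviation and centres binary ones, putting both on comparable
coefficient scales (numeric columns end up with SD 0.5 by construction).

The GRM is the standard standardized-dosage estimator
$K = \frac{1}{m}\sum_v (x_v-2p_v)(x_v-2p_v)^\top / (2p_v(1-p_v))$ after
MAF ≥ 5%, exclusion-region and LD-pruning (r² > 0.1 / 50 kb / step 1)
filters, with missing dosages mean-imputed. A structure-robust kinship
decomposition (partitioning relatedness from ancestry before estimating
kinship) is a substantial project in itself and is out of scope; the
package uses the plain GRM and documents that the locality and ancestry
fixed effects absorb much, not all, of the confounding such estimators
address. PCs come from the eigendecomposition of $K$; per convention the
association scan uses 4 and the polygenic-score null model 10.

The mixed model $y = X\beta + u + c + \varepsilon$ with
$u\sim(0,\sigma_g^2 K)$, $c\sim(0,\sigma^2_{loc}ZZ^\top)$,
$\varepsilon\sim(0,\sigma_e^2 I)$ is fitted by REML with the residual
variance profiled out analytically, leaving a two-parameter bounded
search over log variance ratios (Nelder–Mead, three fixed starts; Brent
when the locality term is absent). Dense Cholesky factorizations make
this exact and adequate at the package's design scale of
$n \lesssim 2{,}000$; no sparse or low-rank tricks are used. Fixed
effects are GLS at the optimum with Wald $z$ tests, $1.96\,SE$
intervals and BH FDR flags across non-intercept terms. Locality effects
are flat (not nested in any higher unit): nesting conventions vary and a
flat effect is the least-structured default.

Polygenic scores use greedy clumping by ascending p (index variant
kept; within-window variants at r² > 0.1 removed) and
effect-size-weighted allele sums at thresholds 0.1, 0.01, 0.001, 1e-5,
1e-8. The clumping window defaults to 250 kb — a conventional
magnitude, stated nowhere authoritative for this pipeline, and left
configurable. Incremental r² is the difference in r² between the
covariates-plus-score and covariates-only models.

## The synthetic cohort

The generator is the package's study-conditions statement, not a tuning
surface; its defaults are fixed once and the tests run at them.

- **Admixture**: a single pulse `g_admix` generations ago (default 15,
  a plausible colonial-era depth at ~25–30 years per generation);
  breakpoints are a homogeneous process at rate $g$ per Morgan and each
  breakpoint-delimited tract draws its label independently with the
  stationary proportions (default 0.5/0.4/0.1). This is the simplest
  model with the exponential tract-length signature; multi-wave
  admixture and correlated neighbouring labels are real-data features
  the generator does not emulate.
- **Frequencies**: ancestral derived frequencies follow a truncated
  $1/x$ density on $[\max(1/4N_0, 0.01), 0.5]$; the 0.01 floor emulates
  a genotyping array's ascertainment against private variants. A
  bottleneck is `t_b` generations of Wright–Fisher binomial resampling
  with $2N_b$ gametes (default $N_b = 300$, $t_b = 15$, a strong
  founder event), which reproduces the loss of rare variants without a
  coalescent dependency. Linkage disequilibrium between variants is
  *not* simulated; LD-dependent steps (pruning, clumping) are therefore
  tested on constructed duplicates rather than on the cohort.
- **IBD**: per-pair bin counts are Poisson with the exact
  `expected_spectrum` means on the pair's shared-ancestry length;
  lengths are drawn from the within-bin coalescent mixture and positions
  placed uniformly in shared regions. Generator and estimator share one
  forward model by construction — the central oracle link.
- **ROH** are implanted (haplotype 1 copied from haplotype 0 over a
  Poisson number of 1.5–6 Mb runs), giving detection an exact truth set.
- **Phenotypes**: $y$ sums per-SD coefficients on a true polygenic
  score, the focal-ancestry proportion, total implanted ROH length and
  an urban indicator, plus GRM-correlated genetic noise, locality
  effects and i.i.d. error. Covariates (sex, birth year 1910–1980,
  urban/rural, educational attainment 0–8, Indigenous-language flag,
  locality) are simulated alongside; enrichment-style non-random
  sampling of language speakers is intentionally not emulated.
- **Seeds**: one global seed; each stage derives a deterministic child
  seed from (seed, stage name), recorded in the manifest, so identical
  configs give byte-identical bundles.

### What the tests show, and what they do not

Passing tests establish that the estimators recover the truth *under
their own model assumptions* at the stated problem sizes: tract lengths
follow the pulse law, Ne fits invert the spectrum model, burden
correlations point the way a bottleneck pushes them, REML recovers
variance mixtures. They do not establish robustness to phasing or
local-ancestry inference error, IBD detection false negatives, LD,
genotyping batch effects, or model misspecification in real cohorts —
all of which sit upstream of this package's inputs by design.

### Numerical and problem-size choices

Monte-Carlo checks of the tract-length law use a long chromosome
(10,000 cM) so that boundary-censored end tracts — which bias every
finite-chromosome average of tract length downward via the inspection
paradox — are a negligible fraction of roughly $10^5$ tracts; on a
single 100 cM chromosome at $g = 10$ the all-tract average sits near
9.1 cM for this reason, and no averaging scheme on that geometry reaches
the asymptotic 10 cM. Ne recovery runs at 30 Morgans × 2,000 pairs
(~7,500 segments), burden direction at 100 individuals × 3,000 variants
× 20 seeds, REML recovery at $n = 800$ × 20 seeds, chosen as the
smallest sizes at which the corresponding sampling distributions are
decisively informative. Degenerate inputs error early and loudly:
empty spectra, rank-deficient designs, non-PSD kinship matrices,
constant vectors to rank transforms, zero-variance numeric predictors.

## Known limitations

- Per-variant OLS stands in for whole-genome regularized association;
  at biobank scale the latter's calibration advantages matter.
- The plain GRM conflates ancestry and relatedness; see above.
- ROH detection over-calls at sparse marker density (documented above).
- The Ne model ignores chromosome edges and detection error, so very
  recent (< 4–5 generations) sizes are weakly identified from ≥ 2 cM
  spectra, and bootstrap bands should be read accordingly.
- The CLI wrapper is a thin convenience over `run_pipeline()`; the R
  functions are the supported interface.
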