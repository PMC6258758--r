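---
title: "Models and methods behind sibtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sibtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sibtrace implements the computational core of a low-coverage ancient-DNA
admixture study: pseudohaploid genotyping from pileups, authentication
(genetic sex, terminal deamination, contamination power), f-statistics with
block-jackknife errors, qpWave/qpAdm admixture modelling with a
rotating-outgroup search, weighted admixture-LD dating, least-squares PCA
projection, and radiocarbon calibration. This vignette documents the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic-data experiments can show.

## The synthetic-data generator

Everything in the test suite and the acceptance script runs on data from the
package's own generator, so it is worth being precise about what it emulates.

**Allele frequencies.** Populations drift independently from a shared
ancestral frequency `p ~ Uniform(0.05, 0.95)` under the Balding–Nichols
model: `p_pop ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `E[p_pop] = p` and
`Var(p_pop) = F p(1-p)`. `F` is the per-population drift parameter (values
of 0.05–0.3 correspond to the differentiation between continental human
groups and deeply diverged outgroups). Admixed populations take
`alpha * p_A + (1 - alpha) * p_B` and then drift by their own `F`. Sites are
unlinked here: f-statistics need many independent sites, not maps.

**Haplotypes and admixture LD.** For dating experiments, source haplotypes
are Bernoulli draws per site and admixed populations are produced by `g`
generations of haploid Wright–Fisher random mating with crossovers arriving
as a Poisson process of rate 1 per Morgan. Founder ancestry is carried along
the same crossovers, so the local-ancestry covariance between sites at
genetic distance `d` decays — per meiosis — by the Haldane transmission
probability `(1 + exp(-2d))/2`, i.e. as `((1+e^{-2d})/2)^g ≈ e^{-gd}` after
`g` generations. Two deliberate choices keep the output in the regime the
exponential model describes:

* the breeding population (default 2000 haplotypes, `n_pop`) is much larger
  than the output sample, so post-admixture drift LD — which decays on the
  much slower timescale of coalescence — stays negligible relative to
  admixture LD;
* parents are drawn independently per chromosome. In the large-population
  limit the chromosomes of an individual descend from effectively disjoint
  lineages; drawing parents per chromosome realizes that limit exactly and
  makes per-chromosome statistics independent, which is also the assumption
  behind the chromosome-level jackknife used downstream.

The default map fixture is 3 chromosomes of 100 cM with uniformly spaced
sites — desk-scale, not a human map. Genetic positions restart at zero on
each chromosome.

**Reads.** Per site, read depth is Poisson with mean
`mean_depth * copies / 2` (`copies` models sex chromosomes: 1 on male X/Y, 0
on female Y). Each read templates one of the two alleles uniformly; 5'
C→T deamination is applied with probability `delta0 * k^position` in read
orientation (appearing as G→A on minus-strand reads in pileup orientation),
then sequencing error substitutes uniformly among the other three bases.
This is a single-strand (UDG-half-like) damage model: the 3' G→A profile of
untreated double-stranded libraries is *not* simulated, and the profiler
will correctly report it near the error floor.

What passing tests on these data do **not** show: robustness to reference
bias, mapping artefacts, non-uniform recombination maps, background LD
within source populations, or ascertainment of the SNP panel. All of those
are real-data effects outside the generator's scope.

## Pseudohaploid genotyping

Observations are filtered by base and mapping quality (default 30/30, the
`samtools mpileup -q 30 -Q 30` convention) and by an end-trim: reads
support a call only from positions at least `trim_bases` (default 2) away
from either read end, which removes the positions dominated by residual
deamination in half-treated libraries. Trimming observations at the caller
has the same effect as trimming the reads themselves, without rewriting
alignments. One surviving read is then drawn uniformly at random and the
individual is recorded homozygous for its base; bases matching neither
panel allele (and `N`) yield missing — a conservative choice that matches
the downstream model, which has no representation for third alleles. The
draw happens *after* filtering and trimming, so a trimmed-off read can
never be chosen. The random draw is keyed by (individual, site) through a
counter-based hash, making calls independent of the order in which reads
were parsed, and bit-reproducible for a given caller seed.

Transversions-only mode masks `{C,T}` and `{G,A}` sites, the standard guard
for untreated libraries where post-mortem deamination mimics transitions.
The coverage QC keeps individuals with at least 15,000 non-missing
autosomal calls by default.

The deamination profiler is reference-based: at distance `i` from the 5'
end it reports (reference-C positions read as T) / (reference-C positions
observed), in read orientation, with the mirrored G-to-A count from the 3'
end. On an all-SNP panel a reference-C site is an "opportunity" even when
the individual carries the alternative allele, so profiles measured on
polymorphic sites are diluted by roughly the mean alternative-allele
frequency relative to profiles on monomorphic positions — visible in the
demo pipeline, whose ancient individuals are heterozygous-in-expectation at
every site. Oracle tests therefore use reference-homozygous genotypes,
where the profile equals the simulator's `delta0 * k^i` exactly.

## Sex determination

With read counts per chromosome class, `x_rate` is X coverage over
autosomal coverage and `y_rate` likewise for Y; females are expected at
(1, 0) and males at (0.5, 0.5). Errors treat each class's read total as a
Poisson count and propagate the ratio to first order:
`se = rate * sqrt(1/n_reads_class + 1/n_reads_aut)`; a zero read count is
propagated at one-count scale so its SE is finite. The classification bands
(`XX` when `x_rate - 2 se_x > 0.75` and `y_rate + 2 se_y < 0.1`; `XY` when
`|x_rate - 0.5| < 2 se_x + 0.1` and `y_rate - 2 se_y > 0.3`;
`consistent-with-` when only one criterion of a pair binds; otherwise
undetermined) are this package's own, deliberately conservative: at very
low coverage the honest answer is "undetermined", never a cross-call.

## f-statistics and the block jackknife

With population allele-frequency estimates (diploid calls contribute two
allele copies, pseudohaploid calls one), the per-site contributions are

* `f3(C; A, B)`: `(c - a)(c - b) - c(1-c)/(n_c - 1)`, the correction
  removing the upward bias from sampling noise in the target frequency;
  significantly negative values indicate admixture in C between populations
  related to A and B. For targets represented only by pseudohaploid
  individuals the correction is omitted with a warning (within-individual
  heterozygosity cannot be estimated); such f3 values are biased upward and
  comparable only among themselves.
* `f4(A, B; C, D)`: `(a - b)(c - d)`, no correction needed.

Sites enter a statistic when all its populations are observed there
(per-statistic intersection — the `allsnps` convention), with `n_c >= 2`
when the f3 correction is active. Estimates are weighted means over
contiguous 5 cM blocks (falling back to 700 equal-count blocks without a
map); standard errors come from the weighted delete-one-block jackknife
(Busing's formula), which reduces to the textbook delete-one jackknife at
equal weights — a tested identity.

## qpWave and qpAdm

The f4 matrix has rows `f4(S_i, T; R_j, R_1)` over sources `S` against
rights `R`, each cell on its own maximal site set (`allsnps = TRUE`), with
the covariance of `vec(X)` from delete-one-block replicates. Covariance
matrices are inverted through an eigenvalue floor at `1e-12 * trace` —
jackknife covariances are rank-deficient whenever blocks are few.

`qpwave_rank(fm, r)` minimizes the chi-square distance to a rank-`r`
matrix under that covariance (alternating generalized least squares on the
factor pair, 5 seeded restarts, objective tolerance `1e-10`), with
`dof = (|L|-1-r)(|R|-1-r)` and an upper-tail chi-square p-value. The dof
convention is standard Wishart-LRT counting, verified against the closed
rank-0 case; it is documented behaviour, not claimed bit-identical to other
implementations.

`qpadm_fit` estimates weights by minimizing `(w'X) Sigma_w^+ (X'w)` subject
to `sum(w) = 1`, re-linearizing `Sigma_w` (the covariance of the projected
vector) by fixed-point iteration from equal weights, stopping at
`||dw|| < 1e-8` (max 100 iterations; non-convergence is an error carrying
the iterate trace). With one source this statistic is *exactly* the rank-0
qpWave test — a tested identity. Weight SEs refit every delete-one-block
replicate; the model p-value uses `dof = |R| - k`. A model is feasible when
all weights lie in `[0, 1]` (tolerance `1e-6`).

The model search follows the protocol: fit the full source set on the
first outgroup set; while `p >= 0.05` but a weight is negative, drop the
most negative source and refit; if no working model emerges, advance to
the next outgroup set. Because the reporting convention is the *minimal*
feasible model, a working model is then greedily reduced — drop the
smallest-weight source while the reduction still works. Every fit is
logged in the returned trial table.

## Admixture-LD dating

For every intra-chromosome site pair within `max_d` (default 30 cM) the
curve accumulates `z(x, y) * delta(x) * delta(y)`, where `z` is the sample
covariance of target genotypes (pairwise-complete for pseudohaploid
targets, whose 0/2 calls still carry covariance proportional to admixture
LD) and `delta` is the reference allele-frequency difference. Bins are
0.05 cM wide; cross-chromosome pairs are excluded (no inter-chromosome
affine correction is implemented).

The fit is weighted least squares of `a(d) = A exp(-g d) + c` (weights =
pair counts, `d` in Morgans so `g` is in generations), from 1 cM — below
which unmodelled short-range LD intrudes — up to 20 cM by default. The
upper limit is a bias control: the true per-meiosis transmission function
is Haldane's `(1+e^{-2d})/2`, and fitting a pure exponential over 1–30 cM
understates `g` by ~3.5% at `g = 17`, while 1–20 cM keeps the
approximation error under ~2%. The affine term `c` absorbs
population-substructure offsets. Starting values come from a log-linear
regression of the tail-corrected curve; the optimizer is
Levenberg–Marquardt (`minpack.lm`) with a `port` fallback. Fits with
`g <= 0` or failed convergence are returned flagged as "no decay", never
silently.

Standard errors jackknife the *entire* pipeline — curve re-aggregation
plus refit — over chromosomes. With the 3-chromosome desk fixture that
jackknife has only 2 degrees of freedom; its SE estimate is unbiased in
our calibration experiments (mean SE ≈ replicate SD) but individual SE
draws are volatile, which is the price of a 3-chromosome genome and is
discussed wherever coverage statements are made. Calendar conversion is
`t = sample_age + 29 g` years BP (generation time configurable) with
first-order error propagation `se_t = sqrt(se_age^2 + (29 se_g)^2)`.

## PCA projection

The reference panel is centered by twice the allele frequency and scaled
by `sqrt(p(1-p))`; monomorphic sites are dropped; the eigendecomposition
of the individual-by-individual covariance gives orthonormal site loadings.
Samples with missingness are projected by ordinary least squares restricted
to their observed sites ("lsqproject") — missing sites are excluded, not
mean-imputed, which is what makes the projection unbiased under random
masking (a tested property at 80% missingness). The optional shrink
correction estimates per-PC factors by leave-one-out projection of panel
members (through-origin regression of projected on fitted scores, clipped
to `(0, 1]`); it is off by default and is an approximation of smartpca's
unpublished "shrinkmode", not a replication of it.

## Supervised ancestry and contamination power

With cluster frequencies frozen, the decomposition maximizes the binomial
mixture likelihood over the proportion simplex by EM (tolerance `1e-8` on
the log-likelihood, max 2000 iterations; the log-likelihood is
non-decreasing by construction and this is asserted in tests). Reference
frequencies are clamped away from 0 and 1 (`1/(2n+1)` for an `n`-diploid
reference) to keep the likelihood finite. Near-boundary solutions converge
slowly; results carry a convergence flag rather than being truncated.

The power experiment contaminates clean pseudohaploid replicates at each
rate (each call independently replaced with probability `r` by a draw from
the contaminant's frequencies), decomposes them, and flags a replicate when
the summed proportion on clusters *outside* the individual's true ancestry
exceeds the clean-replicate mean plus 3 SD. The 3-SD rule is this
package's operationalization — only the outcome ("detectable at 5–8% for
distant contamination, undetectable for closely related contamination") is
inherited from practice, and both behaviours are asserted in the tests:
related contaminants produce near-zero power because their reads are
absorbed by the individual's own clusters.

## Radiocarbon calibration

The posterior over calendar age on a 1-year grid is
`N(r; mu(theta), sigma_r^2 + sigma_curve(theta)^2)` with a flat prior,
`mu` and `sigma_curve` linearly interpolated from the curve. The
normalization factor `1/sqrt(var)` is kept since the curve error varies
with `theta`. Highest-density regions are built by density thresholding
with ties broken toward older years; an error is raised when posterior
mass piles up at the grid edges beyond three times the uniform share
(a truncated curve), while genuinely flat posteriors are allowed. OxCal's
rounding conventions are not replicated; comparisons to published
calibrated dates should allow ±15 years on the mean. The package ships no
calibration curve: IntCal tables are loaded from a user-supplied `.14c`
file.

## Problem sizes

The acceptance experiments use desk-scale designs chosen to make their
Monte-Carlo error small relative to the tested tolerances: 10,000–30,000
unlinked sites and 25–30 diploids per population for f-statistics and
qpAdm (50 recovery replicates), 3×100 cM with 15,000 sites and 400 output
haplotypes for dating (20 replicates), 20,000 sites, 6 clusters and 50
replicates per rate for contamination power, and 200 individuals at 0.5×
for sex determination.
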