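---
title: "Stepwise coalescent demography from ddRAD site-frequency spectra"
author: "coalstep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise coalescent demography from ddRAD site-frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalstep)
```

# The scientific problem

Reduced-representation sequencing (ddRAD-seq) of a few dozen individuals
per species yields thousands of short loci scattered across the genome —
enough to summarize standing variation as a site-frequency spectrum
(SFS), but far from whole genomes.  `coalstep` implements the full
analysis chain from a multi-sample VCF of such data to demographic
history in biological units: genotype filtering, genetic sexing for
ZW-system birds, diversity and divergence statistics, folded and masked
spectra, a stepwise time-interval model of effective population size
fitted by composite likelihood, two-population model comparison, and the
conversion of coalescent-scaled estimates into individuals and years.
A coalescent simulator with known ground truth backs every stage, so the
whole pipeline is testable without any sequencing data.

# The data model and filtering

Genotypes live in a `GenotypeMatrix`, a `RangedSummarizedExperiment`
whose rows are sites (1-based VCF coordinates) and whose columns are
samples, with the two called allele indices and a per-allele read-depth
array as assays.  `filterSites()` applies the retention regime typical
of ddRAD studies, with each rule acting at its natural unit:

* **per-allele depth** (default 5 reads per called allele, i.e. 10x for
  a heterozygous genotype): a genotype whose support falls below the
  threshold is set missing, not deleted with its site, because depth is
  a property of the call;
* **site quality** (PHRED >= 30) invalidates every call at a failing
  site;
* **presence** (>= 80% of alleles called) then drops sites on the
  *post*-invalidation matrix.

`extractBiallelicSnps()` keeps sites at which exactly two alleles
remain observed.  Deviation from Hardy–Weinberg proportions is a
symptom of allelic dropout, so `hweScreen()` runs the exact conditional
test (no chi-square approximation, no mid-p) per site *within each
population* — pooling populations would manufacture heterozygote
deficits out of mere structure (the Wahlund effect).  Flagged sites are
reported, not removed; at the default `alpha = 1e-6` a flag requires
overwhelming evidence.

A reading note on "80% of alleles present": we count alleles (two per
diploid call), which for whole-genotype missingness coincides with
counting genotypes; the distinction would only matter for half-called
genotypes, which we normalize to missing on input.

# Genetic sexing

In birds, males are ZZ and females ZW, so a female yields roughly half
the male sequencing depth on Z-linked loci and no true Z
heterozygosity.  `assignSex()` computes each sample's mean Z to mean
autosomal depth ratio, normalizes the cohort by the upper mode of that
ratio distribution (the male mode, found by a 1-D two-cluster split),
and calls **female** only when both evidence lines agree (normalized
ratio <= 0.65 *and* Z/autosomal heterozygosity ratio <= 0.1), **male**
on depth alone (ratio >= 0.85), and **unassigned** otherwise — a
conflicted sample is surfaced, never forced.  The thresholds bisect the
theoretical 0.5 and 1.0 modes with margin and are arguments, not
constants.  The normalization assumes males are present in the cohort;
an all-female library would be normalized against its own (female) mode
and miscalled, which is the documented limitation of any
relative-depth method.

# Diversity and divergence

Nucleotide diversity is the average pairwise difference per site,
with missing data handled by pairwise-complete counts; for genotype
matrices the per-site value is `x (m - x) / choose(m, 2)` for `x`
alternate among `m` called alleles.  Note that on a SNP-only matrix
this is diversity *per variable site*; per-base-pair values require the
callable invariant length, which the caller supplies.

Differentiation uses the AMOVA form of `Phi_ST`: variance components of
pairwise squared distances decomposed into among- and within-population
parts, `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`.  Two modes are
provided, because reduced data support both readings: per-site allele
AMOVA for unphased diploid SNPs (allele copies treated as haploid
draws — a documented approximation that is exact per site, where phase
cannot matter) and full-sequence AMOVA on mutation-count distances for
haplotype data such as mtDNA COI alignments.  The **composite** value
is the ratio of summed variance components — algebraically the AMOVA of
the concatenated data — *not* the mean of per-locus ratios, which would
weight uninformative loci equally.  Negative among-population
components (expected under panmixia) are preserved in per-locus output
and clamped to zero only in the composite.  `haplotypeCensus()`
collapses aligned sequences into haplotypes, counts them per species
and reports cross-species sharing.

# The stepwise Ne(t) model

The central model describes one population whose size, relative to the
ancestral size `N_ANC`, is piecewise constant: an unbounded ancestral
epoch of relative size 1, then an ordered series of steps (earliest
first), step `k` of size `v_k` lasting `t_k` units of `2 N_ANC`
generations, the last step ending at the present.  Rendered at 100
steps it describes a effectively continuous size trajectory.

## Expected spectrum

The expected unfolded SFS follows from expected coalescent branch
lengths: if `W_k` is the expected time during which the genealogy of
`n` samples has `k` ancestral lineages, then

$$E[\xi_i] = \frac{\theta}{2}\sum_{k=2}^{n-i+1} k\,W_k\,
\frac{\binom{n-i-1}{k-2}}{\binom{n-1}{k-1}},$$

the classical descendant-count polynomial.  `W_k` is computed exactly
(no grid, no Euler stepping) by integrating the occupancy of the
pure-death chain with rates `choose(k, 2)` in *rescaled* time
`tau = integral dt / nu(t)`, using uniformization of the chain per
epoch; each epoch's occupancy is mapped back to natural time by its
`nu`.  The ancestral epoch has the closed form
`W_k += nu_anc * 2/(k(k-1)) * P(lineages >= k)`.  With all sizes 1 this
reproduces `E[xi_i] = theta / i` to machine precision (the unit test
asserts 1e-10 at n up to 60), which pins the whole engine to the
standard coalescent.

## Folding, masking, and what they cost

Without an outgroup the spectrum is folded to minor-allele orientation.
Empirical practice also masks the monomorphic classes and the singleton
class, whose counts are most sensitive to sequencing error and allelic
dropout.  That robustness has a measurable price in information: under
the singleton mask a recent tenfold expansion is nearly aliased by a
boundary model (an extremely large size held for a long time), the two
differing by only ~1.4 expected log-likelihood units at S ~ 6,000 —
statistically invisible — whereas the folded spectrum *with* singletons
separates them by ~2,800 units.  The package therefore masks by default
when fitting empirical data but runs its simulation-based recovery
experiments on folded, unmasked spectra, where the truth is actually
identifiable.  Users of real data should understand that recent-size
estimates under the mask lean heavily on the doubleton class.

## Fitting

`fitStepwise()` maximizes the Poisson composite log-likelihood
`sum_i [k_i log(theta m_i) - theta m_i - log k_i!]` over unmasked
entries, treating sites as independent; `theta` is profiled
analytically (`theta_hat = sum k / sum m`), never searched.  Because a
hundred free `(v, t)` pairs are unidentifiable from one folded SFS, the
optimization runs over `K` control points (default 10) whose sizes are
interpolated geometrically across the rendered steps — `interp =
"step"` gives plain piecewise-constant control points instead.
Optimization is derivative-free Nelder–Mead on log parameters with box
bounds (`v` in [1e-3, 1e3], `t` in [1e-4, 5]) enforced by a quadratic
penalty; each of `nStarts` starts perturbs the neutral start by one
log-unit of seeded Gaussian noise, so results are reproducible and the
best log-likelihood is non-decreasing in the number of starts.

Two numerical choices deserve note.  First, a mild ridge penalty
`regLambda * sum((log v_k)^2)` (default 0.5) resolves likelihood-flat
directions: an extreme size held for a negligible duration leaves the
spectrum untouched, so without the penalty the optimizer halts at
arbitrary points along such ridges and the rendered trajectory shows
spurious excursions.  The penalty pins those directions at the
ancestral size while shifting informative estimates by well under the
sampling noise (a tenfold expansion is recovered with geometric-mean
ratio ~1.0 across replicates).  Second, standard errors come from the
observed information of the composite likelihood, differentiated
numerically on the log scale over all parameters *and* `log theta`
jointly; intervals are `exp(log estimate +/- z SE)`.  Composite
likelihoods understate uncertainty when sites are linked; with
effectively unlinked sites the simulation experiments show close to
nominal coverage.

# Two-population models

Three classical models of a population split at scaled time `T` are
registered: `neutral_no_divergence` (no parameters — the two samples
are arbitrary labels on one panmictic population),
`split_migration` (`nu1`, `nu2`, `T`, symmetric `m`), and
`isolation_with_migration` (asymmetric `m12`, `m21`);
`split_no_migration` is the `m = 0` constraint.  Migration follows the
diffusion convention — `m12` is the scaled rate *into* population 1 —
so the expected migrant lineages per generation is `m12 nu1 / 2`
(`migrantsPerGeneration()`).

The NND expectation is exact: the single-population spectrum for
`n1 + n2` copies split hypergeometrically.  For the split models the
expectation is the average over structured-coalescent genealogies of
per-class branch lengths (no Poisson noise).  Monte Carlo expectations
inside an optimizer need care, and `fitPairwise()` takes it:

* common random numbers (one seed per fit) make the surface
  deterministic and optimizable;
* a continuity floor of half a genealogy's mass prevents `log(0)` at
  cells the finite simulation missed;
* two stages — coarse multi-start, re-ranking of the start endpoints on
  a 10x-finer surface, then a polish — avoid committing to a basin that
  only the Monte Carlo noise created;
* the final log-likelihood is re-evaluated with fresh, many more
  replicates and corrected for the Jensen bias `k Var(m) / (2 m^2)`
  that noisy expectations leave in `sum k log m`, so Monte Carlo fits
  are comparable with the exact NND likelihood;
* a per-batch event budget turns pathological corners (enormous sizes
  with heavy migration) into penalty values instead of multi-second
  simulations.

`selectModel()` ranks fits by AIC — the three models differ in
parameter count, so raw likelihood would always favor the largest —
with ties broken toward fewer parameters.  In simulation this
recovers the generating model in the large majority of replicates in
both directions (panmictic data are not over-fitted by the split model;
genuine migration at `m = 1` is not mistaken for a clean split).

# From scaled parameters to individuals and years

All inference is relative: sizes in units of `N_ANC`, times in
`2 N_ANC` generations, and `theta = 4 N_ANC mu_gen L` for diploid
autosomes.  `Calibration` carries the constants; `generationTime()`
uses the mean-parent-age identity `G = alpha + s / (1 - s)`.  When no
trustworthy per-site mutation rate exists, `calibrateMu()` anchors the
scale on an independently dated divergence: given the anchor in years
and in model time, `mu_gen = T_scaled theta G / (2 L anchor_years)`,
reported per year.  `scaleFit()` then emits the trajectory as (years
before present, Ne in individuals), accumulating durations backwards
from the present, with multiplicative CI propagation; `unscaleFit()`
inverts it exactly.  Every scaled output carries its provenance
constants.

# The simulator: what it emulates, and what it does not

`simulateSfs1d()`/`simulateSfs2d()` are Hudson-style single-locus
coalescent samplers (piecewise-exponential waiting times across epochs,
no Euler discretization) with infinite-sites mutations sprinkled as
Poisson counts on branch lengths; the two-deme version adds per-lineage
migration and a merge into the ancestral deme at `T`.  They serve as
the independent oracle for the deterministic engine (the two agree
within Monte Carlo error on every frequency class) and generate
fitting targets of known truth.

`simulateGenotypeMatrix()` emulates the cohort-level features the
pipeline consumes: group allele frequencies interpolated between a
shared ancestral frequency and fixed differences
(`groupAlleleFreqDivergence`, default 0.7 — two groups at the default
produce composite `Phi_ST` near 0.7, the strong-divergence regime of
multi-species dove cohorts), negative-binomial read depths around a
median of 119 (the study-scale sequencing depth; only the median is
specified, so the overdispersion size parameter is an explicit knob),
hemizygous female Z genotypes reported as homozygous calls at half
depth (what a diploid-assuming caller produces), and a flat missingness
rate.  It deliberately does **not** model linkage within loci,
sequencing-error miscalls, allele-dropout-driven (depth-dependent)
missingness, recombination, or selection.  Passing tests on these
cohorts therefore validate the *estimators* under their own
assumptions; they do not certify robustness to artifacts the emulator
excludes.

The study conditions used by the simulation experiments (and their
sizes, chosen to make the checks sharp at interactive runtimes):
constant-model oracle at n = 10, 40, 60; engine-versus-simulator
agreement at 1e5 genealogies; expansion recovery over 20 replicates of
~5,900 effectively unlinked segregating sites at n = 40; model
recovery over 25 replicates per scenario of ~10,000 sites at
n = 20 + 20; 200 independent panmictic cohorts for the `Phi_ST` null.

# Pipeline orchestration

`runPipeline()` drives the stages from one validated configuration
(unknown keys are errors): simulate or load, filter, sex, diversity
statistics, spectra, single-population fits, optional pairwise
comparison, and conversion — the conversion stage is skipped with an
explicit notice when no calibration block is given.  Every artifact is
written with an md5 checksum into `manifest.json`, and each stage
derives its own seed from the global one by a fixed hash, so any stage
can be reproduced in isolation.  `makeFixture()` packages a small
three-group cohort with truth tables for demos and tests.  The
package's interface is its R functions; the pipeline entry points are
ordinary exported functions scriptable with `Rscript`.

# Known limitations

* Composite-likelihood uncertainty ignores linkage; with few, long
  loci the intervals will be anticonservative.
* The control-point parameterization with geometric interpolation is a
  smoothness choice, not an inference of the underlying step structure;
  sharp historical changes are recovered as compressed ramps.
* Under the singleton mask, recent-size information is thin (see
  above); masked empirical fits should be read with the corresponding
  humility.
* The sexing normalization requires males in the cohort.
* The Monte Carlo two-population engine makes model *comparison*
  robust, but single-replicate parameter estimates carry both sampling
  and (small) optimization-surface noise; replicate medians are
  reliable where single fits scatter.
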