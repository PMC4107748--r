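---
title: "Methods: Poisson quantification, copy-number calling and extreme-phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Poisson quantification, copy-number calling and extreme-phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcnv)
```

## The partition model

A ddPCR reaction is split into $n$ droplets (typically 12,000–15,000
accepted per well here). If template molecules land in droplets
independently with mean $\lambda$ copies per droplet, droplet occupancy is
Poisson($\lambda$) and a droplet reads positive iff it holds at least one
copy, so the positive probability is $p = 1 - e^{-\lambda}$. Inverting the
observed fraction $\hat p = k/n$ gives the maximum-likelihood estimate

$$\hat\lambda = -\ln(1 - k/n),$$

which is absolute: no calibrator or standard curve enters. At the working
concentrations used here ($\lambda \approx 0.3$–$0.8$, i.e. 5,000–8,000
copies per 14,000-droplet reaction) roughly a third to a half of droplets
are positive, near the information optimum of the design. A saturated well
($k = n$) carries no finite estimate and is reported as its own status,
never as a number.

### Interval for $\lambda$

The delta method on $\lambda(p) = -\ln(1-p)$ gives
$\mathrm{se}(\hat\lambda) = \sqrt{\hat p \,/\, (n(1-\hat p))}$ and a normal
interval clipped below at 0. With huge $n$ and moderate $p$ this is
essentially exact; measured coverage at $n = 14{,}000$ and
$\lambda \in \{0.1, 0.5, 1.0\}$ sits within 1.5 percentage points of the
nominal 95% (the acceptance script recomputes this). Near the boundaries
(fewer than 5 positive or 5 negative droplets) the normal approximation on
a count is not trustworthy, so the interval switches to an exact
Clopper–Pearson binomial interval on $p$ pushed through $-\ln(1-p)$; the
two agree in the overlap region and the exact branch is what makes the
$k = 0$ interval honest (lower bound exactly 0). No formula for the
commercial software's interval is published; this pairing reproduces its
bulk behaviour while staying valid at the edges.

### Replicate pooling

Replicate wells of a sample are merged at the droplet level
($\sum k, \sum n$) before estimation — the MLE under the model, and
standard merged-well practice — rather than averaging per-well estimates.
Pooling $m$ identical wells leaves $\hat\lambda$ unchanged and shrinks the
interval width by $1/\sqrt m$. Reaction sizing uses the 3.3 pg haploid
genome mass: the ~10,000 genome copies wanted for accurate copy-number
work correspond to 33 ng of DNA per reaction
(`dna_mass_for_copies(10000, 3.3)`).

## Copy number and the calling rule

Duplexing against a reference locus present at exactly two copies per
diploid genome gives

$$\hat c = 2\,\hat\lambda_t / \hat\lambda_r,$$

scale-invariant in the common factors (DNA input, droplet volume). The
interval is propagated on the log scale: squared relative standard errors
of the two channels add, and the bound is back-transformed around
$\hat c$. This is the standard ratio-of-rates treatment; it requires a
positive target estimate, so a zero-target channel falls back to interval
arithmetic on the channel bounds (giving $\hat c = 0$ with an honest upper
bound), and a zero or saturated reference is a *reference failure* — the
sample cannot be normalised at all and is reported as
`failed_amplification`.

A sample is **called** at integer $m$ when the 95% CI of $\hat c$ contains
exactly one candidate integer in $\{1, 2, 3\}$ and that integer is $m$.
The containment direction matters and is deliberately this way around:
only the measured quantity has a defined interval, so the rule asks
whether the measurement is compatible with exactly one genotype — not
whether the estimate falls in an interval centred on an integer. No
integer in range gives `no_integer`; two or more give `ambiguous`; values
above 3 are `no_integer` by default because the genotype universe modelled
here is 1–3 copies (`max_cn` raises it when an assay warrants). Calling is
deterministic and total: every estimate maps to exactly one status.

Unresolved samples are repeated. Resolution is conservative: concordant
integer calls stand; discordant integer calls exclude the sample (a
majority vote was considered and rejected — with at most a handful of
repeats it would manufacture confidence); two or more attempts with no
integer call exclude the sample. Exclusion percentages are reported to one
decimal over the full attempted cohort.

### What "recovery" means under a 95% gate

A calibrated 95% interval excludes the true value in ~5% of wells by
construction, so at most ~95% of single wells can pass the containment
gate — no implementation can call 99% of wells *and* use an honest 95% CI.
The package therefore separates two quantities: the **call rate** (~94–95%
of simulated wells at these droplet counts, tracking CI non-coverage plus
ambiguity, and regression-tested against that expectation) and **accuracy
among calls**, which is the quantity a genotyping pipeline must maximise.
Accuracy is ≥ 99% (empirically 100% at $n = 14{,}000$,
$\lambda_r \in [0.3, 0.8]$): a *wrong* call requires the interval to
contain a wrong integer while excluding the true one, i.e. a
many-standard-error excursion. Failed wells are repeated, not miscalled.

## The simulator

`simulate_well()` draws the two channels independently (the estimator
assumes channel independence): reference occupancy Poisson($\lambda_r$),
target Poisson($(c/2)\lambda_r$) for true copy number $c$, so a two-copy
sample runs at the reference concentration. Per-droplet positive
indicators are iid Bernoulli with
$p = q + \mathrm{fp}\,(1-q)$, $q = (1-e^{-\lambda})(1-\mathrm{fn})$ —
false positives fire on droplets that would otherwise read negative — and
the counts are drawn directly from the implied Binomial$(n, p)$, which is
distributionally identical to simulating droplets one by one and much
faster. False-call rates default to 0: they are stress-test knobs, not a
model of rain (intermediate-fluorescence droplets), which is out of scope
along with amplitudes and droplet-volume variability. Per-well seeds
derive from a master seed plus a stable hash of (sample, replicate), so
any subset of a plate reproduces identically.

`simulate_cohort()` emulates the two-group extreme design: Gaussian
SBP/DBP/age/BMI per group, Bernoulli sex, treatment only in the high group,
and a Bernoulli deletion genotype per group. Defaults are the modelled
study's conditions: 96 high / 92 low; SBP 165.9 ± 12.3 vs 98.6 ± 5.2 mmHg;
DBP 94.4 ± 10.8 vs 64.3 ± 7.2; age 55.1 ± 8.3 vs 32.6 ± 14.5 years; BMI
28.3 ± 4.5 vs 22.7 ± 3.2 kg/m²; ~50% male; 53.1% of the high group
treated; deletion prevalence 12.6% vs 2.2%. The per-assay λ is not
published, so the default $\lambda_r = 0.5$ is back-computed from the
droplet counts and the 5,000–8,000 copies/reaction range and is
configurable. Two deliberate simplifications: phenotypes are *not*
truncated to physical ranges (rejection sampling would bias the configured
moments that the recovery tests check; range invariants are enforced when
reading observed data instead), and the Gaussians are drawn independently,
so the simulator does not emulate SBP–DBP correlation, phenotype–genotype
effects within group, or measurement rounding. Passing tests therefore
demonstrate calibration of the machinery under the stated sampling model,
not robustness to the messiness of real cohorts.

## Extreme-phenotype design arithmetic

Treated subjects' pressures are shifted +10/+5 mmHg (systolic/diastolic)
*before* extremes are defined — the adjustment is part of the phenotype —
and the shift is tracked so it cannot be applied twice. Extreme groups are
the empirical SBP deciles; membership is by rank under a stable ordering
on (SBP, subject id), taking $\lfloor 0.1 n \rfloor$ subjects per tail.
Rank selection rather than an interpolated quantile threshold is a
deliberate choice: it is the same empirical-decile notion, but remains
disjoint and deterministic under ties, where any threshold rule degenerates.

The standardized separation is
$D = (\bar x_\mathrm{high} - \bar x_\mathrm{low}) / \mathrm{SD}_\mathrm{pop}$;
for the modelled design $(165.9 - 98.6)/14.3 = 4.71$. The effective sample
size uses the non-centrality-ratio convention

$$n_\mathrm{eff} = \frac{D^2}{4}\,(n_\mathrm{high} + n_\mathrm{low}),$$

anchored so that two groups 2 SDs apart are exactly equivalent to a random
sample of the same size; the modelled design evaluates to ≈ 1041.
Published power-of-extremes equivalences in this design's literature quote
larger numbers (e.g. ≈ 1714 for this configuration) from formulas in work
not reproducible here; the convention is therefore exposed as a
replaceable function and the package's own number is documented rather
than the citation's. Similarly, ≈ 4.5 SDs is sometimes quoted for this
separation; the arithmetic on the stated means and SD gives 4.71, and the
package reports what it computes.

## Association statistics

Carrier status is an indicator — deletion carriage ($c < 2$) for deletion
assays, gain ($c > 2$) for duplication assays — mirroring how such
genotype tables are analysed; copy number is not entered as a continuous
covariate. The logistic model regresses extreme-group membership
(high = 1) on carriage plus age, BMI and sex, fitted by `glm` (IRLS) with
a tightened convergence tolerance; Wald intervals are reported on both the
coefficient and odds-ratio scales (profile intervals would also be
defensible; Wald matches the era's standard output and the 2×2 oracle
check). Complete separation is detected (boundary fitted probabilities or
a diverging coefficient) and reported as a status, never as a silently
huge estimate. With a single binary predictor the MLE equals the analytic
cross-product odds ratio — the suite checks agreement to $10^{-6}$ on the
12/83 vs 2/90 genotype table, whose odds ratio is 6.506.

Within-group BP differences by genotype use the two-sided Wilcoxon
rank-sum test, unadjusted (deliberately: the within-group samples are too
small to support covariate adjustment). Midranks handle ties; for
$n + m \le 12$ the p-value is exact by enumerating the permutation
distribution of the rank-sum (a subset-sum counting recursion over doubled
ranks — unlike `stats::wilcox.test`, exactness survives ties), otherwise
the normal approximation with tie-corrected variance and continuity
correction is used. Type-I error at $n = m = 30$ measures ~0.04–0.05 at
nominal 0.05. Monomorphic assays (one copy-number class among called
samples) are flagged and skipped — there is nothing to test. No
multiple-testing correction is applied, matching the design's
hypothesis-driven scope; the report counts the tests run so users can
adjust externally. Comparisons against reference catalogue (DGV-style)
loss/gain frequencies are descriptive differences only; reference
frequencies are user-supplied inputs.

## Region bookkeeping

CNV coordinates are 1-based with both endpoints inclusive (UCSC browser
display style), so length is $end - start + 1$. The convention is pinned
by the shipped region table: the two published lengths (553,635 bp and
224,588 bp) are reproduced exactly from their printed coordinates, and the
"approximately 3.5 Mb" region computes to 3,584,238 bp. BED export
converts to 0-based half-open. No liftover or gene annotation is provided.

## Problem sizes and tolerances

The default verification sizes — 200-well convergence checks, 2,000 wells
per λ for coverage, 500 wells per (copy number, λ) condition for calling,
1,000 null simulations for test calibration, 40 replicate cohorts for
moment recovery — were chosen so Monte-Carlo error is several times
smaller than the tolerance being asserted (4 MC SEs for convergence
checks, ±1.5% on coverage, 3 SEs on moments) while keeping the whole suite
inside a coffee break. Numerical agreement checks (λ̂ vs bisection,
logistic vs cross-product) use $10^{-10}$ and $10^{-6}$ respectively,
far below the statistical noise floor of any real experiment.

## Known limitations

- No rain/amplitude model: droplet classification is taken as given.
- Channel independence is assumed both in simulation and estimation;
  molecular linkage between nearby target and reference loci would
  violate it (undigested DNA is the practical risk, hence the restriction
  digest upstream in the wet protocol this models).
- Mosaicism is not modelled; persistent non-integer samples are excluded,
  not decomposed.
- The cohort simulator's Gaussian, independent phenotypes understate real
  covariance structure (see above).
- The effective-sample-size convention is one of several in the
  literature and is reported as such.
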