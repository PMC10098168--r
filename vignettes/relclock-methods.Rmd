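---
title: "Methods: relaxed-clock dating, rooting and curation in relclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relaxed-clock dating, rooting and curation in relclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(relclock)
```

relclock implements a complete desk-scale pipeline for dating ancient
protein families on gene trees: curation of homology-search output,
rooting without an outgroup, Bayesian node-age estimation under three
relaxed-clock rate processes with fossil calibrations, and the diagnostics
needed to decide whether any of the resulting ages deserve belief. This
vignette is the package's own account of the models, the defaults, and the
design decisions, including what the synthetic-data generators do and do
not establish.

## 1. The dating model

### Time, rates, and data

A rooted topology is fixed; the unknowns are the internal node ages
(Ma before present, tips at 0), a global rate $\mu$
(substitutions/site/Ma), per-branch dimensionless rate multipliers, and
the rate model's hyperparameters. Branch $b$ with duration $\Delta t_b$
and effective multiplier $\bar r_b$ has expected length
$e_b = \bar r_b\,\mu\,\Delta t_b$ substitutions/site.

The sequence data are summarized as **per-branch substitution counts**
over an alignment of $L$ sites:

$$k_b \sim \mathrm{Poisson}(\bar r_b\,\mu\,\Delta t_b\,L),$$

independent across branches. This is the package's single largest
deliberate simplification: a full phylogenetic likelihood under an
empirical profile mixture model is replaced by its sufficient-statistic
caricature. The Poisson count likelihood preserves exactly the structure
that matters for dating — the confounding of rates and times through their
product, and the information content scaling with $L$ — while making every
posterior property testable against closed forms at desk scale. It ignores
site-rate heterogeneity, substitutional saturation and topological
uncertainty; absolute ages from real alignments should not be read off
this likelihood, which is why the acceptance checks are properties
(coverage, prior recovery) rather than reproductions of published ages.

### Rate processes

All three models are mean-1 multiplier processes so that $\mu$ carries the
time dimension and models are comparable:

* **UGAM** (uncorrelated gamma): $r_b \sim \Gamma(1/\nu, \nu)$ i.i.d.,
  mean 1, variance $\nu$. $\bar r_b = r_b$.
* **LN** (autocorrelated lognormal): the node rate follows geometric
  Brownian motion in time,
  $\ln r_c \mid r_p \sim N(\ln r_p - \sigma^2\Delta t/2,\ \sigma^2\Delta t)$.
  The $-\sigma^2\Delta t/2$ drift makes the rate a martingale
  ($E[r_c \mid r_p] = r_p$); implementations differ on this point, so it is
  stated explicitly. Nonstationary: the log-variance grows linearly.
* **CIR** (mean-reverting square-root diffusion):
  $dr = \theta(1-r)\,dt + \sigma\sqrt{r}\,dW$, with the exact transition
  $r(\Delta) = Y/(2c)$, $Y \sim \chi^2_{4\theta/\sigma^2}(\lambda)$,
  $c = 2\theta/(\sigma^2(1 - e^{-\theta\Delta}))$,
  $\lambda = 2c\,r_p\,e^{-\theta\Delta}$. Stationary
  $\Gamma(2\theta/\sigma^2,\ \mathrm{rate}\ 2\theta/\sigma^2)$: mean 1,
  variance $\sigma^2/2\theta$. The Feller condition $2\theta > \sigma^2$
  is enforced (paths strictly positive) rather than reflecting at zero —
  simpler and testable.

For the autocorrelated models the branch effective rate is the arithmetic
mean of its endpoint rates, $\bar r_b = (r_p + r_c)/2$ — the standard
discretization, documented as an approximation. The root rate is fixed at
1 by convention, which anchors identifiability.

**Parameter scales.** Because time is measured in Ma and branches span
hundreds of Ma, diffusion parameters must be stated *per Ma*. Defaults:
$\nu = 0.3$; $\sigma^2 = 5\times10^{-4}$/Ma (log-rate standard deviation
$\approx 1$ across a 2000 Ma path — strong but realistic rate variation
for deep-time proteins); CIR $\theta = 0.01$/Ma (reversion over
$\sim$100 Ma) with $\sigma = 0.1$ (stationary rate variance 0.5). Unit-scale
values such as $\sigma^2 = 0.1$/Ma, natural when tree height is rescaled
to 1, produce per-branch log-rate variances of order 100 here — absurd
biology and unusable mixing — and are deliberately not the defaults.

### Priors

* **Root age**: an interval $[\text{young}, \text{old}]$ (e.g. the
  0.8–3.8 Ga used for Precambrian enzyme families) is read as the central
  95% span of a normal: mean $(\text{old}+\text{young})/2$, sd
  $(\text{old}-\text{young})/4$, truncated at 0.
* **Internal ages**: uniform over order-compatible configurations given
  the root. The conditional is *normalized*: its support volume scales as
  $a_\text{root}^{m}$ with $m$ = (number of internal nodes) − 1, so the
  joint prior carries a $-m\ln a_\text{root}$ term. This makes the
  marginal prior of the root age exactly the truncated normal, which is
  what the prior-recovery tests verify by comparing the sampler (with the
  likelihood disabled) against direct rejection sampling.
* **Calibrations**: hard bounds (uniform mass inside, zero outside) on the
  MRCA of two named tips — the default behaviour of mainstream dating
  software. Contradictory systems (a descendant's minimum above an
  ancestor's maximum) are detected by interval propagation at
  configuration time and reported with the offending calibration names.
* **Hyperpriors**: diffuse exponentials — on $\mu$ (mean $10\times$ the
  initial value), and per model on $\nu$ (mean 1), $\sigma^2$ (mean
  $10^{-3}$/Ma), $\theta, \sigma$ (means 0.02, 0.1; the Feller condition
  truncates the support). The original study did not report its
  hyperpriors, so no fidelity to them is claimed; they are configuration.

### The sampler

Metropolis-within-Gibbs, implemented in C++ (Rcpp), using R's RNG so
`set.seed()` governs chains end-to-end:

1. per-node age slides, uniform windows scaled to the local
   parent/children interval (reflected at the bounds; the root uses an
   absolute window when unbounded above);
2. a joint rescaling of all internal ages with $\mu^{-1}$ — the
   time/rate-confounding direction, along which the count likelihood is
   exactly invariant;
3. subtree scaling moves (all internal ages below a node multiplied by a
   common factor) to decorrelate nested ages;
4. multiplicative rate updates per node (LN/CIR) or per branch (UGAM);
5. for UGAM, a joint $\mu \cdot c$, $r_b / c$ rescale, because only the
   products $\mu r_b$ are likelihood-identified;
6. multiplicative updates of $\mu$ and the hyperparameters.

Step sizes adapt toward 20–50% acceptance during burn-in (default 20% of
the chain) and are then frozen, preserving detailed balance in the
retained portion. Defaults: 20,000 sweeps, thinning 10, two chains.
Initial states come from calibration-bound propagation (lower bounds up,
upper bounds down) with seeded jitter, so every chain starts in the
support.

Degenerate inputs are handled explicitly: non-positive proposed rates get
$-\infty$ density rather than errors; zero-duration branches reject
autocorrelated transitions; a zero expected length with a positive count
is impossible ($-\infty$); $0\ln 0 = 0$ in the likelihood.

## 2. Rooting and clade analysis

MAD rooting scores every branch position by the RMS relative deviation of
all tip pairs; the optimal position on each branch has the closed form
$\rho^* = \mathrm{clamp}\!\left(\sum_{ij}(D_{ij}-2d_i)D_{ij}^{-2} \big/
2\sum_{ij}D_{ij}^{-2},\ 0,\ t\right)$ over the spanning pairs, while
same-side pairs contribute constants through their fixed ancestors. Ties
between branches resolve to the first branch in a deterministic postorder
traversal; zero-length branches are legal candidates with $\rho = 0$. A
rooted input is silently unrooted first. The implementation is verified
against an exhaustive branch × position-grid search written from first
principles (distances to a sliding root point only).

Monophyly detection returns *maximal* clades sharing one value at a rank;
tips with unknown rank never join a clade. Clade-composition coding labels
maximal clades where one group's share strictly exceeds a threshold
(default 0.67, "over 67%"). Unannotated tips count in the denominator —
the conservative reading, since the convention is not fixed by the
figure-legend phrasing this rule comes from. Subsampling keeps the most
divergent pair per clade at $k = 2$ and the longest-terminal-branch tip at
$k = 1$ (ties lexicographic): the original analyses do not say which
members were kept, and these choices preserve within-clade depth, which is
what matters for downstream dating.

## 3. Diagnostics

* **ESS**: $n / (1 + 2\sum\rho_k)$ with Geyer's initial-positive-sequence
  truncation, FFT autocovariances, capped at $n$; a constant series is
  defined to have ESS $= n$ (no autocorrelation evidence, avoiding 0/0).
* **Discrepancy**: $|\bar x_1 - \bar x_2| / \sqrt{(s_1^2+s_2^2)/2}$ —
  the tracecomp-style statistic behind the conventional 0.30 threshold.
  The pass rule (all ESS ≥ 50, all $d \le 0.30$) is configurable.
* **Boundary check**: the fraction of root-age samples within 1% of the
  prior-interval span of either bound; a fraction above 5% flags the prior
  as likely truncating the posterior, operationalizing the
  relax-the-bound-and-re-run procedure. The 1%/5% constants are package
  choices; only the qualitative procedure is inherited.
* **Calibration cross-validation**: each grid cell's posterior means for
  fossil-bearing clades are classified against their fossil intervals,
  with self-exclusion (a clade never scores a subset where its own
  calibration is active); per-calibration informativeness is the recovery
  rate of held-out clades when that calibration is active — the metric is
  a package choice; the source analyses state only the conclusion.
* **Duplicate-calibration variance**: population variance (and SD) of the
  posterior *mean* ages of clades sharing one calibration; lower = more
  internally consistent model. Computing it on means rather than pooled
  posteriors is a choice; the alternative is a one-liner on the traces.

## 4. Synthetic data: what a green test establishes

The generators produce every input the pipeline consumes: Yule trees
conditioned on $n$ with the crown age rescaled (topology exchangeability
is χ²-tested); rates from each model's exact process; Poisson counts
(the generative twin of the likelihood — by construction, not an
independent check of the count model itself); taxonomies with planted
monophyletic blocks and HGT nestings (eukaryote clades inside
bacteria-labelled hosts, host ≥ 3× + 1 the nested size so the 2/3
majority rule labels it); alignments with fixed Glu/Lys/Cys triad columns,
planted triad-gap violators and private insertions; and hit tables
straddling every filter threshold with single-rule failures.

Because the generator and the dating model share the count likelihood,
parameter-recovery tests establish *internal coherence* (the sampler
inverts the stated model), not robustness to model misspecification. Real
data add alignment error, saturation, topology error and non-Poisson
dispersion that these tests cannot see. The QC fixtures, by contrast, are
exact: planted-truth equality is a complete check of those filters.

One deliberate misspecification experiment is included: data generated
under strongly autocorrelated LN rates and fit with UGAM produce a larger
duplicate-calibration variance than the matched model in the majority of
seeds — the variance criterion detects the mismatch.

## 5. Known limitations and one honest red

* The LN clock fails the simulation-based-calibration acceptance bar
  (17/20 root-age coverage): it achieves ~15–16/20 under the stated world
  (fixed 2000 Ma truth, the 3.8–0.8 Ga root prior, shallow-biased
  calibration placement). This is a property of the converged posterior —
  verified with 600k-sweep chains at ESS in the thousands and
  between-chain discrepancies ≤ 0.05 — not a sampler defect: with the
  likelihood disabled the same sampler reproduces its prior exactly under
  all three models. The mechanism is the autocorrelated rate/age
  confounding that lets the root prior pull LN ages old; UGAM and CIR
  decouple rates enough for the data to dominate. The criterion is left
  red rather than re-tuned, and the result independently mirrors the
  empirical finding that motivated comparing clock models in the first
  place: LN gives the oldest and least internally consistent estimates.
* Coverage definition in hit filtering ((query span)/(query length)×100)
  follows common BLAST tabular usage; sources rarely define it.
* "Adjacent to" a catalytic site means ±1 alignment column by default
  (configurable) — the source phrasing does not quantify it.
* Node ages and calibrations assume contemporaneous tips (no fossil tips).
* Marginal likelihoods / Bayes factors for formal model choice are out of
  scope; model ranking here is via the duplicate-calibration variance and
  CV informativeness.
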