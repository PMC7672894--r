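---
title: "Model-based subclonal deconvolution of the site frequency spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based subclonal deconvolution of the site frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(sfsmix)
```

## The problem

A bulk tumour biopsy sequenced by whole-genome DNA sequencing yields, for
every somatic mutation, a variant allele frequency (VAF): the fraction of
reads supporting the mutant allele. The distribution of these frequencies —
the site frequency spectrum — encodes the clonal composition of the sample.
Mutations present in every tumour cell (truncal, "clonal") pile up around
VAF 0.5 in a pure diploid sample; a subclone under positive selection
produces a second peak at half its cell fraction; and the neutral dynamics
of mutations drifting within each growing clone produce a dense
low-frequency tail whose shape population genetics predicts to be a power
law, with the cumulative count growing like 1/f.

Purely data-driven clustering of VAFs tends to shred this neutral tail into
spurious "subclones". `sfsmix` instead fits a mixture in which the tail is
modelled explicitly, so Beta clusters are only spent on genuine clonal and
subclonal peaks.

## The model

For `n` frequencies `x_i` in (0, 1) the likelihood is a univariate finite
mixture

```
f(D | theta, pi) = prod_i [ pi_1 g(x_i | x*, alpha)
                            + sum_{w=2}^{k+1} pi_w h(x_i | a_{w-1}, b_{w-1}) ]
```

with `g` a Pareto Type-I density (the neutral tail, fixed at component
index 1, support `[x*, Inf)`) and `h` standard Beta densities (the `k >= 1`
clonal/subclonal peaks). Fitting alternates a responsibility step with
component refits: mixing proportions are mean responsibilities, Beta
components are refit by weighted moment matching (default) or weighted
maximum likelihood (`beta_estimator = "mle"`, a proper EM whose
negative-log-likelihood trace is non-increasing), and the tail shape by its
weighted closed-form maximum-likelihood (Hill-type) estimator. The tail
scale `x*` is fixed at the minimum retained frequency rather than estimated:
the maximum-likelihood estimate of a Pareto scale is the sample minimum, and
fixing it stabilises model selection, so it is not counted among the free
parameters.

Candidate structures (each `k` in `k_range`, tail on/off) are scored by

```
BIC   = 2 NLL + lambda log n
ICL   = BIC + H(z)
reICL = BIC + H(z-hat)        (default selection criterion)
```

where `lambda = 2k + [tail] + (components - 1)` counts free parameters,
`H(z)` is the entropy of the latent assignment probabilities, and `z-hat`
re-normalises `z` after removing mutations hard-assigned to the tail.
`H(z-hat) <= H(z)` always, and reICL penalises exactly the overlap between
Beta peaks, promoting well-separated subclones. A selected model with
`k = 1` is a monoclonal tumour; `k > 1` is polyclonal. Note a structural
property of reICL worth knowing: a one-Beta model has `H(z-hat) = 0`
identically, so a second Beta is accepted only when its likelihood gain
exceeds its own assignment entropy — reICL is deliberately conservative
about splitting peaks.

## Tunable parameters

* `k_range` (default 1–3): candidate Beta counts.
* `tail_mode` (`auto`): compare with and without the neutral tail.
* `score` (`reICL`): selection criterion; `ICL`, `BIC`, `NLL` available.
* `restarts` (10): random initialisations per candidate. Initial Beta means
  are drawn from data quantiles with jitter and variance `0.05 m(1-m)`;
  a much flatter initialisation makes the components near-identical and the
  moment-matching iteration can then sit at a symmetric fixed point it
  never leaves, which is why the initial components are kept peaked.
  Degenerate restarts (a component losing all responsibility mass, or a
  moment fit outside the Beta moment region) are discarded and the best
  remaining restart by NLL wins.
* `epsilon` (1e-6): relative NLL convergence tolerance; `max_iter` 500.
* Hard assignments are argmax responsibilities with ties broken toward the
  lowest component index (the tail first), so outputs are deterministic.
* All randomness is driven by one seed; restarts, bootstrap resamples and
  simulator retries derive per-task sub-seeds, so results are identical
  under any execution order or worker count.

Frequencies must lie strictly inside (0, 1) for fitting; values at 0 or 1
are excluded (both densities are degenerate there), and "above 5%" input
filtering is a strict inequality. CCF input is halved on load so a clonal
mutation sits at 0.5 like a VAF; raw CCF in (1, 2] (multi-copy states) is
legal, above 2 is rejected.

## Evolutionary estimates

With a fitted model and its hard assignments:

* mutation rate: `mu = N_tail(f_min, f_max) / (1/f_min - 1/f_max)`, the
  inversion of the neutral prediction `M(f) = mu (1/f - 1/f_max)`. The
  default window spans the tail's 5th–95th percentiles (clipped below by
  the dataset cutoff) because both extremes are noise-dominated: the low
  edge by detection censoring at the VAF cutoff, the high edge by collision
  with the Beta peaks.
* subclone age: `t = N_sub / mu` tumour doublings, reading the subclonal
  cluster size as the mutation load accrued along the subclone founder's
  lineage.
* selection coefficient: with subclone cell fraction `x = 2 * mean(C_j)`
  (diploid heterozygous; the same conversion restores CCF for halved-CCF
  input) and sampling time `T` (default `N_clonal / mu`),
  `s = 1 + log2(x / (1 - x)) / (T - t)`; `s > 1` indicates positive
  selection and a subclone at exactly half the cells gives `s = 1`.

These formulas are simple inversions of deterministic exponential-growth
relations; they may differ from other tools by convention-dependent
constant factors, which is why the simulator below shares one explicit
time/rate convention with them.

## What the simulator emulates

`simulate_dataset()` grows a tumour through discrete generations of a
branching process (divide / die / persist per cell, infinite-sites
Poisson(`mu_sim`) mutations per daughter per division), optionally plants a
driver that founds a faster-growing subclone, and then sequences the final
population with Poisson depth and binomial read sampling.

Three design choices deserve explanation, because they are what make the
simulator and the estimators mutually consistent rather than merely similar:

1. **Stochastic birth–death, not deterministic doubling.** With certain
   division and no death the genotype tree is a perfect binary tree and the
   site frequency spectrum concentrates on dyadic atoms (1/2, 1/4, ...);
   window counts then depend on which atoms a window happens to contain.
   Division/death noise diffuses lineage sizes into the smooth 1/f tail the
   Pareto component encodes.

2. **The `e/2` growth regime.** In a discrete-generation process with
   per-generation growth factor `gamma`, mutation cohorts sit on frequency
   shells `gamma^-g`, and the windowed spectrum carries
   `mu b / (gamma log gamma)` mutations per unit of 1/VAF — not the naive
   `mu`. Separately, the ancestry of a randomly drawn surviving cell is
   size-biased (paths through a division carry double weight) and divides
   with probability `2b / (2b + persist)` per generation. The default
   probabilities (divide 0.417, die 0.058, persist 0.525, growth
   `gamma = e/2`) are the unique regime in which the windowed spectrum
   carries exactly `mu_sim` per 1/VAF unit; and times are expressed in
   *effective doublings* (one expected division along a surviving lineage),
   the clock under which a lineage accrues `mu_sim` mutations per unit —
   precisely what the mutation-rate and subclone-age estimators assume. In
   population-doubling units the two conventions differ by an irreducible
   factor of `2 log 2` in any birth–death process, which is why the
   effective-doubling clock is the honest one to report.

3. **The driver as a clock-speed multiplier.** A division-probability
   advantage is bounded at one division per generation, so a single founder
   cell appearing at 13 of 17 doublings could never reach a detectable
   fraction (it would be at most `2^4` cells among `2^17`). Driver cells
   instead run `fitness_multiplier` (default 4.1) complete
   birth–death–persist rounds per generation: the subclone grows by
   `gamma^fitness_multiplier` per generation while its internal neutral
   dynamics — and hence its contribution to the tail — remain statistically
   identical to the host clone's.

Driver runs condition on a biopsy taken mid-sweep: the subclone cell
fraction must land in `subclone_range` (default 0.45–0.62), re-drawing the
run otherwise. The lower bound keeps the subclone past half its sweep (the
selection estimate then exceeds its baseline of 1); the upper bound keeps
the subclonal VAF peak at most ~0.31, at least three binomial standard
deviations below the clonal 0.5 peak at 120x coverage, so the two Beta
components remain resolvable. The founder's truncal load defaults to
`mu_sim * sampling_time` mutations so the truncal branch length equals the
tumour age in doublings, the convention the age estimator uses for `T`.
Mutations whose true VAF falls below `min_true_vaf` (default 0.01) are not
expanded into the sequencing table: at 120x their chance of passing the 5%
observed-VAF filter is below 1e-5, and the full infinite-sites catalog
would be orders of magnitude larger than the detectable one.

What the simulator does **not** emulate: copy-number events, purity
mis-estimation, sequencing error substitutions (noise is pure sampling),
multi-region biopsies, overlapping generations. Passing the self-consistency
tests therefore shows that the estimators invert this model class
correctly; it does not certify behaviour on real data violating those
assumptions (e.g. aneuploid genomes must be reduced to CCF externally
first).

## Numerical choices and degenerate inputs

* Likelihoods are accumulated with a row-wise log-sum-exp; a data point
  with zero mixture density (possible only for models that cannot explain
  the data) is a hard error naming the point.
* Points below the tail scale have tail responsibility exactly 0; this is a
  support constraint, not an error.
* Weighted moment matching is rejected (and the restart re-drawn) when the
  weighted variance reaches the Beta moment boundary `m(1-m)`.
* The weighted Beta MLE is optimised on the log scale with analytic
  gradients and never returns a worse likelihood than its start, so the
  pure-MLE mode retains EM monotonicity.
* Per-seed windowed counts on simulated tumours carry irreducible 15–25%
  noise: the observable VAF window maps onto the first few generations of
  each clone, i.e. a handful of Poisson(`mu_sim`)-sized mutation cohorts.
  Multi-seed checks therefore aggregate by the median across seeds.

## Study sizes used in the test suite

The packaged tests exercise: the subclonal-sweep workflow (10 simulated
tumours at default parameters, ~700-800 detected mutations each), parameter
recovery on 5,000-point samples over 20 seeds, a 50-resample non-parametric
bootstrap of a 3,000-point fixture, 10-seed evolutionary self-consistency
at `mu_sim = 20`, and a 10-seed neutral control. These sizes were chosen so
the full suite runs comfortably on a single desktop core while keeping
every multi-seed criterion statistically meaningful.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(simulation_config(seed = 11))
d <- sim$dataset

sel <- select_model(d, fit_config(seed = 11))
sel$best

plot_fit(d, sel$best)
plot_entropy_profile(sel$best)

ev <- evolutionary_parameters(sel$best, d)
ev

boot <- bootstrap_fit(d, sel$best, kind = "nonparametric", n_boot = 50,
                      config = fit_config(restarts = 2, seed = 11))
plot_cocluster(boot, sel$best, d)
```

## Known limitations

* The Pareto tail is untruncated above 1; with very heavy tails a small
  amount of probability mass lies outside the frequency domain.
* Percentile bootstrap intervals are not bias-corrected; when the tail and
  a Beta peak overlap, the tail-shape estimator is biased upward and its
  intervals inherit that bias (no BCa by design).
* reICL's conservatism can favour `k = 1` when a subclonal peak sits very
  close to the clonal peak; inspecting the full candidate table
  (`sel$candidates`) and the entropy profile is recommended in borderline
  cases.
* Conversely, reICL has a blind spot for "tail-shoulder" Betas: its entropy
  term removes tail-assigned mutations, so a Beta that overlaps only the
  tail pays no entropy penalty. Because the real neutral spectrum has a
  hard upper cutoff (at the clonal VAF) that the untruncated Pareto cannot
  express, the fitted tail steepens and a shoulder Beta can capture the
  mid-tail residual: a fraction of genuinely monoclonal samples is then
  called polyclonal, typically with a small cluster around VAF 0.13-0.16
  whose implied selection coefficient stays at or below baseline. The
  full-entropy ICL score does penalise such clusters; compare both when
  monoclonality matters. High per-division mutation rates aggravate this:
  all mutations from one division co-segregate, so large per-division
  cohorts form real linked clusters at one frequency.
* dN/dS statistics and clone-tree assembly are intentionally out of scope;
  the assignment table (`write_assignments()`) is formatted so external
  tools can consume the clusters.
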