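---
title: "Methods: dynamic correlation and Bayesian networks for mediator panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic correlation and Bayesian networks for mediator panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynanet)
```

# The data and the two inference problems

The input is a `MediatorPanel`: concentrations of 20–30 inflammatory
mediators (cytokines, chemokines, HMGB1, nitrite/nitrate) measured in the
same subjects at a handful of time points — daily serum draws over a week,
or culture supernatants at 1, 3, 6 and 24 h. Values are non-negative,
right-skewed, in pg/ml (µM for NO2-+NO3-); missing samples are common and
are stored as `NA`, never imputed. Subjects carry a group label (clinical
sub-group or experimental condition), and all inference is within-group.

Two questions are asked of such panels. *Which mediators co-move, when?*
— answered by windowed correlation networks (DyNA). *Which mediators
drive which, one step ahead?* — answered by a discrete first-order
dynamic Bayesian network (DBN). The two are deliberately different
lenses: the first is undirected, contemporaneous and signed; the second
directed, lagged and unsigned.

# Windowed correlation networks

For a window $[t_0, t_1]$ and group $g$, every $(subject, time)$ sample
with $t_0 \le t \le t_1$ is pooled into one observation set. For each
unordered mediator pair the Pearson correlation $r$ is computed over the
samples where both are non-missing, and an edge is created iff

1. at least `min_pairs` complete pairs exist (default 4),
2. neither paired vector is constant, and
3. $|r| \ge$ `stringency` (default 0.7, the conventional cut-off for
   trajectories moving in parallel), with ties at the threshold kept.

The edge records $r$, its sign, and the number of pairs. Each window
network is summarized by the degree-sum complexity
$\sum_i N_i/(n-1) = 2|E|/(n-1)$, with $n$ the number of mediators
*assayed* (not just connected) — so complexity is comparable across
windows and groups that share a panel. Negative edges count in degrees
exactly like positive ones: the statistic measures how much of the panel
is co-moving, not in which direction.

Design choices worth spelling out:

- **Pooling across subjects and times.** A one-day window contains at
  most two samples per subject, so per-subject correlations are
  impossible at this design; pooling the group's samples is the only
  estimator with usable sample size. The price is that pooled $r$ mixes
  between-subject level differences with within-subject dynamics; the
  synthetic generator (below) mirrors exactly this structure. A
  per-subject analysis is not offered because the sampling designs the
  package targets cannot support it.
- **Closed windows.** Windows include both endpoints, so a sample taken
  on a shared boundary day contributes to both adjacent windows. With
  daily sampling this is what keeps two-point windows populated; it also
  means adjacent window networks are not independent.
- **Raw vs log scale.** The default correlates raw concentrations;
  `transform = "log10"` uses $\log_{10}(1+x)$, which is often better
  matched to log-normal assay noise. The choice is exposed because
  neither is canonical for this analysis tradition.
- **Degenerate input.** Constant vectors yield no edge (correlation
  undefined; no co-movement is the conservative reading) rather than an
  error; windows with no computable pair yield an empty network,
  complexity 0, and a warning. No multiple-testing correction is applied:
  edge creation is a fixed-threshold rule, not a hypothesis test, and is
  reproduced as such.

Per-group summaries are the total connections (edges summed over the
schedule), the negative-edge count/fraction (reported as 0 with an
`undefined` flag when there are no edges at all), and the focused
subnetwork restricted to edges incident to one mediator of interest.

# Discrete dynamic Bayesian networks

The DBN engine fixes a standard, desk-scale pipeline:

1. **Quantile discretization**, per mediator, into `levels = 3` bins
   (low/medium/high) over the group's pooled values. Three levels keep
   conditional probability tables estimable from the few hundred
   transitions a cohort yields. Mediators with too few distinct values
   fall back to fewer bins; a constant mediator collapses to one level,
   which makes it scoring-neutral — it can neither gain parents nor help
   a child, so it stays isolated by construction rather than by special
   case.
2. **Transitions.** One row per strictly consecutive same-subject time
   pair (gap days produce no row; subjects are never concatenated). For
   unevenly spaced grids (1, 3, 6, 24 h) the `gap_tolerant` option treats
   each adjacent observed pair as one step; the pipeline enables it
   automatically for the hour-grid preset.
3. **BDeu scoring.** Each child's family score is the Dirichlet-
   multinomial log marginal likelihood with equivalent sample size
   `ess = 1` spread uniformly over parent-configuration cells, and a
   uniform structure prior. The score decomposes over children, so
   search is per child. Transitions missing the child or a parent are
   dropped family-wise (available-case analysis), which slightly shifts
   the data between competing families when missingness is heavy — the
   generator's missing-at-random samples match this assumption.
4. **Greedy search with restarts.** Per child: from an initial parent
   set, repeatedly take the single add/remove move with the largest
   *strict* score improvement (ties never move, making the search
   deterministic), up to `max_parents = 3`; keep the best of the empty
   start plus `restarts = 10` random starts. The child's own lag competes
   like any other parent, so self-loops are learned, not assumed.
5. **Bootstrap confidence.** Subjects are resampled with replacement
   `n_boot` times (duplicated subjects re-keyed so their series stay
   separate); each resample is re-discretized and re-learned, and an
   edge's confidence is the fraction of resamples containing it.
   Re-discretizing inside the resample keeps the bootstrap honest about
   binning variability.

**Central nodes** are mediators whose self-loop is present with
confidence at least a cut-off (0.5 in the pipeline): self-feedback is the
signature of a mediator driving its own expression, the motif used to
nominate master regulators of the inflammatory program.

All randomness (restart draws, bootstrap) flows through explicit seed
arguments; the pipeline derives per-stage seeds from its single master
seed so stages can be re-run in isolation.

# The synthetic-cohort generator

The generator exists so that both analyses can be validated against known
truth without any external data. Per subject, latent log-concentrations
follow a first-order autoregressive system on the sampling grid,

$$x_t = A\,x_{t-1} + \varepsilon_t,\qquad
  \varepsilon_t \sim N(0, \sigma^2 I),\qquad
  x_{t_1} \sim N(0, \tau^2 I),$$

with observed concentration $\mathrm{baseline}\cdot e^{x}$. The signed
matrix $A$ is the planted truth: off-diagonal entries couple a driver's
past to a target's present (negative entries plant anti-correlated
pairs), diagonal entries make self-feedback hubs persistent. Per-window
adjacency overrides plant time-localized coupling bursts. Whole
$(subject, time)$ samples are deleted with probability `missing_rate`,
and subjects falling below the minimum-samples inclusion rule are
redrawn.

Defaults (chosen once, as plausible for multiplex serum panels):
$\sigma = 0.3$ (log-scale step noise, i.e. ~35% multiplicative
variation), $\tau = 1$ (between-subject spread, the dominant variance
component, as is typical for cytokine baselines), baseline 100 pg/ml for
every mediator (assay units are reported per kit, not per cohort; only
correlation structure matters downstream), `missing_rate` 0.1. Hub
self-weight and planted couplings default to 0.9, strong enough that a
pooled two-point window sees the coupling at $|r| > 0.7$.

Two presets mirror the study designs the package targets: a four-group
human cohort (13/8/40/12 subjects, 27 mediators, daily d0–d7) in which
the non-survivor analogue carries the densest planted coupling plus a
d1–3 burst and the non-APAPo non-NAC analogue the sparsest; and a
four-condition mouse hepatocyte design (12/3/9/3 cultures, 22 mediators,
1–24 h) in which the APAP condition is densely positively coupled around
an HMGB1 hub and the APAP+NAC condition mixes in negative couplings.

What the generator does *not* emulate: assay floor/ceiling censoring,
batch effects, heteroscedastic per-mediator noise, non-stationary
baselines, informative missingness, and any mechanistic liver-injury
biology. Passing recovery tests on these cohorts therefore shows the
estimators do what they claim under the generative assumptions — pooled
correlations reflect planted couplings, greedy BDeu search finds planted
lag structure — not that real cohorts satisfy those assumptions.

# Validation scale and determinism

The shipped tests run at deliberately small sizes: oracle-equivalence
fuzzing uses ≤ 12 observations × ≤ 8 mediators per panel; planted-hub
recovery uses 12 subjects × 8 days × 8 mediators over 20 seeds; DBN
recovery and null-control checks use ~300 transitions (30 subjects × 11
days) over 20 seeds; preset-scale runs use the full 73-subject × 27-mediator
human design for the windowed analysis only. These sizes make the whole
suite run in well under a minute per module while leaving the recovery
margins (≥ 80–90% of seeds) far from their thresholds.

Everything numeric is deterministic given seeds: the correlation module
contains no randomness at all; generator, search and bootstrap are pure
functions of (spec, seed). Identical runs produce byte-identical CSV
outputs, and the run manifest (config echo, seed, versions) suffices to
reproduce a run exactly.

# Known limitations

- Pooled windowed correlations conflate between-subject heterogeneity
  with shared dynamics; group differences in totals should be read
  comparatively (same panel, same schedule, same threshold), not as
  absolute connectivity. Edge counts also inflate as group size shrinks,
  because small-sample $r$ is noisier at a fixed threshold — comparisons
  across very different group sizes need care.
- The fixed-threshold rule has no error control; it is a descriptive
  screening statistic, and the package intentionally reproduces it
  without a significance layer.
- The DBN is first-order, discrete and unsigned; it cannot represent
  longer memory, graded dose-response, or activation vs inhibition, and
  with 3-level discretization subtle couplings need several hundred
  transitions to be found.
- Greedy per-child search finds local optima; restarts mitigate but do
  not eliminate this, which is one reason edges are reported with
  bootstrap confidence rather than as certainties.
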