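---
title: "Quantifying behavioral predictability from Y-maze turn bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral predictability from Y-maze turn bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnvar)
library(dplyr)
```

## The scientific question

Genetically near-identical animals reared in a common environment still
differ consistently from one another in behavior. In *Drosophila*, a classic
readout of such individuality is *turn bias*: when a fly walks freely in a
symmetric three-armed (Y) maze, each arm-to-arm transition is a left or
right turn, and individual flies maintain idiosyncratic right-turn
proportions. The group-level *spread* of those per-fly proportions is then a
measure of behavioral individuality: a treatment that narrows the spread
makes individuals more alike — more *predictable* — even if it does not
shift the average bias at all.

turnvar implements this analysis end to end: scoring turns from centroid
tracks, summarizing per-fly bias and activity, measuring group dispersion,
and testing treatment effects on dispersion and on activity.

## The dispersion statistic and its tests

For fly $i$ with $N_i$ turns, each coded $1$ (right) or $0$ (left), the
bias score is the right-turn proportion $\hat p_i$. For a group of flies
the variability index is the **raw median absolute deviation**

$$\mathrm{MAD} = \mathrm{median}_i\,\lvert \hat p_i -
\mathrm{median}_j(\hat p_j) \rvert ,$$

with the even-length median taken as the midpoint of the middle two order
statistics and **no** consistency constant (1.4826): the statistic stays on
the proportion scale and no normality is assumed. Lower MAD means higher
predictability.

Two resampling procedures quantify uncertainty and treatment effects:

* **Label-permutation test** (`perm_test_mad()`): the observed statistic is
  $\Delta = \mathrm{MAD}_A - \mathrm{MAD}_B$; under the exchangeable null
  the pooled scores are reassigned to groups of the original sizes (10,000
  permutations by default) and the add-one estimator
  $p = (1 + \#\{|\Delta^\ast| \ge |\Delta|\})/(1 + n_{\mathrm{iter}})$ is
  reported. The add-one form guarantees $p > 0$ and valid type-I control;
  the default alternative is two-sided, since a direction is rarely
  prespecified for dispersion contrasts.
* **Fly-level bootstrap** (`bootstrap_mad()`): flies are resampled with
  replacement (10,000 resamples by default); the SE of the resampled MADs
  is reported as the error bar on the group MAD, and the 2.5/97.5
  percentiles give the interval. The percentile interval was chosen over
  BCa for transparency; for a dispersion statistic of proportions at the
  group sizes involved the difference is immaterial next to permutation
  inference, which carries the hypothesis tests.

One aggregation subtlety deserves a note. A per-fly MAD of the raw 0/1
choice codes is a function only of that fly's own proportion and collapses
to 0 whenever the fly is not perfectly ambivalent, so it cannot produce
group dispersion values on the 0.05–0.1 scale that characterizes across-fly
bias spread. turnvar therefore computes the MAD **across flies** of the
per-fly proportions as its primary statistic; the per-fly variant is still
available (`group_variability(per_fly = TRUE)` aggregates the `choice_mad`
column) for anyone who wants the alternative reading, without endorsement.

Companion tests mirror standard practice: one-way fixed-effects ANOVA on
$\hat p_i$ against treatment (`anova_bias()`), with Shapiro–Wilk residual
normality and Brown–Forsythe (median-centered Levene) homoscedasticity
diagnostics attached; Kruskal–Wallis with tie correction on turns/min
(`kruskal_activity()`); and pairwise two-sided Mann–Whitney U tests
(`mann_whitney_u()`; exact null when the smaller group has at most 8
observations and the pooled data are tie-free, otherwise the normal
approximation with tie-corrected variance and continuity correction),
adjusted as one Benjamini–Hochberg family (`bh_adjust()`). The standard
steps are delegated to the standard machinery (`stats`, `car`); the MAD /
permutation / bootstrap core is implemented in the package and verified
against enumeration oracles in the test suite.

## The synthetic cohort generator

Because per-turn data for a real cohort are an external download, the
package carries a first-class generator whose hierarchical structure is the
one the analysis assumes:

$$p_i \sim \mathrm{Beta}(\mu\kappa, (1-\mu)\kappa), \qquad
r_i \sim \mathrm{LogNormal}(m, s), \qquad
N_i \sim \mathrm{Poisson}(r_i T),$$

with each of the $N_i$ turns right with probability $p_i$ and event times
uniform order statistics over the session of length $T$. The concentration
$\kappa$ is the single interpretable dispersion knob (larger $\kappa$ ⇒
smaller group MAD); the lognormal turn rate captures the right-skewed
activity distributions characteristic of these assays. Timing carries no
information beyond the turns/min rate, so uniform order statistics are
sufficient.

The default `study_config()` emulates a three-arm dietary-serotonin
experiment: control ($n = 425$), a 5-HTP arm ($n = 410$) and an
escitalopram arm ($n = 450$), 120-minute sessions, $\mu = 0.5$ everywhere
(no directional bias). The remaining parameters were fixed once, by
simulation at the population scale, so that the generated cohorts reproduce
the magnitudes that motivate the analysis: $\kappa$ of 18 / 22 / 32 gives
population group MADs of per-fly right-turn proportions of about 0.086 /
0.080 / 0.067 (dispersion reduction under the SSRI, none under 5-HTP), and
lognormal parameters $(m, s)$ of $(\log 1.24, 0.79)$, $(\log 1.20, 1.02)$,
$(\log 1.45, 1.01)$ bracket the observed turns/min medians and quartiles.
Note that the *observed* per-fly proportion spread exceeds the Beta spread
by the binomial component $\mathbb{E}[p(1-p)/N_i]$; the calibration
accounts for this, which is why $\kappa$ is larger than a Beta-only moment
match would suggest.

Seeding is hierarchical: one master seed, with each fly's draws taken from
a counter-derived substream, so appending a fly to a group never perturbs
the others — cohorts are reproducible and extensible.

What the generator deliberately does **not** emulate: within-fly
nonstationarity (bias drift over the session), between-fly interaction
(each maze holds one fly), tracking artifacts, and any treatment effect on
the *mean* bias. Passing tests therefore demonstrate the statistical
machinery under the hierarchical model, not the biological claims
themselves; real tracker output adds segmentation noise that only the
trajectory-scoring layer (below) addresses.

## Turn scoring from centroid tracks

`score_turns()` converts a centroid track into events using a
zone-commitment state machine over a symmetric maze geometry
(`maze_geometry()`: three arms, default bearings 90°/210°/330°, arm length
12 mm). Two radii create hysteresis: inside `center_radius_mm` (2 mm) the
fly is in the central decision zone; only at `commit_radius_mm` (4 mm) or
beyond is it *committed* to an arm. An event fires when the committed arm
changes; jitter smaller than half the gap between the radii provably cannot
alter the emitted sequence (a property the test suite checks with injected
noise). Points beyond the arm length (plus a 0.5 mm tolerance) are flagged
`OUT` and counted into a per-fly QC fraction. At exact sector boundaries
the lowest arm index wins — an arbitrary but deterministic and documented
tie-break.

The left/right convention is geometric and not self-evident from tracker
output, so it is explicit and flippable: with arms indexed clockwise,
moving to the clockwise-adjacent arm is a right turn (`"cw-right"`,
default). At $\mu = 0.5$ every dispersion statistic is invariant to the
flip; the convention matters only if absolute handedness is interpreted.
A real tracking pipeline may define its decision point differently (center
exit rather than arm entry); the commitment rule here is one defensible
reading, and the scoring layer is deliberately sampling-rate agnostic since
it consumes zone-commitment sequences rather than frame counts.

## Inclusion filtering

The right-turn proportion of a fly with very few turns is dominated by
binomial noise, so `summarize_flies()` excludes flies below `min_turns`
(default 10 — below that the binomial SE at $p = 0.5$ exceeds 0.15, on the
order of twice the across-fly spread being measured) and reports every
exclusion with a reason. Published df from this kind of assay frequently
imply stricter unstated filters; matching someone else's df exactly
requires matching their filter, which is why the threshold is an explicit,
recorded parameter rather than a constant.

## A worked example

```{r example}
cfg <- run_config(
  "simulate",
  synth = synth_config(
    list(
      synth_group("control", 120, bias_concentration = 18,
                  rate_log_mean = log(1.24), rate_log_sd = 0.79),
      synth_group("escitalopram", 120, bias_concentration = 32,
                  rate_log_mean = log(1.45), rate_log_sd = 1.01)
    ),
    seed = 2026),
  n_iter = 2000, n_boot = 1000, seed = 2026)
bundle <- run_pipeline(cfg)
bundle$group_variability
bundle$permutation_tests %>%
  select(group_a, group_b, mad_a, mad_b, stat_observed, p_value)
bundle$omnibus_tests %>% select(test, statistic, df1, df2, p_value)
```

The MAD gap (escitalopram below control) is the dispersion-reduction
signature; the ANOVA row shows the mean bias itself does not shift. Figures
mirror the reporting conventions of the field — a MAD barplot whose error
bars are the bootstrap SE (labeled as such, not a normal-theory SEM), and
strip plots with group medians plus compact letter displays derived from
the BH-adjusted pairwise matrix:

```{r figures, fig.width = 5, fig.height = 4}
autoplot(bundle, "mad")
autoplot(bundle, "activity")
```

## Numerical choices and degenerate inputs

* Even-length medians are midpoints of the middle two order statistics
  throughout (statistic and oracle alike).
* `bootstrap_mad()` on all-identical input returns SE 0 and a `[0, 0]`
  interval instead of failing; `kruskal_activity()` on a constant column
  reports $H = 0$, $p = 1$ (the tie-corrected statistic is otherwise
  undefined there).
* Permutation and bootstrap outputs are exactly reproducible given the
  recorded seed; the pipeline manifest echoes every seed, iteration count
  and input hash, and a run can be rebuilt from the manifest alone.
* Shapiro–Wilk is defined for at most 5000 observations; above that the
  residuals are thinned by a deterministic stride before testing.
* `n_iter` below 1000 draws a warning: with the add-one estimator the
  smallest attainable p-value is $1/(1+n_{\mathrm{iter}})$.

## Problem sizes used in validation

The test suite validates the statistic against a direct-enumeration oracle
on $10^4$ random vectors; permutation p-values against exhaustive
enumeration at group sizes (3,3), (4,3), (4,4); type-I calibration with
1000 replicate tests at $n = 100$/group and 999 permutations each (the
rejection-rate estimate needs replicates, not long nulls, so iterations per
test were kept modest by design); and power at the dispersion-reduction
effect ($\kappa$ 60 vs 20, $n = 200$/group, 50 replicates). The acceptance
script reruns the full pipeline at study scale (1285 flies) with the
default 10,000 permutations and resamples.

## Limitations

* The across-fly MAD is a cross-sectional individuality measure; with one
  session per fly it cannot separate stable individuality from slow
  within-session drift (a repeatability/ICC design would).
* The permutation test compares dispersions under full exchangeability; a
  mean shift between groups would also register. At $\mu = 0.5$ in both
  groups this is immaterial, but users applying it to mean-shifted data
  should center groups first or interpret accordingly.
* The generator's Beta-Bernoulli structure is an assumption, not a fit to
  any particular dataset; conclusions about real cohorts require the real
  event tables.
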