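---
title: "The Tlox labeling model: combinatorics, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Tlox labeling model: combinatorics, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tloxr)
```

## The reporter and what it measures

A Tlox cassette is a tandem pair of overlapping loxP sites with a stop codon
in the overlap of the second unit, placed between a constitutive GFP and a
silent tdTomato. Because Cre recombination requires a tetramer bridging two
full sites, the overlapping pair cannot recombine in *cis*; recombination
happens only in *trans*, between sister chromatids after replication. The
reporter therefore turns on **iff** a cell inherits a chromatid whose array
has collapsed to a single loxP unit — an event that requires a division —
and once on it is permanent and heritable. The tdTomato⁺ fraction of a
population is a cumulative record of divisions inside the window where the
Cre driver is expressed: a *proliferative history*, as opposed to the
instantaneous *proliferation rate* a short BrdU pulse measures.

## Crossover combinatorics

Both sisters carry the same $n$-unit array. A single crossover joining unit
$i$ on one sister to unit $j$ on the other produces arrays of $i + n - j$
and $j + n - i$ units (sum conserved at $2n$; neither can reach 0, so the
labeled state $n = 1$ is absorbing — a pair of single-loxP sisters can only
exchange equally). We assume:

* at most one crossover per division (**one Cre-mediated exchange per
  S/G2/M**), with probability $c \in [0,1]$;
* the pairing $(i, j)$ uniform over the $n^2$ possibilities;
* products segregate to daughters at random (probability 1/2 each),
  independently across divisions.

Uniform pairing is the minimal assumption that reproduces the 25%
first-cycle ceiling, and single-crossover matches how the exchange is
depicted mechanistically; whether multiple exchanges occur at very high Cre
levels is unknown, and we do not model it. The marginal daughter-array
distribution is then

$$P(n + d) = c\,\frac{n - |d|}{n^2} \;\; (1 \le |d| \le n-1), \qquad
  P(n) = (1 - c) + \frac{c}{n},$$

and a daughter becomes labeled in one division with probability $c / n^2$:
$c/4$ for the 2-unit cassette, $c/9$ for the triple-loxP intermediate, and
so on.

## Two cumulative models, kept deliberately apart

* **Simplified**: each daughter of an unlabeled cell activates independently
  with a fixed probability $p$ per division, so
  $f(k) = 1 - (1-p)^k$. At the maximal $p = 1/4$ this gives 25% after one
  cycle and 43.75% — 44% at integer-percent reporting — after two. This is
  the bookkeeping in which per-cycle labeling is usually quoted, it is
  closed-form and invertible, and it is what the inference layer uses.
* **Exact**: the array-size Markov chain. States $\{1, \dots, n_{\max}\}$,
  row $n$ equal to the marginal distribution above, state 1 absorbing. After
  two maximal cycles the labeled fraction is
  $\tfrac14 + \tfrac12\cdot\tfrac14 + \tfrac14\cdot\tfrac19 = \tfrac{29}{72}
  \approx 40.3\%$ — *below* 43.75%, because the triple-loxP cells produced
  by the first unequal exchange activate at only $1/9$ per cycle.

The quoted 44% corresponds to assuming every unlabeled cell keeps activating
at $1/4$; the exact combinatorics disagree once multiplicity states appear.
Neither number is hidden: the two variants bracket the intended biology and
tests pin both (`cumulative_label_fraction()` with
`tlox_params("simplified")` vs `tlox_params("exact")`). The simplified
variant is the default for reported numbers; the exact variant is there for
forward checks.

Numerical choices: the state space is truncated at `n_max = 32`, with
overflow mass accumulated onto the last state rather than renormalized, so
rows stay stochastic exactly; at $c = 1$ the mass beyond 32 units after 20
divisions is below $10^{-9}$, and labeled-fraction errors are far smaller
still. Percentages are rounded only at the reporting layer.

## Simulators

`simulate_population()` advances synchronous generations with two engines:
a *population* engine that tracks only counts per array-size state and
samples each daughter from the marginal distribution (daughters are
exchangeable, so population fractions are unaffected by dropping the sister
pairing — memory stays $O(n_{\max})$ at any population size), and a *tree*
engine with explicit cells and anti-correlated sister products for
lineage-level questions. Tests assert the two agree on fractions and that
both track the analytic curves within Monte Carlo error. Labeling is
monotone within every run: labeled cells double exactly while unlabeled
cells can only add, so the labeled fraction never decreases.

`simulate_culture()` models unsynchronized growth: per-cell exponential
inter-division times with mean $T_d/\ln 2$ (population doubling time
$T_d$), a Cre onset time before which divisions never label, and a joint
count over (array size, generation) so the output time series carries the
mean generation alongside the labeled fraction. A subtlety worth knowing:
with asynchronous growth the per-cell generation number at time $t$ is
dispersed, and since $(1-p)^G$ is convex in $G$, the expected labeled
fraction sits *below* the fixed-generation curve evaluated at $t/T_d$
(Jensen's inequality). Calibrations of an effective $p$ from culture data
via `fit_effective_p_timeseries()` — which uses the deterministic
$f(t) = 1 - (1-p)^{t/T_d}$ — therefore absorb that dispersion into the
effective parameter, one more reason the fitted $p$ lands below the
mechanistic ceiling. This is consistent with how such calibrations are used:
as tissue-specific empirical constants, not as crossover probabilities.

## Stage-structured development

`stage_path()` orders developmental stages with a division count each;
`cre_driver()` fixes the onset stage, with `missed_fraction` modeling a
driver that switches on part-way through its onset stage (the CD4-driven
Cre, turning on between DN3 and DN4, defaults to missing half the DN4
divisions — the data constrain the ordering, not the timing). Cumulative
Cre-active divisions map through the labeling curve, which yields the
qualitative signatures the reporter is known for: nothing at DN3 under an
Lck-driven Cre (DN3 cells do not divide), a plateau across the
non-proliferative DP→SP transition and from marrow to spleen in mature B
cells, and a persistent deficit for later-onset drivers even in
post-proliferative stages.

The shipped division counts (pro-B 2, pre-B 2, mature-B 0; DN3 0, DN4 2, DP
0, CD4SP 0, CD8SP 1) are illustrative configuration defaults, not
estimates: true per-stage counts are not identifiable from endpoint
fractions alone (inter-stage increments could also reflect differential
survival), which is why the inference layer only ever reports *effective*
divisions. One limit worth noting: with CD4SP at $F(2)$ and CD8SP at
$F(3)$, the ratio $F(3)/F(2) = (1-(1-p)^3)/(1-(1-p)^2)$ is at most 1.5
(approached as $p \to 0$), so a two-fold CD8SP/CD4SP ratio cannot arise
from one extra division in this model — the defaults reproduce the ordering
CD8SP > CD4SP, not the magnitude.

`brdu_fraction()` is the standard asynchronous-pulse closed form
$\phi \cdot \min\{1, (t_S + t_{pulse})/t_{cycle}\}$ for cycling fraction
$\phi$: label dilution and re-entry are ignored, which is adequate when the
pulse (4 h) is much shorter than the cycle (~24 h).

## Inference

`estimate_divisions()` inverts $f = 1-(1-p)^k$ at the pooled labeled
fraction; `estimate_activation_prob()` does the converse for known $k$.
Both treat the **mouse** as the resampling unit whenever at least two mice
are present — cohorts of 3–7 animals are the norm, and mouse-to-mouse
overdispersion dwarfs cell-level binomial noise — and fall back to
cell-level binomial resampling for a single mouse. A pooled fraction at or
above 99.9% raises an explicit saturation error instead of an absurd
$\hat k$.

The default interval (`ci_method = "tboot"`) pairs the bootstrap standard
error, inflated by $\sqrt{n/(n-1)}$ to undo the plug-in bias, with a
Student-$t$ quantile on $n-1$ degrees of freedom. The reason is blunt: at
$n = 3$ mice the percentile bootstrap interval is essentially the sample
range and covers far below nominal (~58% in our simulations at the designs
above), while the $t$-form measures ~95% coverage. Percentile intervals
remain available for larger cohorts. `history_vs_rate_report()` uses the
same machinery in Welch form (per-group bootstrap variances,
Welch–Satterthwaite degrees of freedom) to classify group contrasts as
up/down/similar on the rate (BrdU) and history (Tlox) axes.

`two_population_test()` permutes mouse group labels and uses
$|\hat k_a - \hat k_b|$ as the statistic, enumerating all assignments
exactly when feasible. A hard granularity fact shapes its behavior: with 3
vs 3 mice there are only $\binom{6}{3} = 20$ assignments and, by the
symmetry of the absolute difference, the smallest attainable two-sided
p-value is $2/20 = 0.10$ — no mouse-level permutation can reject at
$\alpha = 0.05$. The default `method = "auto"` therefore requires at least
4 mice per group (minimum attainable p $= 2/70 \approx 0.029$) and
otherwise falls back to a cell-level two-proportion test with a classed
warning. The fallback ignores overdispersion and is anti-conservative under
it; it is a fallback, not a recommendation. Alongside the p-value the test
reports a per-group method-of-moments intra-class correlation (one-way
ANOVA estimator on cell labels), the beta-binomial overdispersion the
generator uses.

## The synthetic-data generator

`generate_cohort()` emulates the statistical structure of gated FACS data:
per mouse a true labeled fraction from a beta distribution with mean
$1-(1-p)^k$ and intra-class correlation $\rho$ (default 0.02, which puts
simulated 3-mouse standard errors in the few-percentage-point range
reported for in vivo B-cell cohorts); per cell a Bernoulli label, a
Bernoulli BrdU status at the group's pulse fraction, and log-normal
two-component intensities per channel. The default tdTomato separation is 6
log-sd (~400-fold, a bright reporter): midpoint-gate misclassification is
the Gaussian overlap $\Phi(-\mathrm{sep}/2) \approx 0.13\%$. Note that a
3-sd separation — which sounds comfortable — already misgates ~7% of
cells, enough to visibly bias history estimates at low labeled fractions;
`gate_events()` warns below 2 sd and reports the achieved error rate
against ground truth. Otsu thresholding is available when no manifest (or
no known mixture) exists.

What the generator does **not** emulate: spillover/compensation, doublets,
dead-cell artifacts, the dim-signal compression of small DP thymocytes, or
any correlation between BrdU status and label within a mouse. Passing tests
therefore show that the estimators recover the parameters of *this*
generative structure, not that real cytometry is this clean. True
mouse-level dispersion in vivo is unknown; $\rho$ is a per-scenario knob,
recorded in every manifest.

Shipped scenarios: `scenario_b_path()` (B-lineage endpoint with $p$ solved
so the mature-B fraction sits at 0.43), `scenario_vg11_liver_node()`
(histories of 6 vs 2 divisions at $p = 0.1$, 3 mice × 3000 cells — the
liver-resident vs circulating γδ T-cell contrast), and
`scenario_id3_contrast()` (neonate pairs differing in cycling rate but not
history; adult pairs with lower cycling but more accumulated history — the
canonical rate/history discordance).

## Problem sizes used in the checks

The test suite verifies: the crossover oracle by exhaustive enumeration up
to 5-unit arrays; simulator/analytic agreement at $10^5$ cells over
$c \in \{0.25, 0.5, 1\}$ and 5 generations (3 Monte Carlo SE); division
recovery over 100 cohort replicates (3 mice × 10⁴ cells, $k$ cycling 1–6,
$p = 0.1$, $\rho = 0.02$) against the 95% intervals; activation-probability
recovery over 100 five-point culture series of 10⁴ cells; two-population
power over 200 replicates of the liver/node scenario and null calibration
over 500 replicates at 5 mice per group (Kolmogorov–Smirnov against
uniform). These sizes keep every individual check to seconds while leaving
Monte Carlo error well inside the asserted tolerances.

## Known limitations

* Crossover position uniformity and the single-crossover-per-division
  assumption are modeling choices; the effective parameters $c$ and $p$
  absorb whatever biology they miss (Cre level, cassette accessibility,
  S/G2 duration, generation-number dispersion).
* No cell death, selection or export: populations are treated as uniformly
  proliferating within a window, so differential survival masquerades as
  history.
* Inter-homolog mitotic recombination (a sub-percent effect) and reporter
  protein maturation/dilution kinetics are out of scope.
* $(k, p)$ are jointly unidentifiable from a single endpoint fraction; all
  estimators condition on one of the two.
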