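---
title: "Decomposing QTL pyramids: mixed models, epistasis and homeostasis in substitution-line trials"
author: "qtlPyramid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing QTL pyramids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlPyramid)
```

# The experimental system

Single-segment substitution lines (SSSLs) carry exactly one donor
chromosome segment in an otherwise uniform recipient genome, isolating one
QTL per line.  Crossing SSSLs produces *pyramids* that combine two or three
segments, each either heterozygous or homozygous.  Measured in a
multi-environment randomized-block trial, such a design turns QTL genetics
into arithmetic on genotype contrasts: every additive, dominance and
epistatic component is a difference between a small set of genotype means.

The package's reference design is the four-locus heading-date system in the
indica rice background HJX74 (loci *Ehd1*, *OsMADS50*, *Hd3a*, *Hd1*,
`hdLoci()`): the recipient, 4 heterozygous and 4 homozygous single-segment
lines, 24 dual-QTL and 32 triple-QTL pyramids — 65 materials
(`enumerateMaterials()`), grown in 3 environments (two natural short-day
seasons, one long-day) with complete blocks.  The response is the plot-mean
heading date in days (the mean over the plants of a plot; within-plot
plant-to-plant variation is deliberately not modelled anywhere in the
package).

# The mixed model

Each plot observation is modelled as

$$y_{hjk} = \mu + E_h + G_j + GE_{hj} + B_{k/h} + e_{hjk},$$

with environment effects $E_h$ fixed and genotypic effects $G_j$,
genotype-by-environment interactions $GE_{hj}$, blocks-within-environment
$B_{k/h}$ and plot residuals $e_{hjk}$ random.  Treating $E$ as fixed
matches the variance components actually estimated ($\sigma^2_G$,
$\sigma^2_{GE}$, $\sigma^2_B$, $\sigma^2_e$); seasons are chosen
deliberately for their photoperiod, not sampled from a population.

Three estimation layers:

* **Joint ANOVA** (`fitAnova()`): balanced two-factor ANOVA with blocks
  nested in environments, expected-mean-square coefficients under the
  random model, genotypes tested against the G×E mean square, G×E and
  blocks against the residual, and the fixed environment term against the
  Satterthwaite combination $MS_B + MS_{GE} - MS_e$.
* **MINQUE(1)** (`estimateVarianceMinque()`): minimum-norm quadratic
  unbiased estimation with all prior values set to 1 solves
  $\mathrm{tr}(QV_iQV_j)\,\theta_j = y'QV_iQy$.  A single pass is the
  default — the estimator is defined by its priors, not iterated to
  convergence — with an optional `iterations` argument.  On balanced
  designs MINQUE coincides with the ANOVA/EMS method-of-moments solution
  (`estimateVarianceAnova()`), which the test suite verifies to 1e-8
  relative; the two implementations are deliberately independent (normal
  equations vs. mean-square arithmetic) so each checks the other.
  Negative solutions are truncated to zero with a warning (BLUP needs
  nonnegative ratios); the raw solutions are retained.
* **BLUP** (`predictBlup()`): Henderson's mixed-model equations at the
  estimated variance ratios.  Predictions are identified by sum-to-zero
  conventions: $G$ centred, $GE$ double-centred and $B$ centred within
  environment, the absorbed means folded into $\mu$, $G$ and $E$.  Genotype
  *contrasts* — everything the decomposition uses — are unaffected by this
  identification.  When $\hat\sigma^2_e = 0$ the equations reduce to least
  squares and the exact balanced decomposition of cell means is returned;
  when a component is estimated as zero its predictions are exactly zero.

Heritability (`heritability()`) reports the genotypic (general) and
interaction (peculiar) shares of phenotypic variance.  The denominator is
the plot-level variance $\sigma^2_G+\sigma^2_{GE}+\sigma^2_B+\sigma^2_e$ by
default; published heritabilities for such trials do not always state their
basis, so an entry-mean basis (`basis = "mean"`, dividing $\sigma^2_{GE}$
by $H$ and the block/plot terms by $HK$) is available and always reported
explicitly.  Heritabilities are functions of the particular field data and
are not reproducible from effect tables alone; the package makes no claim
about any published value.

# The effect decomposition

All effects use the substitution-line convention, *not* the classical
midparent parameterization:

* additive $a$ = homozygote − recipient; dominance $d$ = heterozygote −
  recipient (`estimateSingleEffects()`).  The dominance degree is the
  literal ratio $d/a$ (`dominanceDegree()`), with $|d/a|>1$ labelled
  super-dominant.
* pyramiding $g$ = pyramid − recipient (`estimatePyramidingEffects()`).
* dual epistasis $e = g - \sum s$, the residual of $g$ over the
  constituent single effects ($d$ for a heterozygous locus, $a$ for a
  homozygous one) (`estimateDualEpistasis()`).
* mixed epistasis (order-3) $e_{mixed} = g - \sum s$
  (`estimateMixedEpistasis()`), bundling the pairwise and pure-triple
  interactions.
* triple epistasis $e_3 = e_{mixed} - \sum e_{dual}$
  (`estimateTripleEpistasis()`).

Two conventions matter and are enforced:

* **Nonsignificant constituents are never zeroed.**  Higher-order
  residuals subtract the *estimated* lower-order values, significant or
  not.  Zeroing them would bias every residual; published tables built
  this way only close arithmetically because their unprinted entries were
  carried internally at full value.  Conversely, when a constituent is
  genuinely unavailable (its material missing, or a printed table omitting
  a nonsignificant value whose magnitude is therefore unknown), the
  dependent effect is reported as `NA` — undefined, never zero.
* **Environment interactions are deviation coded.**  Every effect's
  per-environment components sum to zero over environments; per-environment
  stars test each deviation separately.  An effect whose main value is
  nonsignificant but which has a significant environment deviation is
  reported descriptively ("significant only in particular environments")
  and still participates in counts.

`estimateEffectsLm()` provides an algebraically independent route: least
squares of the genotypic predictions on the hierarchical indicator design
(intercept, per-locus hom/het indicators, pair- and triple-combination
indicators).  On the saturated design its coefficients equal the
sequential differences to machine precision — a structural identity the
tests assert at 1e-9 — and it generalizes to reduced designs, naming
aliased columns when the design cannot support the parameterization.

## Significance

Every effect is a linear contrast over genotype means (inclusion–exclusion
over the material's sub-combinations: e.g. a triple interaction is
$+\bar y_{ABC} - \sum \bar y_{\mathrm{pairs}} + \sum \bar
y_{\mathrm{singles}} - \bar y_{\mathrm{recipient}}$).  Tests are two-sided
t statistics of these contrasts against the plot residual variance of the
joint ANOVA: a main-effect contrast $c$ has
$SE^2 = \sum c^2\,\hat\sigma^2_e/(HK)$, an environment deviation
$SE^2 = \sum c^2\,\frac{H-1}{H}\hat\sigma^2_e/K$, with the ANOVA error
degrees of freedom.  The tests are computed from the *unshrunken* genotype
and cell means, so they are invariant to BLUP shrinkage; under a null
model this makes the procedure an exact t test, and the suite verifies the
empirical size at $\alpha=0.05$ by simulation.  Reported values are the
BLUP-based estimates (stabilized toward zero under noise), while `se` and
`p` describe the corresponding least-squares contrast; in the noise-free
limit the two coincide exactly.  Stars follow the table convention
(`**` for $p \le 0.01$, `*` for $0.01 < p \le 0.05$).  P-values are raw
per-contrast values — the reporting convention of this literature — with
`adjustSignificance()` available for FDR/family-wise control.  With zero
residual degrees of freedom (or a zero residual variance) p-values are
withheld rather than fabricated.

# The synthetic-data generator

`TruthModel` + `simulateExperiment()` generate plot data with exactly the
structure the estimators assume: fixed environment shifts, genotypic
values accumulated from the truth terms (`genotypicValue()`), interaction
values accumulated from zero-sum per-effect environment rows
(`interactionValue()`), Gaussian blocks and Gaussian plot residuals,
homoscedastic across environments.  The exported ground truth
(`truthEffects()`) has the same shape as the estimated table, so
parameter-recovery tests are a table diff; noise-free simulation followed
by the full pipeline recovers every truth term to 1e-9 days, which is the
package's core correctness guarantee.

Defaults are chosen once, as realistic values for plot-mean heading date
in a two-season rice trial, and are not tuned to any estimator:

* `blocksPerEnv = 3`: replicate counts are rarely printed for such trials;
  three complete blocks is standard practice and gives nonzero error
  degrees of freedom at desk scale.
* `hdTruthPreset()`: effect magnitudes taken verbatim from the packaged
  printed tables (unprinted nonsignificant terms set to 0), grand mean
  85 d, environment shifts (−4, +7, −3) d reflecting two short-day and one
  long-day season, block SD 1 d, and plot-residual SD 1.5 d — small,
  because the plot value is already a mean over many plants.  Printed
  interaction rows are completed to zero-sum deviation rows (unprinted
  environments absorb the negative of the printed sum, split equally).
* `simulateVarianceModel()` draws every random term from its distribution
  at stated variance components, the generating model under which the
  variance-component estimators are evaluated.

What the generator does *not* emulate: within-plot variance (inputs are
plot means by design), heteroscedastic environments, spatial field trend,
non-Gaussian error, segregation distortion or genotyping error (states are
known, not inferred).  Passing recovery tests therefore demonstrates
correctness of the estimators under the stated model, not robustness of
the model to real field data.

# Packaged printed tables

`hdPrintedEffects()` loads the published effect tables of the reference
four-locus study as fixtures (values to one decimal, days).  Conventions
of the transcription: blank printed cells are `NA` with empty stars
(tested, not significant, magnitude unknown); when a row prints fewer
environment-interaction terms than environments, the terms are stored
left-to-right from `e1`, since the extraction does not preserve column
positions — no packaged identity depends on the placement.  The
decomposition identities that *are* arithmetically closed over printed
inputs (dual epistasis from $g-\sum s$, mixed epistasis, triple epistasis
from mixed minus printed duals) are reproduced by the package's operations
to the printed precision, and the count summaries (24 dual components, 18
significant, 10 of them negative; 29 of 32 mixed epistases significant =
90.6%) are reproduced exactly.  Counts are always *literal* counts of
starred entries; where a published denominator excludes
"significant-only-in-particular-environments" entries, the package reports
the literal count as primary (e.g. 27 of 32 starred triple interactions)
and leaves the narrower denominators to the reader.

# Sign summaries, homeostasis and the locus network

`summarizeSigns()` and `classStats()` aggregate a table by decomposition
level and by component class (`a-a`, `d-d`, `d-a-d`, ...).  Class means
use significant entries by default — the convention behind published
class-mean ± SD statements — with `significantOnly = FALSE` as the
alternative.  `homeostasisReport()` formalizes the buffering pattern: the
signs of the summed significant singles, dual and triple epistases, and
per pyramid the neutralization fraction
$|e_{epi}|/|\sum s|$, flagging pyramids whose epistasis opposes the
single-effect sum.

`buildNetwork()` classifies ordered locus pairs from the dual-epistasis
evidence (focal state × background state; the change of a focal effect in
an order-1 background *is* the pair's dual epistasis).  "Unchanged" is
operationalized as: not significant at $\alpha$, or smaller than 1 day in
magnitude (both configurable — the underlying literature gives no numeric
rule).  A changed piece of evidence promotes when it pushes the focal
effect further in the direction of its own solo effect and inhibits when
it pulls it back toward (or past) zero; this magnitude-based reading is
what makes a negative-effect locus "promoted" by epistasis that makes it
more negative.  An edge is called only when a strict majority of the
evidence (more than half: at least 3 of the 4 state combinations) shows a
change; a single deviating state combination leaves the pair independent.
This majority rule is a deliberate design choice: demanding that *all*
evidence be unchanged would let one marginal contrast manufacture an edge,
and at the half-way point a single false positive stacked on a single true
deviation would do the same — a strict majority makes the call robust to
one borderline contrast either way.  Heterozygous and homozygous focal states
are additionally classified separately, because they can and do respond in
opposite directions; ties at the pair level are reported as `ambiguous`,
never silently resolved.

# Numerical choices and limitations

* Balance is required and checked (every environment × block × material
  cell exactly once); unbalanced data fail loudly rather than silently
  reweighting.
* Negative variance solutions truncate to zero (warned, raw kept); a
  singular MINQUE system names the confounded components.
* Zero residual variance short-circuits the mixed-model equations to the
  exact cell-mean decomposition (threshold 1e-10 relative to the total
  variance, protecting the solver from degenerate ratios).
* Reports round to 0.1 d (`renderEffectReport()`); full precision is kept
  internally and in the machine files.
* Problem sizes in the test suite are chosen for desk-scale determinism:
  the 585-plot reference design for round trips, a 13-material design with
  200 seeded replicates for variance-component recovery, and a 27-material
  null design with 20 replicates (1080 contrasts) for test calibration.
* The package estimates statistical, not biological, epistasis: network
  edges are background-dependence of effects, not claims about molecular
  regulation; loci are known a priori (no mapping, no marker calling).

# A worked run

```{r, eval = FALSE}
catalog <- enumerateMaterials(hdLoci(), 3)     # 65 materials
truth   <- hdTruthPreset()
plots   <- simulateExperiment(truth, catalog, seed = 1)  # 585 plots
vc      <- estimateVarianceMinque(plots)
fit     <- predictBlup(plots, vc)
effects <- decomposeEffects(fit, catalog)
summarizeSigns(effects, "dualEpistasis")
homeostasisReport(effects)$pattern
buildNetwork(effects)
```

`runPipeline()` drives the same chain from a configuration list or YAML
file and writes every intermediate as delimited text with a provenance
record (configuration hash and seed), byte-reproducibly.
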