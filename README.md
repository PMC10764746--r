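# qtlPyramid

Quantitative-genetic analysis of **QTL pyramiding trials with
single-segment substitution lines (SSSLs)**: lines that carry exactly one
donor chromosome segment in a uniform recipient background, and their
dual/triple pyramids.  The package is written for geneticists and breeders
who run such multi-environment randomized-block trials (the reference
design is the four heading-date loci *Ehd1*, *OsMADS50*, *Hd3a*, *Hd1* in
the rice background HJX74) and want the complete chain from plot records to
effect tables, epistasis summaries and a locus promote/inhibit network.

## The model and the decomposition

Plot-mean phenotypes follow the mixed linear model

```
y_hjk = μ + E_h + G_j + GE_hj + B_k/h + e_hjk
```

with environments `E` fixed and genotypes `G`, genotype-by-environment
`GE`, blocks-within-environment `B` and plot error `e` random.  Variance
components are estimated by **MINQUE(1)** (minimum-norm quadratic unbiased
estimation with all priors 1; equal to the ANOVA/EMS solution on balanced
designs), and realized `G`/`GE` values are predicted by **BLUP** from
Henderson's mixed-model equations.

Predicted genotypic values are then decomposed hierarchically, in the
substitution-line convention (all deviations from the recipient):

| effect | definition |
|---|---|
| additive `a` | homozygous single-segment line − recipient |
| dominance `d` | heterozygous line − recipient |
| pyramiding `g` | multi-segment pyramid − recipient |
| dual epistasis `e` | `g − Σ` constituent single effects |
| mixed epistasis (order 3) | `g − Σ` singles (pairs + triple combined) |
| triple epistasis `e3` | mixed `e` − `Σ` dual `e` of the three sub-pairs |

with the same contrasts applied per environment (deviation coded, summing
to zero) for `ae`, `de`, `ge`, `ee`, and t-tests of every contrast against
the plot residual variance.  Sign summaries, component-class statistics
(`a-a`, `d-d`, `d-d-d`, ...), a homeostasis report (do epistatic sums
neutralize the single-QTL sums?) and a pairwise promote/inhibit network
complete the pipeline.  A seeded synthetic-data generator with exported
ground truth makes every estimator testable by exact round trip.

## Worked example

```r
library(qtlPyramid)

catalog <- enumerateMaterials(hdLoci(), 3)   # the 65-material design
plots   <- simulateExperiment(hdTruthPreset(), catalog, seed = 1)  # 585 plots
vc      <- estimateVarianceMinque(plots)
fit     <- predictBlup(plots, vc)
effects <- decomposeEffects(fit, catalog)
```

```
> vc
VarianceComponents (MINQUE1)
      G      GE       B       e
83.3952 19.5229  0.6040  2.2443
> round(heritability(vc), 3)
 general peculiar
   0.788    0.185
```

Most phenotypic variance here is genotypic (`general` heritability 0.79),
with a modest interaction share (`peculiar` 0.19) — as expected from the
preset, whose genetic effects dwarf its 1.5-day plot noise.  The effect
table renders in the field's one-decimal star convention:

```
> head(renderEffectReport(effectSubset(effects, c("additive", "dominance"))), 4)
      kind       id class effect     e1    e2   e3
  additive     Ehd1     a  3.7**   -0.2   1.1 -0.9
 dominance     Ehd1     d  3.9** -2.6** 4.5** -1.9
  additive OsMADS50     a -5.3** -3.0** 3.0**  0.0
 dominance OsMADS50     d -7.7**   -0.6   1.3 -0.7
```

(*OsMADS50* shortens heading date, the other loci delay it; per-environment
columns are interaction deviations that sum to zero.)  Downstream
summaries:

```
> summarizeSigns(effects, "dualEpistasis")[, c("n_total", "n_significant", "n_negative_significant")]
  n_total n_significant n_negative_significant
1      24            18                     11
> homeostasisReport(effects)$pattern
[1] "positive/negative/positive"
```

18 of the 24 dual epistatic components are significant and most of those
are negative while the single-QTL effects are predominantly positive — the
homeostasis pattern: first-order interactions oppose the aggregated
single-QTL effects, buffering the pyramid's total change.  The network
stage classifies locus pairs from the background-dependence of their
effects:

```
> net <- buildNetwork(effects)
> net[net$source %in% c("Hd1", "Hd3a") & net$target %in% c("Ehd1", "Hd1"), 1:3]
 source target    relation
   Hd3a   Ehd1   ambiguous
   Hd3a    Hd1    promotes
    Hd1   Ehd1 independent
```

*Hd1* leaves *Ehd1* unchanged (independent), *Hd3a* promotes *Hd1*, and
*Hd3a*'s heterozygote and homozygote push *Ehd1* in opposite directions,
reported per state in the `detail` column.  `runPipeline(config)` drives
the same chain from a YAML/list configuration and writes every
intermediate as CSV with a provenance record.

The published effect tables of the reference four-locus study ship as
plain-text fixtures (`hdPrintedEffects()`), so the decomposition identities
can be checked directly against printed values.

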