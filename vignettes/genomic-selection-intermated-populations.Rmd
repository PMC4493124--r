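---
title: "Genomic selection in intermated biparental populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection in intermated biparental populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gsimpop studies how the accuracy of genomic selection (GS) in maize-style
intermated biparental populations depends on training-population size,
marker density, linkage disequilibrium (LD) and genetic relationship. It
bundles a population and trait simulator, genotype imputation, LD and
kinship statistics, an RR-BLUP predictor and a cross-validation engine.
This vignette explains the underlying models, the tunable parameters, and
the design decisions taken where the methodology left choices open.

## The prediction model

Line-mean phenotypes of a training set are modelled as

$$y = \mu \mathbf{1} + X g + e,$$

where $X$ is the $N_P \times N_M$ matrix of marker codes (0 for the AA
homozygote, 2 for BB — fully inbred lines carry no heterozygote class),
$g$ the vector of marker breeding values with prior
$g_i \sim N(0, V_g / N_M)$, and $e$ residuals on the line-mean scale. The
mixed-model equations then amount to ridge regression with

$$\lambda = \frac{V_e / n_{\mathrm{reps}}}{V_g / N_M}.$$

Two equivalent solvers are provided: the primal solve of the
$(N_M + 1)$-dimensional equations and a dual, observation-dimension solve
via $g = X'(XX' + \lambda I)^{-1}(y - \hat\mu\mathbf{1})$ with the GLS
intercept. `fit_rrblup(method = "auto")` picks the dual path whenever
$N_M > N_P$, which is the typical regime here; the test suite asserts
agreement of the two paths to $10^{-8}$ relative error.

Choices worth flagging:

* **Coding basis.** $X$ is kept at $\{0, 2\}$ rather than centred to
  $\{-1, 1\}$; the intercept absorbs the shift, and predictions are
  invariant.
* **Residual basis.** The model's $e$ applies to means of replicated
  plots, so the effective residual variance is $V_e / n_{\mathrm{reps}}$.
* **Variance components** come from a one-way ANOVA
  (`estimate_variance_anova()`): $V_e = MS_W$, $V_g = (MS_B - MS_W)/r$
  truncated at zero, $h^2 = V_g / (V_g + V_e / r)$ on the line-mean basis,
  with $r$ the harmonic-mean replicate count for unbalanced data. No REML
  refit is attempted. For the canonical seven-scenario analysis a single
  set of mixed-population estimates drives both $\lambda$ and the accuracy
  rescaling.
* **Accuracy.** For a validation set, $r_{MP}$ is the Pearson correlation
  between predicted and observed line means and
  $r_{MG} = r_{MP} / h$ rescales it to the genotypic-value scale. $r_{MG}$
  is reported uncapped; values above 1 are possible by construction when
  sampling noise is large.

## The population simulator

`sim_population()` emulates intermated biparental designs: two fully
homozygous founders, an F1, an F2 pool, $t$ generations of random
intermating, then line derivation either as doubled haploids (Syn10-like,
$t = 10$) or by repeated selfing (Syn4-like recombinant inbred lines,
$t = 4$). Meiosis follows the Haldane model — crossover counts Poisson
with mean equal to the chromosome length in Morgans, positions uniform on
the genetic scale, no interference. Defaults:

| parameter | default | rationale |
|---|---|---|
| intermating pool size | 200 | pedigree sizes unreported for the real populations; 200 keeps drift modest |
| offspring per pairing | 1, parents drawn anew per offspring | neutral random mating, no selfing |
| RIL selfing generations | 6 | residual heterozygosity below 1%; leftovers resolved by doubling a random allele |
| base genome | 10 chromosomes, 1,800 cM, 2 Gb | maize-like F2-scale map |
| lines | 244 (Syn4-like), 194 (Syn10-like) | the two study panels |
| markers | 1,339 / 6,611 | the two panel densities |

The base-map length deserves a note. Published maps of such populations
are *expanded* maps: recombination accumulated over intermating makes the
apparent map longer than the F2 map. Under this simulator the expansion
factor is about 4 for the Syn4-like design (one F2 meiosis, four
intermating generations, selfing) and about 6.5 for the Syn10-like design,
so the 1,800 cM base yields expanded maps near 7,500 and 11,700 cM with a
ratio of roughly 1.55. `estimate_expanded_map()` recovers the expanded map
from line genotypes by inverting the adjacent-marker discordance rate
through the Haldane function, $d = -50 \ln(1 - 2\hat c)$ cM, capping
saturated intervals at a configurable distance.

Marker positions are jittered around a uniform grid with a deterministic
golden-ratio sequence (chromosome ends fixed). A perfectly regular grid is
not only unrealistic, it creates an exact-midpoint degeneracy for
flanking-marker imputation in which every interpolated marker is
equidistant from both flanks and the tie rule would dominate the result.

`sim_trait()` draws additive QTL effects from a standard normal and
rescales breeding values so their sample variance equals the target $V_g$
exactly; plot residuals are i.i.d. normal with
$V_e = n_{\mathrm{reps}} V_g (1 - h^2)/h^2$, the value at which the
expected line-mean heritability equals the target. The full-study wrapper
`sim_gs_study()` draws 17 QTL positions uniformly on the genetic map as
*off-panel* loci — markers tag QTL only through LD, which is the situation
GS faces in practice. Default targets ($V_g \approx 900$–$1{,}075$,
$h^2 \approx 0.79$–$0.81$ per population; $V_g = 1{,}022.71$,
$h^2 = 0.80$ for the mixed set) match growing-degree-day-scale variance
components of the two real panels.

What the generator does *not* emulate: selection, segregation distortion,
residual heterozygosity in outputs, genotyping error (error enters only
through the imputation module's emission model), non-uniform recombination
along chromosomes, and marker ascertainment. Passing directional tests on
these simulations therefore demonstrates internal consistency of the
method chain under neutral conditions, not agreement with every feature of
the real panels; see "Known limitations".

## Imputation

`impute_missing_hmm()` fills missing codes with a two-state (AA/BB) hidden
Markov model per line and chromosome: uniform initial distribution (the
designs are symmetric), Haldane transition probabilities from the panel's
own — expanded — genetic map, and a symmetric emission error rate
$\varepsilon$ (default 0.01, configurable; the value used in the original
analyses is unstated). Each missing cell takes the posterior-mode state
from the forward–backward pass; posterior ties at exactly 0.5 are left
missing and reported. Observed cells are never altered.

`impute_cross_panel()` projects a dense marker panel onto sparsely
genotyped lines by physical position: copy at coincident positions,
otherwise take the genotype shared by agreeing flanks, the physically
nearer flank when they disagree, the single flank beyond chromosome ends,
and missing at exactly equidistant disagreeing flanks (no rule is stated
for that tie in the source methodology).

A note on attainable accuracy: with expanded adjacent spacing around
5 cM (adjacent recombination fraction $c \approx 0.05$), a masked marker
whose flanks disagree is genuinely ambiguous — the optimal per-cell rule
errs at roughly $2c(1-c)\,E[\min(u, 1-u)]$ where $u$ is the relative
position in the interval. Imputation error of a few percent at Syn4-like
density is therefore a property of the data, not of the algorithm; the
acceptance script reports the measured recovery.

## LD, kinship and marker sets

* `pairwise_r2()` is the squared Pearson correlation of two code columns,
  identical to haplotype $r^2$ for fully homozygous biallelic data; pairs
  with missing values are dropped and monomorphic columns yield `NA`,
  excluded from averages.
* `ld_decay_curve()` averages $r^2$ over intra-chromosomal pairs in
  half-open 100-kb physical-distance bins (left-closed; distance
  $|bp_a - bp_b|$); empty bins are emitted with `NA`.
* `alam()` — average LD between adjacent markers of a marker set — uses
  literal adjacent pairs of the subset in map order. An alternative
  reading (binned LD evaluated at the set's mean spacing) exists; literal
  adjacency was chosen as the direct interpretation, and the two differ
  little on smooth decay curves.
* `kinship_matrix()` is proportion-IBS: the fraction of markers with equal
  codes. The convention used by the original TASSEL computation is
  unstated and its printed values cannot be reproduced by any plain IBS on
  biparental homozygous data, so only orderings and structure — not
  absolute kinship values — should be compared across conventions.
* `sample_marker_set()` draws evenly distributed marker sets by splitting
  the genome-wide cumulative cM axis into $N_M$ equal strata and sampling
  one marker per stratum, reassigning empty strata to the nearest stratum
  with markers to spare. Sets are redrawn independently per repeat.

## The scenario engine

`gs_scenarios()` fixes the seven training/validation configurations for
two populations: within-population (1, 2), between-population (3, 4 —
training in one, validating on the *entire* other population, which
maximises validation precision since no subsampling is stated for these
cases), and across-population with an equally mixed training set (5–7;
scenario 5 pools both populations' remainders as validation). Training and
validation sets are disjoint by construction, and `run_grid()` iterates
scenarios over $N_P \in \{30, \dots, 180\}$, $N_M$ from 100 up to the full
panel, and (by default) 100 repeats, fitting RR-BLUP per cell and
recording $r_{MP}$ and $r_{MG}$. Per-repeat seeds derive from the master
seed through a counter-based scheme, so any repeat is reproducible in
isolation and the full table is bit-identical under a fixed seed; repeats
with fewer than three usable validation lines are skipped and logged, and
cell summaries average only completed repeats.

`lsd_bonferroni()` compares cells within a scenario by one-way ANOVA of
repeat-level $r_{MG}$ with the $(N_P, N_M)$ cell as factor:
$LSD = t_{1-\alpha'/2, df_E} \sqrt{2\,MSE/n}$ with
$\alpha' = \alpha / \binom{k}{2}$, harmonic-mean $n$ under unequal repeat
counts.

## Problem sizes used by the test and acceptance runs

The shipped suites simulate the two panels at full size (244 × 1,339 and
194 × 6,611) once per run and reuse them; accuracy grids for the
directional checks use $N_M \in \{100, 800, \text{full}\}$,
$N_P \in \{30, 180\}$ with 50 repeats in the tests and 30 in the
acceptance script, and oracle-vs-solver comparisons cover 200 random
instances up to $N_P = 100$, $N_M = 2{,}000$. These sizes give
Monte-Carlo standard errors well below the directional effects being
asserted.

## Known limitations

* Neutral intermating with equal pool sizes makes mean proportion-IBS
  kinship *increase* with intermating generations
  ($E[K] = 0.5 + 2\,\mathrm{Var}(p)$, and drift variance is monotone in
  generations), so the ten-generation DH panel shows slightly higher mean
  kinship than the four-generation RIL panel. Real panels show the
  opposite ordering, which requires segregation distortion and/or a
  different kinship convention; the package reports both means and leaves
  the interpretation to the analyst.
* The HMM imputation error floor discussed above means masked-cell
  recovery saturates near 95–96% at Syn4-like density on clean simulated
  data.
* No between-year or spatial field structure: plot residuals are i.i.d.,
  so the ANOVA is strictly one-way.
* Bayesian shrinkage regressions, kernel methods and pedigree-expected
  kinship are out of scope.
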