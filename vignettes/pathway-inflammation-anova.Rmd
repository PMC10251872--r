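---
title: "Mixed-model gene-set ANOVA for paired tumor-normal studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model gene-set ANOVA for paired tumor-normal studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsanova)
```

`gsanova` implements pathway-level differential expression and promoter
methylation analysis for paired tumor/adjacent-normal designs: gene-level
and gene-set mixed ANOVA with method-of-moments variance components,
signed fold-change reporting, differential-pathway calling and Venn
intersection, stratified replication with interaction tests, chi-square
category enrichment, and delta-beta methylation scoring. This vignette
documents the models, the estimation machinery, the conventions, and the
design decisions behind them.

## The models

### Gene-level paired model

For a single probe, the response (log2 expression, or a methylation beta
value) is modeled as

$$Y_{ijk} = \mu + \mathrm{Tumor}_i + \mathrm{Person}_j + \varepsilon_{ijk},$$

with Tumor a two-level fixed effect (tumor minus normal is the quantity
reported), Person a random effect with variance $\sigma_P^2$ — persons are
a random sample of a population, and the paired design makes them blocks —
and $\varepsilon \sim N(0, \delta^2)$ independent. Assumptions: Gaussian
additive effects on the log2 scale, homoscedastic errors, and person
effects exchangeable across patients.

### Gene-set model

A pathway's evidence is pooled by stacking all member-probe observations:

$$Y = \mu + T + P + G + S(T \times P) + \varepsilon,$$

where $T$ is the tissue effect (fixed), $G$ the gene/probe baseline
(fixed; implemented at probe resolution so probes of the same gene keep
their own baselines), $P$ the person effect (random) and $S(T\times P)$
the sample effect (random, nested in tissue-by-person: all probes measured
on one physical sample share its draw). The sample term is what prevents
the set-level test from treating $m$ genes on the same array as $m$
independent replicates — omitting it would understate the standard error
roughly by a factor $\sqrt{m}$ when sample-level noise dominates.

The analysis is performed at the gene level and expressed at the set level
by **averaging the member genes' effects**: the reported set effect
$\bar d$ is the unweighted mean of per-gene tumor effects (each estimated
by the paired machinery on that gene's probes), while the standard error
and degrees of freedom come from the tissue contrast of the stacked model.
Averaging is done on the log2 scale, not on fold changes; the two are
identical for homogeneous sets and the log2 average is the one with an
additive interpretation for heterogeneous ones.

### Interaction (stratified replication) model

Replication across strata (stage, grade, MSI, KRAS, sex, TIL) uses the
two-way fixed model

$$Y = \mu + \mathrm{Tumor} + \mathrm{Stratum} + \mathrm{Tumor}\times\mathrm{Stratum} + \varepsilon,$$

reporting each stratum's tumor fold change with confidence interval and
the interaction F test. Deliberately, the default carries **no person
term** even though the data are paired — that is the model as specified,
and the stratum is a person-level covariate, so a person block would
absorb the stratum main effect. A blocked variant is available via the
`person` argument of `fit_interaction_model()` (person entered as a fixed
blocking factor; aliased stratum main effects are dropped, the per-stratum
tumor contrasts and the interaction term remain estimable). For pathway
tables, `replicate_stratified()` stacks member probes and absorbs probe
baselines through the `baseline` argument; without that adjustment probe-
to-probe baseline spread would swamp the residual.

## Estimation

**Variance components: Henderson Method III.** Components are estimated by
equating sequential reductions in sums of squares to their expectations.
With fixed design $X$ and random-term indicator matrices $Z_1, \ldots,
Z_K$ (nesting order: person, then sample), define $R_k =
\mathrm{SSR}([X\,Z_1..Z_k]) - \mathrm{SSR}([X\,Z_1..Z_{k-1}])$ and the
residual $\mathrm{SSE}$. Then
$E[\mathrm{SSE}] = (n - r_K)\,\sigma_e^2$ and
$E[R_k] = (r_k - r_{k-1})\,\sigma_e^2 + \sum_{j \ge k}
\mathrm{tr}\!\left(Z_j^\top (P_k - P_{k-1}) Z_j\right) \sigma_j^2$,
a triangular system solved from the bottom up. No likelihood is maximized;
the estimates are closed-form quadratic forms, which also makes them fast
and deterministic. Negative solutions are clamped to zero and flagged in
the result (`variance_components$clamped`) — the standard method-of-moments
pathology on designs where a component is small.

**Fixed effects: GLS at the plug-in components.** The tumor contrast and
its standard error come from generalized least squares with
$V = \sum_k \hat\sigma_k^2 Z_k Z_k^\top + \hat\sigma_e^2 I$, computed via
the Woodbury identity so only a $q \times q$ solve is needed ($q$ = total
random levels). On balanced paired data this reduces exactly to the mean
within-pair difference, and the tumor F equals the squared paired $t$ —
an identity the test suite enforces to $10^{-8}$ relative.

**Degrees of freedom: Satterthwaite.** For unbalanced designs the
denominator df is approximated by linearizing the contrast variance in the
observed quadratic forms $(R_1, \ldots, R_K, \mathrm{SSE})$ and matching
moments of the resulting linear combination. On balanced paired data this
recovers the exact $n-1$.

**Degenerate inputs.** Noise-free data (residual variance 0) are handled
by flooring $\hat\sigma_e^2$ at a relative $10^{-12}$ so the GLS solve
stays defined; effects are then recovered to machine precision and the
interval collapses. A pathway with fewer than two member genes on the
platform cannot separate the gene baseline from the set effect and is
skipped with a recorded reason rather than fitted.

## Conventions

- **Signed fold change.** $FC = 2^d$ for $d \ge 0$, $-2^{-d}$ for
  $d < 0$; values in $(-1, 1)$ are impossible. Confidence intervals are
  t-intervals on $d$ mapped endpoint-wise; because the transform jumps
  from $-1$ to $+1$ at $d = 0$, a null gene's interval can straddle the
  gap (e.g. FC 1.02, 95% CI $-1.009$ to $1.06$).
- **Percent regulation** is $(|FC| - 1) \times 100$ with direction from
  the sign — the convention that pairs an FC of $-1.72$ with "down by
  72%". Note this is *not* $1 - 1/|FC|$; the package follows the
  published pairing.
- **FDR.** Benjamini–Hochberg step-up (via `stats::p.adjust`), the field
  default; adjustment is across probes for gene tables and across fitted
  pathways for set tables.
- **Thresholds.** Discovery lists use FDR $\le 0.05$ *and* $|FC| \ge 2$ at
  the pathway level; replication uses FDR alone (`min_abs_fc = 1`). Both
  are configurable (`pipeline_config()`).
- **Enrichment.** The chi-square compares "significant genes in category /
  all significant genes" with "chip genes in category / all chip genes" as
  a category-vs-rest 2×2 Pearson test, no continuity correction by default
  (a Yates flag exists). The score is $-\log_{10} p$; base 10 keeps scores
  readable as orders of magnitude and is configurable. Zero expected
  counts yield $p = 1$, score 0, flagged. The significant-gene total is
  used as given, without re-restricting to the category universe.
- **Quantile normalization** maps every column to the mean of sorted
  columns, ties sharing the mean of their target quantiles
  (`limma::normalizeQuantiles(ties = TRUE)`). **Log2 CPM** is
  $\log_2(\mathrm{count}/\mathrm{libsize} \times 10^6 + c)$ with
  pseudocount $c = 1$ by default (configurable): a zero count maps to 0
  and per-library rescaling leaves values unchanged.
- **Methylation.** Beta is $X/(X+Y)$; both-zero intensity pairs become
  counted missing values. Betas are modeled *untransformed* (no M-value
  logit): the beta value itself is the response of record, its bounded
  scale is what "delta beta" is defined on, and tumor-normal differences
  of ~0.1–0.3 sit far from the boundary where heteroscedasticity bites.
  Markers map to genes via the annotation table; a multi-gene marker
  contributes to each mapped gene (the 450K annotation convention).
  Missing betas are dropped observation-wise. The promoter analysis
  defaults to promoter-associated markers in CpG islands only (open sea
  excluded chip-wide; shore/shelf excluded for the promoter question,
  which the island-focused definition of promoter CpG methylation
  supports).

## The synthetic-data generator

`simulate_expression_study()` draws from exactly the decomposition the
models assume: grand mean, per-gene baselines
$N(0, \mathrm{gene\_baseline\_sd}^2)$, pathway-driven tumor effects (with
optional per-stratum interaction deltas), person effects
$N(0, \sigma_P^2)$, sample effects $N(0, \sigma_S^2)$ nested in person and
tissue, and iid error. All effects are Gaussian on the log2 scale. Strata
are assigned per person, independently of effects unless interaction
deltas are configured — the simplest structure under which interaction
tests can be calibrated against a true null. Each study uses a single RNG
stream seeded once, so a fixed seed reproduces the whole study bit for
bit; the caller's RNG state is restored afterwards.

Default noise magnitudes ($\sigma_P = 0.5$, $\sigma_S = 0.3$,
$\delta = 0.5$ log2 units) are package defaults chosen as typical for
log-scale expression data with strong inter-individual variation; no
cohort-derived values exist to calibrate against.

`simulate_methylation_study()` shares the person/tissue layout of its
expression design and emulates a 450K-style marker panel: a mean of 17
markers per gene, island-relation proportions following the chip-wide
category counts (Island 0.31, Shore 0.23, Shelf 0.10, open sea 0.36),
island markers mostly unmethylated and open-sea markers mostly methylated.
Beta values arise from Gamma-distributed methylated/unmethylated intensity
pairs — mirroring the $X/(X+Y)$ definition and keeping betas naturally in
$[0,1]$ rather than clipping Gaussians — with a person-level logit shift
for within-person correlation. Hyper-methylation effects are added on the
probability scale to the promoter-island markers of the configured
pathways in tumor samples, so the planted tumor-normal delta-beta equals
the configured effect.

What the generator does **not** emulate: read-level RNA-seq noise
(counts enter only through the log2-CPM transform), probe sequence and
Infinium I/II chemistry effects, batch/chip effects, correlated gene-gene
networks beyond shared pathway effects, and cell-composition mixtures.
Passing tests therefore demonstrate correctness of the estimators under
the assumed hierarchical Gaussian model, not robustness to those
real-data artifacts.

## Numerical and design choices

- Henderson Method III was chosen over REML deliberately: the target is a
  method-of-moments fit, and Method III is the standard quadratic-form
  family for unbalanced designs. REML/ML and moderated (empirical-Bayes)
  statistics are out of scope.
- Per-gene effects inside a set are computed with the same paired
  machinery as single-gene fits, which makes the set effect exactly equal
  to the mean of separately fitted member genes (a tested invariant,
  including invariance to gene order).
- In the stacked model the gene baseline is carried at probe resolution;
  this absorbs probe-level baseline differences that would otherwise
  inflate the residual, and reduces to the gene-level baseline when each
  gene has one probe.
- The GMT dialect tolerates trailing empty fields; results tables are
  written with 17 significant digits so write-then-read round-trips are
  exact; display rounding (two-decimal FCs, whole-number percentages,
  scientific-notation interaction p) is applied only in printed output.
- The pipeline writes one flat results directory per run plus a
  `manifest.json` (config, seed, package version); reruns with the same
  config and seed are byte-identical.

## Problem sizes in the test suite

The simulation-based checks run at sizes chosen to give tight Monte-Carlo
error while staying quick on a laptop: oracle equivalence on 200 random
balanced instances; variance-component recovery and interval coverage on
500 replicates of a 300-person paired design; gene-set recovery with 20
member genes over 60 persons (interval calibration at 120 replicates);
interaction-test size under a 2000-replicate null; and an end-to-end run
on three 20-person contrasts over a 10-pathway universe with five planted
inflammation pathways. In the end-to-end fixture the pathways are disjoint
gene blocks — with overlapping sets the planted "exactly these five are
differential everywhere" ground truth would not be true of the generated
data, since shared genes inherit the effect.

## Known limitations

- Method-of-moments components can be negative before clamping; the clamp
  introduces a small upward bias in tiny-variance regimes (flagged in the
  output).
- The Satterthwaite df comes from a linearization; for severely unbalanced
  tiny designs it is approximate (the balanced case is exact).
- The stacked set model assumes a common residual variance across member
  probes; strongly heteroscedastic sets will see conservative or
  anticonservative pooling that the per-gene table helps diagnose.
- The interaction model's default (no person term) follows the printed
  specification; with person-level strata the blocked variant changes the
  interaction test little but can shift per-stratum intervals.
- Beta values are analyzed untransformed; effects at extreme baseline
  methylation (near 0 or 1) are compressed relative to a logit analysis.
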