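---
title: "Methods: from an in vivo RNAi tumor screen to patient stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from an in vivo RNAi tumor screen to patient stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstum)
```

`crosstum` implements the computational chain of a cross-species
tumor-suppressor screen: an in vivo *Drosophila* RNAi screen against an
oncogenic-Ras background is scored for hits; hits are translated to human
genes through an orthology table; the human gene set is scored for coherent
down-regulation across tumor/normal expression pairs with a resampling
null; top candidates are validated, expanded with protein-interaction
partners and tested for gene-set enrichment; and finally the validated
signature is used to stratify a patient cohort for survival and KRAS-G12
mutation enrichment. Every stage is exercised end to end on synthetic data
whose generators are first-class, tested code.

This vignette explains the models and procedures, the parameters that
matter, what the synthetic data does and does not emulate, and the
numerical decisions taken where the design was genuinely open.

## Screen hit calling

Each RNAi line is crossed once into the oncogene background and the percent
of progeny still larval at day 8 is recorded; delayed pupariation reads out
enhanced tumor growth. The hit statistic is a Z-score against the control
cross,

$$Z = \frac{\bar{x}_{\text{control}} - x_{\text{test}}}{s_{\text{control}}},$$

on the percent-pupariation scale. Because the assay reports percent
*larvae*, `pupariation_zscore()` converts as $100 - \text{\%larvae}$ by
default; a flag accepts pre-converted pupariation percentages. Only the
control distribution's SD enters the formula: a single cross yields one
measurement per line, so no per-line SD exists. A line is a primary hit
when $Z$ strictly exceeds the cutoff (default 1.65) **or** it shows
mouth-hook invasion or ectopic GFP foci. Day-12 counts are recorded for
reporting but not used for calling.

Before calling, lines with insufficient hairpin specificity are removed:
kept lines have S19 score $\ge 0.8$ and at most 6 CAN repeats, both
boundaries inclusive (the exclusion rule drops lines with S19 $< 0.8$
and/or *more than* six repeats).

Secondary validation scores each line's rough-eye enhancement on a 0–3
scale; a gene is validated when the mean over its lines is $\ge 0.75$
(inclusive).

The synthetic screen draws control pupariation from a normal distribution
(mean 98.8, SD 5 — the control behaviour this class of oncogene-only
crosses shows) **clamped** to
$[0, 100]$. Clamping rather than renormalized truncation is deliberate: a
draw above 100 simply means complete pupariation, and censoring at the
bound leaves the lower tail — the tail that produces hits — exactly
Gaussian, so the null hit rate equals the normal tail mass beyond the
cutoff ($\approx 4.9\%$ at 1.65). Planted hits have their mean reduced by
`pupariation_effect` (default 35 points), far beyond the cutoff, so
sensitivity is essentially 1 at the default conditions.

## Ortholog expansion and platform restriction

Fly hits are expanded to human genes by taking the union of each hit's seed
ortholog and (by default) all inparalogs, mirroring one-to-many orthology
tables where all targets of a mapping are considered. Mouse columns are
parsed and carried for table fidelity but unused downstream. Genes without
any probe set on the expression platform are partitioned out — never
silently dropped and never scored zero — before any expression scoring.

## Direction scores and the TSOS

For one probe set in one tumor/normal tissue pair, a Welch two-sample
t-test (unequal variances, two-sided) is run at $\alpha = 0.01$; the probe
scores $+1$ if significantly higher in tumor, $-1$ if significantly higher
in normal, else 0. Reading the sign after a two-sided test is equivalent to
two one-sided tests at $\alpha/2$. A gene's score in a pair is the mean of
its probe directions (so directions $(-1,-1,0)$ over three probe sets give
$-2/3$), which normalizes platform redundancy; it always lies in
$[-1, 1]$.

The tumor-suppressor-oncogene score of a gene list is

$$\mathrm{TSOS}(G) = \frac{1}{|G|}\sum_{g \in G}\sum_{\text{pairs } t} s_{g,t},$$

negative when the list is coherently lower in tumors. Significance comes
from a resampling null: sets of the same size are drawn uniformly without
replacement from the universe of *all screened genes' measurable human
orthologs* (never from all human genes, which would bias the comparison),
and the empirical p is the fraction of null sets with a strictly lower
TSOS (for the lower tail). The strict-fraction convention is the primary
one; a $(k+1)/(N+1)$ variant is available by flag. A p of exactly 0 is
printed as "< 1/N" while stored as 0. An RNA-seq mode applies
$\log(1+x)$ before testing, for RSEM-like inputs.

Candidates are ranked by the per-gene total over pairs (no division by the
pair count), ascending, ties broken lexicographically; the top 100 feed
secondary validation.

### Why the synthetic panel contains background differential expression

Real tumor/normal compendia show differential expression for a large share
of genes; the resampling null exists precisely because random gene sets
have nonzero TSOS. The generator therefore gives every gene an incoherent
per-pair effect (Gaussian, SD `background_effect_sd = 1`, random sign,
shared across the gene's probe sets) in addition to the coherent planted
down-regulation (`planted_effect = 2` SD for `planted_set_size = 50`
genes). The background carries no gene-set structure, so set-level
statistics remain null; but it makes the direction matrix dense, which
matters numerically: with a near-empty matrix the null TSOS collapses onto
a coarse lattice and the strict-fraction empirical p is visibly non-uniform
under the null, an artifact of sparsity rather than of the method. Setting
`background_effect_sd = 0` recovers the fully null panel in which the
per-probe significance rate equals $\alpha$.

## Binding partners, enrichment, and graph condensation

First-degree binding partners are the non-hit genes interacting with at
least two distinct hits (`min_hit_degree = 2`). Gene-set enrichment is the
hypergeometric upper tail $P(X \ge k)$ — one-sided Fisher on the 2x2 table
— with the background universe always passed explicitly (all screened
genes' orthologs, not all genes). Benjamini–Hochberg FDR is reported
alongside, but selection uses the nominal p, $\le 0.05$ inclusive, and
terms with more than 500 genes are discarded as uninformatively generic
(500 itself is kept). An optional rule requires a minimum number of
candidate genes per term.

The annotation graph over the significant terms is produced by
*condensation*: every non-significant term is removed and its children are
reconnected to its parents, iterating until only significant terms remain.
Removal proceeds in reverse topological order (parents before
descendants); the order does not affect the result — reachability between
surviving terms is exactly the transitive-closure restriction of the input,
a property the test suite verifies against an independent closure oracle —
but fixing it makes the procedure deterministic. Multi-edges arising from
diamond-shaped ancestry are deduplicated: the output is a simple graph.

The systems map assembles typed nodes (hit, partner, term) and typed edges
(gene-to-term annotation, protein interaction restricted to map genes);
hits annotated to no surviving term are flagged rather than dropped,
mirroring the headline observation that a fraction of validated hits fall
outside known pathways.

## Patient stratification

Samples lacking either a mutation call or survival information are removed
first; the retained percentage is reported with truncation (132 of 177
prints as 74%). Expression is $\log(1+x)$-transformed and each *sample* is
centered and scaled across genes; methylation beta values, already bounded,
get the per-sample scaling only. By default the matrix is restricted to the
signature genes *before* scaling (a flag selects scale-first).

Stratification runs Lloyd's k-means ($k=2$, Euclidean, up to 300
iterations) `reps = 100` times, each initialized from $k$ distinct samples
drawn uniformly. Cluster labels switch arbitrarily between repetitions, so
votes must be aligned before they are counted: within each repetition the
cluster whose members have the larger mean signature value is "high".
One subtlety forced a design decision: after per-sample z-scoring every
sample's mean is exactly zero, so the alignment average is computed on the
*unscaled* per-sample mean signature value ($\log(1+x)$ expression, or raw
beta). Each sample's final label is its majority label; exact 50/50 ties
are broken toward the nearer average centroid and reported.

Survival is compared by the standard two-group log-rank test (1 df,
aggregated risk sets at ties). KRAS mutation categories "other" and "none"
are aggregated and a one-sided Fisher exact test asks whether G12 carriers
are over-represented in one stratum — the low-expression stratum for
expression, and the *high* stratum for methylation, because promoter
hypermethylation silences the signature: the hypermethylated stratum is the
low-expression, G12-enriched one. The synthetic cohort builds in exactly
this anti-correlation.

### Cohort generator

A latent balanced binary group drives everything: the low group's
signature expression drops by `expr_shift_sd = 1.5` SD on the log scale
*on average* — per-gene effect sizes vary (uniform factors in
$[0.25, 1.75]$), because a perfectly uniform signature-wide shift is a
degenerate special case that per-sample centering removes entirely, which
no real signature resembles. Survival is exponential with the low group's
hazard multiplied by `hazard_ratio_low_vs_high = 3`; censoring is uniform
on $[0, t]$ for a `censoring_rate = 0.3` fraction; G12 carriage has
baseline probability 0.5 with odds multiplied by
`g12_odds_low_vs_high = 4` in the low group; a `missing_rate = 0.1`
fraction of samples independently lacks survival and mutation records to
exercise the cohort filter. Methylation is generated at gene level
(already mean-aggregated), anti-correlated with centered log expression
through a logistic link; a separate probe-level path exercises the
mean-aggregation operation.

## Calibration, and what an exact test can promise

The test suite checks that, under null configurations, the pipeline's
p-values are calibrated over replicate simulations: the TSOS empirical p
and the log-rank p are approximately Uniform(0,1) (two-sided
Kolmogorov–Smirnov). For the G12 Fisher exact p the two-sided check is the
wrong yardstick: an exact test on a discrete table is *conservative* — its
null rejection rate sits below the nominal level and its p-value
distribution below uniform — and this gap does not vanish at the cohort
sizes used here. The suite therefore asserts the property an exact test
can and must satisfy, validity: the p-value CDF never rises above uniform
(one-sided KS) and the attained rejection rate at the 5% level does not
exceed it.

## Problem sizes and reproducibility

Defaults are chosen so a full synthetic study runs in seconds: 600 screen
lines at 5% planted hits; a 600-gene platform with 1–3 probe sets per gene,
10 tissue pairs and 30 samples per arm; 50 planted genes at 2 SD; 10,000
null samplings for a single analysis (calibration suites use 2,000 over 200
replicate panels); cohorts of 200 patients with 100 k-means repetitions.
These sizes are stated here as the package's simulation-study design; all
of them scale through `sim_config()` and the analysis parameters.

Reproducibility discipline: one master seed fans out to fixed,
generator-specific substreams (a hash of the generator name), so adding or
reordering generator calls never perturbs another generator's draws, and
identical configurations reproduce outputs byte for byte. `run_pipeline()`
writes a manifest (config, config hash, seed, package version, per-stage
counts) sufficient to reproduce a run.

## Limitations

The generators emulate the *statistical* structure the analysis assumes,
not the measurement process: there are no microarray normalization
artifacts, batch effects, probe cross-hybridization, copy-number effects,
or realistic mutation spectra, and orthology is simulated as a clean
one-to-one/one-to-many table. Passing tests therefore demonstrate that the
pipeline recovers planted structure and reports calibrated uncertainty
under its own model assumptions — not that those assumptions hold in any
particular real data set. The survival model is exponential
(proportional hazards holds exactly); no Cox modeling or multivariate
adjustment is attempted, matching the scope of the stratification
procedure.

```{r example, eval = FALSE}
# a complete synthetic study
cfg <- sim_config(seed = 1)
run <- run_pipeline(cfg, out_dir = "crosstum_run")
pipeline_report(run$dir)
```
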