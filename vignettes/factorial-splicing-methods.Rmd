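---
title: "Methods: factorial differential splicing with spliceFactorial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial differential splicing with spliceFactorial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceFactorial)
```

## The problem

Splicing-modulator drugs (SF3B1-binding compounds) and spliceosome-gene
mutations such as U2AF1(S34F) both perturb 3' splice-site choice in
haematopoietic cells. When a mutant clone is exposed to such a drug, the two
perturbations act in the same cell, and the practical question is whether
their effects on each splicing event *interact* (synergy/antagonism) or
simply *accumulate*. spliceFactorial implements the full analysis for a 2x2
genotype-by-treatment design — {WT, MT} x {vehicle, drug} with replicated
samples per cell — from event-level junction counts to classified events,
plus the surrounding analyses (direction bias, acceptor sequence context,
gene-level expression), and a generative simulator so every stage is
testable with known ground truth.

## PSI quantification

For an event with inclusion reads $I$, skipping reads $S$ and effective
junction numbers $n_I, n_S$ (SE default 2 and 1; RI 1 and 1),

$$\Psi = \frac{I/n_I}{I/n_I + S/n_S}.$$

A sample with $I = S = 0$ is missing, excluded from condition means and from
z-scoring. Condition-level $\Psi$ is the unweighted mean of per-replicate
values. Row z-scores use the population SD (divisor $n$), the usual heatmap
convention; constant or incomplete rows are dropped and reported. PCA treats
samples as observations of the z-scored event matrix.

## ΔΨ orientation

All reported differences are **baseline minus perturbed**: for a drug
comparison, vehicle minus drug, so a positive ΔΨ means the event was spliced
in more in the baseline — i.e. the perturbation increased skipping (SE) or
decreased retention-removal (RI; retention appears as negative ΔΨ). The
orientation string travels with every result. This sign convention is what
makes the five-comparison decomposition read naturally: the cumulative
effect

$$\Delta\Psi_{cum} = \Psi(\mathrm{WT,Veh}) - \Psi(\mathrm{MT,Drug})$$

decomposes *exactly* (machine precision, it is an algebraic identity on
condition means) along either path:

$$\Delta\Psi_{cum} = \Delta\Psi_{mut|Veh} + \Delta\Psi_{drug|MT}
                   = \Delta\Psi_{drug|WT} + \Delta\Psi_{mut|Drug}.$$

The canonical worked example — genotype effect 0.205 in vehicle, drug effect
0.188 in WT and 0.204 in MT, cumulative 0.409 — is reproduced exactly by the
acceptance tests from constructed counts.

## The differential splicing test

Replicate inclusion counts are modelled beta-binomially:
$I_j \sim \mathrm{BB}(n_j, \mu, \rho)$ with mean $\mu$ and intra-class
correlation $\rho$ (variance $n\mu(1-\mu)(1+(n-1)\rho)$; $\rho = 0$ is
binomial). The two-group test compares the model with separate group means
against a common mean by likelihood ratio, referred to $\chi^2_1$.

**How $\rho$ is handled matters at $n = 5$ per group.** Profiling $\rho$ per
event by ML is noticeably anticonservative here: in our 2,000-event null
calibration (coverage $\approx 60$, $\rho = 0.05$, 5 vs 5) the per-event
profile LRT rejects at 9% for nominal 5%, and its p values are visibly
non-uniform (KS $\approx$ 0.08). The package therefore pools: one $\rho$ is
estimated across all events of a table by maximizing the **Cox-Reid
adjusted** profile likelihood of the cell-means model (the adjustment,
$-\tfrac12\log I(\hat\mu_g)$ per fitted mean, removes most of the downward
bias of plain profile ML; it is the same device edgeR and DESeq2 use for NB
dispersions), then held fixed in every event's LRT. With the pooled
estimate, the same null gives empirical type-I 0.055 (99% binomial band
[0.037, 0.063]) and KS 0.013. A deterministic, evenly spaced subset of up to
300 events is used for the pooled estimate. Per-event profiling remains
available (`rho = NULL` in `betabinomial_lrt()`), documented as
anticonservative; this pooling is the package's one deliberate departure
from a strictly per-event dispersion, adopted because the per-event variant
fails its own calibration target.

Degenerate input (fewer than two informative replicates in a group) yields a
missing p value, excluded before FDR adjustment. The dispersion floor is
1e-6 and group means are clamped away from 0/1 by 1e-9 for numerical
stability; model fits are nested 1-D optimizations (golden-section), which
are reliable where a joint simplex search was not.

## Multiple testing and calling

`bh_adjust()` is a hand-rolled Benjamini-Hochberg step-up (tested against an
$O(n^2)$ enumeration and `p.adjust`). The published workflow filters events
(expressed junctions, mean total count >= `min_mean_total`, default 10 — a
stand-in, the source analyses do not state their threshold) and then
**re-adjusts on exactly the surviving subset** (`filter_then_readjust()`);
discarded events carry no FDR. Calls use strict inequalities with presets:
human CD34+ (FDR < 0.05, |ΔΨ| > 0.10) and mouse bone-marrow (FDR < 0.10,
|ΔΨ| > 0.01). Each of the five comparisons is adjusted separately within
itself, not jointly.

## Interaction vs cumulative effect — two scales

Interaction is tested on the **logit-Ψ scale**: beta-binomial regression
with logit link, additive model (mut + drug) vs the model with a mut:drug
term, LRT with 1 df at the pooled $\rho$. The interaction model is the
saturated cell-means model, so its likelihood splits per cell, and the
interaction coefficient is the logit-scale difference of differences of the
fitted cell means; its sign separates synergy from antagonism. The
*cumulative* effect, by contrast, lives on the **Ψ-difference scale**. These
scales deliberately coexist: two perturbations can be perfectly additive on
the logit scale (no interaction) and still produce a cumulative ΔΨ larger
than either single effect — which is exactly the phenomenon the
classification labels capture (`drug_concordant`, `cumulative_exacerbated`,
`trajectory_eligible` when all five comparisons pass).

Concordance of drug effects across genotypes is ordinary least squares of
ΔΨ(drug|MT) on ΔΨ(drug|WT) over events significant in both comparisons,
reporting slope, $R^2$ and the F-test p. The fit includes an intercept by
default — whether the published regression was forced through the origin is
unstated, so both are offered (`through_origin`).

## Direction bias

Significant calls are tallied by event type and canonical direction
(skipping for SE, retention for RI) and tested against a fair coin with a
one-sided exact binomial upper tail, computed by log-space summation of PMF
terms (no normal approximation; tested against brute-force summation to
relative error 1e-10 up to n = 1,000). The one-sided alternative toward
skipping/retention is fixed a priori; a two-sided option exists but is not
the default.

## Acceptor sequence context

Context windows cover 20 intronic + 3 exonic bases around the 3' acceptor
(the window length is not stated in the source; 20 nt covers the -3 position
and the polypyrimidine tract). Position 0 is the exon's first base, intronic
positions are negative, the acceptor AG occupies -2/-1, and U2AF1 contacts
-3. Minus-strand events are reverse-complemented so the planted -3 base is
recovered identically on both strands (tested). Position frequency matrices
report per-position base frequencies and information content $2 - H$ bits,
no small-sample correction. Enrichment at a position is a two-sided Fisher
exact test on the (base vs not) x (dysregulated vs control) table; the
reported odds ratio is the sample cross-product ratio with a Haldane +0.5
correction when a cell is zero (not the conditional-MLE OR). Control events
are "unperturbed" (FDR > 50% and |ΔΨ| < 0.1%); the alternative
changed-but-nonsignificant reading of the mouse methods text (apparently a
typo) is selectable but not default.

## Gene expression

Size factors are DESeq-style median-of-ratios over genes with no zero
counts. Each gene's two-group contrast is an NB GLM with log link and
size-factor offsets; the dispersion is estimated per gene by Cox-Reid
adjusted profile ML under the full model (floor 1e-8, **no**
empirical-Bayes shrinkage across genes — a documented simplification,
adequate at simulated depths), then held fixed while full and reduced mean
models are compared by LRT (1 df). Calibration and log2FC recovery
(median within ±0.25 of a planted 2 at mean 100, dispersion 0.05) are
exercised by the acceptance tests. Heatmap/PCA input is
$\log_2(\text{normalized count}+1)$, a plain stand-in for a regularized log.

## The simulator: a stated world

`simulation_config()` defaults describe the emulated experiment, not tuning
knobs: 4,000 events (80% SE / 20% RI), 1,000 genes, **5 replicates per
condition**, negative-binomial event coverage with mean 60 (per-event
coverage is not published; these are documented stand-ins), beta-binomial
replicate noise $\rho = 0.05$, logit-additive mutation and drug effects of
magnitude 1.5 (jittered 50-150%) on 15% of events each, an interacting
minority (1%, forced both-sensitive so the additive null is the complement),
a 0.6 probability that a drug effect points in the canonical direction (the
published skew is 388/657 ≈ 59% toward skipping), gene-level log2 fold
changes of ±2 on 10% of genes, and a -3 T probability of 0.8 for
mutation-sensitive events vs 0.25 background. Effects are additive on the
*logit* scale so Ψ stays in [0,1] and "no interaction" is a well-defined
null. Counts are drawn at the read level with probability
$n_I\Psi/(n_I\Psi + n_S(1-\Psi))$ so that PSI normalization is genuinely
exercised. One RNG stream, seeded once, with a fixed draw order makes the
whole dataset byte-reproducible.

What the simulator does *not* emulate: read-level alignment artifacts,
isoform structure beyond two-way inclusion/skipping, cell-type mixtures,
correlated events within genes, and library-preparation covariates. A green
test therefore establishes the statistical machinery on its own model
assumptions, not agreement with the deposited sequencing data — the
published dataset-level counts are explicitly out of desk-scale reach.

## Numerical choices and degenerate inputs

- Dispersion floor 1e-6 (beta-binomial) and 1e-8 (NB); $\rho$ searched on a
  log grid to 0.99; boundary $\rho = 0$ (binomial) always considered.
- LRT statistics are clamped at 0; p values at `.Machine$double.xmin`.
- Strict inequalities everywhere a threshold is applied; an event exactly at
  a threshold is not called (tested).
- Empty survivor sets after filtering warn and return empty results; a
  missing factorial cell is an error for testing, a report-only violation in
  `validate_inputs()`.
- Ties in BH are handled by the step-up minimum; the rank-m multiplier is
  exactly 1 so adjusted values never round below their p value.

## Known limitations

- No empirical-Bayes moment sharing for NB dispersions; power at very low
  counts is below what DESeq2/edgeR achieve.
- The interaction test operates on event-level inclusion/skipping counts,
  not junction-level bins; it is a declared substitute for a DEXSeq-style
  analysis, not an equivalence.
- No paired-sample design, no de novo event discovery, no pathway
  enrichment, no figure rendering (tabular figure inputs are written
  instead).
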