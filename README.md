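# spliceFactorial

Factorial differential splicing analysis for drug-by-genotype designs.

When a splicing-modulator drug (an SF3B1-binding compound such as a
sudemycin) is given to cells carrying a spliceosome mutation such as
U2AF1(S34F), both perturbations act on 3' splice-site choice in the same
cell. This package asks, event by event, whether the two effects interact
or simply accumulate. It is aimed at transcriptomics analysts working with
replicated 2x2 designs — {WT, MT} x {vehicle, drug} — who have event-level
inclusion/skipping junction counts (rMATS-style skipped-exon and
retained-intron events) and want a self-contained, tested implementation of
the whole downstream analysis.

## What it computes

**PSI.** Per cent spliced in with effective-junction normalization,
`Psi = (I/nI) / (I/nI + S/nS)`, missing when a sample has no informative
reads; condition means, row z-scores (population SD), sample PCA.

**Differential splicing.** A replicate-aware beta-binomial likelihood-ratio
test (`I_j ~ BB(n_j, mu, rho)`, group means compared with 1-df chi-square).
The intra-class correlation `rho` is pooled across events by Cox-Reid
adjusted profile likelihood and held fixed per event, which calibrates the
test at 5 replicates per group (empirical type-I 0.055 at nominal 0.05 in a
2,000-event null; see the methods vignette). Benjamini-Hochberg FDR is
hand-rolled, with the published filter-then-readjust behaviour; calls use
strict thresholds with presets `"human-cd34"` (FDR<5%, |dPSI|>10%) and
`"mouse-bm"` (FDR<10%, |dPSI|>1%).

**The five-comparison decomposition.** All delta PSI values are reported
baseline-minus-perturbed (skipping-positive), so the cumulative effect of
mutation plus drug decomposes exactly:

    dPSI_cum = Psi(WT,Veh) - Psi(MT,Drug)
             = dPSI(mut|Veh) + dPSI(drug|MT)
             = dPSI(drug|WT) + dPSI(mut|Drug)

Events are classified drug-concordant / discordant, cumulative-exacerbated,
trajectory-eligible (significant in all five comparisons), and
interaction-significant — the last from a beta-binomial GLM comparing
`mut + drug` against `mut + drug + mut:drug` on the logit scale. Interaction
(logit scale) and accumulation (PSI scale) deliberately coexist: effects can
be perfectly additive yet still cumulative.

**Also:** one-sided exact binomial direction-bias tests (log-space tail
summation), 3' splice-acceptor context analysis (position frequency
matrices, information content, -3 T enrichment by Fisher's exact test),
gene-level NB-GLM differential expression with median-of-ratios size
factors, OLS concordance regression of drug effects across genotypes, and a
ground-truth factorial simulator that makes every stage testable offline.

## Worked example

```r
library(spliceFactorial)
cfg <- pipeline_config(output_dir = "demo_out", seed = 42,
                       simulation = list(n_events = 1000, n_genes = 200))
res <- run_pipeline(cfg)
```

which prints (seed 42):

```
simulate: 1000 events, 200 genes, 20 samples
quantify: 1000 events pass the coverage filter
diff: five comparisons over 1000 events
factorial: 121 concordant, 12 trajectory-eligible, 0 interaction-significant
bias: SE 67/122 toward skipping (p=0.16)
context: -3 T enrichment OR=10.73 p=0.0175 (129 vs 6 SE events)
expression: 17 / 17 DE calls (drug in WT / MT)
```

Reading this: of 1,000 simulated events, 121 had a significant drug effect
of the same sign in both genotypes (the simulator plants genotype-independent
drug effects on ~15% of events, so concordance dominates and interaction
calls stay near zero — 0 here at the 1% planted interaction rate); 12 events
were significant in all five comparisons and get trajectory rows relative to
the (WT,Veh) baseline, e.g.

```
        event_id WT.Veh    WT.Drug     MT.Veh    MT.Drug     group
EV00134  EV00134      0  0.3037876  0.2334778  0.4340820  skipping
```

— drug alone shifts this event by +0.30, mutation alone by +0.23, and the
mutant-plus-drug cell sits at +0.43, a cumulative effect larger than either
alone. The -3 T enrichment (odds ratio 10.7) recovers the planted T/C
dichotomy at the -3 intronic acceptor position of mutation-sensitive exons.
The drug-effect concordance regression across genotypes for this run gives
slope 0.949, R² 0.878 (`res$concordance_splicing`). All outputs are written
as deterministic TSV (plus a FASTA of acceptor contexts and a JSON manifest
with MD5 sums) under `demo_out/`.

A command-line driver with one subcommand per stage lives at
`inst/cli/splicefactorial.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","splicefactorial.R",
                        package="spliceFactorial"))')" \
    all --out demo_out --seed 42 --n-events 1000 --n-genes 200
```

## Layout

- `R/` — simulator, PSI/event model, beta-binomial tests, factorial
  decomposition, direction bias, sequence context, expression, pipeline.
- `tests/testthat/` — unit, property and acceptance tests (fixtures are
  generated in code; no binary data).
- `vignettes/factorial-splicing-methods.Rmd` — the model, its assumptions,
  numerical choices, what the simulator does and does not emulate.
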