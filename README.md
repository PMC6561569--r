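# wgdtv

Dating and characterising gene-duplication events from transcriptome- or
genome-derived gene families, for researchers studying whole-genome
duplications (WGD), tandem segmental duplications and delayed
rediploidization in fish and other eukaryote lineages.

A retained paralogue pair carries three signals about its origin, and
`wgdtv` computes and combines all three:

* **4dTv divergence.** For two aligned coding sequences, the raw distance
  is d = (transversions at third positions of fourfold-degenerate codons)
  / (number of fourfold-degenerate codon sites), corrected for saturation
  as −ln(1 − 2d)/2. Bursts of duplication appear as peaks in the
  distribution of corrected 4dTv over pairs; `wgdtv` dates them by
  fitting a lognormal mixture (Gaussian EM on ln-values, component count
  by BIC) and reporting the local maxima of the fitted density.
* **Branch assignment.** Gene trees are reconciled against the species
  tree by parsimony LCA mapping; each internal node maps to
  M(v) = LCA of its children's images and is a duplication iff
  M(v) = M(child) for some child. Duplications are assigned to the
  species-tree branch above M(v) and counted per branch.
* **Synteny.** Each paralogue pair is classified per genome from gene
  order: `CLOSE` (within 50 neighbouring genes — the tandem signature),
  `SOME_SYNTENY` (neighbourhoods share ≥ 2 other paralogous families —
  the WGD-block signature), `NO_SYNTENY`, or `NO_INFO`; votes across
  genomes combine to a consensus with disagreements flagged
  `CONFLICTING`.

Around this core sit the standard preparation steps (DUST low-complexity,
length and TPM transcript filters; transitive isoform clustering;
protein-length/gap-fraction alignment filters; protein-guided codon
back-translation), Fisher-exact/Benjamini–Hochberg term enrichment, and a
ground-truthed simulator that plants WGDs (optionally with delayed
divergence onset), tandem duplications, sequence divergence with a
closed-form expected 4dTv, and genome gene orders with planted synteny —
so every stage is testable end to end without any external data.

## Worked example

Simulate a two-burst scenario — an old WGD on the basal branch of a
three-species clade (expected corrected 4dTv 0.75 between copies) and a
younger WGD on a nested branch (expected 0.40) — then run every stage:

```r
library(wgdtv)
dir <- tempfile()
cfg <- pipeline_config(rng_seed = 1)
run_stage("simulate", dir, cfg,
          sim_config = two_burst_scenario(seed = 1, n_families = 60,
                                          tandem_rate = 0.03))
run_stage("all", dir, cfg)
read.table(file.path(dir, "branch_summary.tsv"), header = TRUE, sep = "\t")
```

```
  branch n_duplications median_corrected_4dtv n_informative pct_close pct_some_synteny
1      A              5               0.11157             5    100.00              0.0
2      B              4               0.05163             4    100.00              0.0
3      C              4               0.15477             4    100.00              0.0
4      D              1               0.00604             1    100.00              0.0
5     N2             51               0.73920           416      2.88             97.1
6     N3             87               0.40148           205      7.32             92.7
7     N1              0                    NA            NA        NA               NA
```

Reading the table: the old burst was planted on branch N2 (the stem of
the A,B,C clade) and the young burst on N3 (the stem of A,B). Their
duplications are recovered on those branches with median corrected 4dTv
0.739 and 0.401 — at the planted expectations — and their pairs are
overwhelmingly `SOME_SYNTENY` (mirrored duplicated blocks), while the
few duplications on terminal branches are the planted tandem copies,
100% `CLOSE`. The fitted mixture makes the two bursts explicit:

```r
read.table(file.path(dir, "density_maxima.tsv"), header = TRUE)
```

```
  maximum_4dtv
1        0.375
2        0.735
```

Two local density maxima, one per burst. (The old peak is wider and its
maximum scatters more between seeds because the saturation correction
amplifies sampling noise as d approaches 0.5; see the vignette.)

Individual operations are exported too:

```r
four_dtv(paste(rep("GGA", 10), collapse = ""),
         paste(c(rep("GGC", 2), rep("GGA", 8)), collapse = ""))
#   n_4d_sites n_transversions raw_4dtv corrected_4dtv status
# 1         10               2      0.2      0.2554128     OK
```

## Layout

```
R/                      implementation (config/IO, alignment prep, 4dTv,
                        reconciliation, synteny, mixture, enrichment,
                        simulator, pipeline stages)
tests/testthat/         oracle-based test suite
scripts/acceptance.R    end-to-end reproduction script
vignettes/              methods vignette (models, parameters, design)
inst/scripts/wgdtv.R    thin command-line wrapper over run_stage()
```
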