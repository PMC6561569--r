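---
title: "Dating gene-duplication bursts from 4dTv, reconciliation and synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating gene-duplication bursts from 4dTv, reconciliation and synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtv)
```

## The problem

When a genome duplicates (a whole-genome duplication, WGD), every retained
paralogue pair starts a molecular clock at the same moment, and the pairs
stay embedded in large duplicated blocks of conserved gene content. A
tandem segmental duplication (SD) instead creates two adjacent copies at an
arbitrary time, with no block signature. Distinguishing these histories —
and placing each duplication on a branch of the species tree — requires
three measurements to be combined:

1. **Neutral divergence.** The 4dTv distance between two coding sequences
   is the proportion of transversions at the third position of
   fourfold-degenerate codons. Because every substitution at those sites is
   synonymous, 4dTv grows with time since divergence rather than with
   selective regime. As the distance approaches the equilibrium
   transversion share of 1/2 it saturates, so the raw proportion *d* is
   transformed to $-\ln(1 - 2d)/2$, which is linear in time under simple
   substitution models.
2. **Reconciliation.** Mapping a gene tree onto the species tree by the
   parsimony LCA rule labels each internal node as a speciation or a
   duplication and assigns each duplication to a species-tree branch.
3. **Synteny.** Paralogues within 50 neighbouring genes of one another on
   a scaffold look like tandem SDs ("close"); paralogues far apart but
   whose neighbourhoods share 2 or more other paralogous gene families
   look like WGD remnants ("some synteny").

A burst of duplication (a WGD, or rediploidization of a large region)
appears as a peak in the distribution of corrected 4dTv over paralogue
pairs; fitting a lognormal mixture and reading off the local density
maxima dates the bursts on the 4dTv scale. The package deliberately stops
there: converting 4dTv modes into absolute ages requires external
calibration and is out of scope.

## Pipeline stages and their parameters

All thresholds live in one `pipeline_config()` object that is serialized
with every run:

* **Transcript filters** — minimum length 500 bp (inclusive), minimum
  expression 1 TPM (inclusive), and a DUST low-complexity score of at most
  7 computed over 64-base windows. The DUST score of a window holding $k$
  overlapping triplets with per-type counts $c_t$ is
  $\sum_t c_t(c_t-1)/2 \,/\, (k-1)$; the sequence score is the maximum over
  windows advanced by half a window, with the final window flushed to the
  sequence end. A 64-base homopolymer scores 31; a window of all-distinct
  triplets scores 0. The exact window schedule is a choice of this
  implementation; any schedule covering the sequence gives the same
  accept/reject behaviour for sequences much longer than one window.
* **Isoform clustering** — transcripts sharing at least 100 aligned bases
  at 97% identity or better are isoforms of one gene (transitive closure);
  the representative is the most expressed transcript, with ties broken by
  the lexicographically smallest id so that reruns are reproducible.
* **Alignment filters** — rows longer than 1,500 residues, rows whose CDS
  has DUST score above 7, and rows with more than 40% gaps are removed, in
  that order of precedence, in a single pass over the input alignment (an
  alternative would be to re-evaluate gap fractions after each removal; on
  a single pass the rule is order-independent and idempotent, which we
  test). The gap rule and length rule are strict inequalities, the length
  and TPM minima inclusive, following the usual reading of "minimum of
  500" versus "more than 40%".
* **Back-translation** — the codon alignment is built directly from the
  protein alignment template: gap columns become `---`, residue columns
  take the next CDS codon. The CDS must translate exactly to the ungapped
  protein row (one trailing stop codon is tolerated); disagreements are
  errors rather than warnings because silently shifted frames would
  corrupt every downstream distance.
* **4dTv** — a site qualifies only if both codons are gap-free,
  unambiguous, belong to one of the eight fourfold codon families
  (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN) *and* have identical first two
  positions in the two sequences. Requiring identical prefixes guarantees
  the third-position change is synonymous; allowing different prefixes
  within a family would admit a handful of non-synonymous histories. This
  is the main comparability caveat against other 4dTv scripts, which do
  not always state their site rule. Pairs with fewer than `min_4d_sites`
  (default 10) qualifying sites are UNDEFINED; pairs with $d \ge 0.5$ are
  SATURATED. Both are excluded from density fitting but kept in the
  output tables.
* **Reconciliation** — inputs are rooted binary gene trees; polytomies
  are rejected with an error rather than resolved arbitrarily, because an
  arbitrary resolution would manufacture duplications. Branches are named
  by their child node (leaves by species id, internal nodes `N1`, `N2`,
  ... in the tree's internal node order, `N1` being the root). Each
  duplication emits all cross pairs between its two child clades; a
  representative-pair mode (the cross pair with most qualifying fourfold
  sites) is available when one pair per event is preferred.
* **Synteny** — the classifier applies, in order: NO_INFO (either gene
  unlocatable, or fewer than 2 annotated gene families among either
  gene's neighbours), CLOSE (same scaffold, at most 50 gene positions
  apart), SOME_SYNTENY (at least 2 shared neighbour families), else
  NO_SYNTENY. Testing CLOSE before synteny means a tandem pair embedded
  in a duplicated block reports CLOSE, which is the intended tandem-SD
  signature. Shared families are counted with set semantics, pooling both
  sides of each neighbourhood; the window spans all genes (annotated or
  not) but only annotated ones count as evidence. Across genomes,
  NO_INFO votes are dropped, unanimity wins, and disagreement is reported
  as CONFLICTING rather than resolved by majority — a deliberate choice,
  since a majority rule would hide real biology (lineage-specific
  rearrangements) behind a clean label. Per-branch percentages are
  computed over informative pairs only.
* **Mixture dating** — the "lognormal mixture" is a Gaussian mixture with
  unequal variances fitted by EM on $\ln$(corrected 4dTv); the component
  count is selected among `mixture_k_candidates` (default 1–4) by minimum
  BIC ($-2\log L + p\ln n$). Component modes on the original scale are
  $e^{\mu - \sigma^2}$, and the reported burst dates are the local maxima
  of the full mixture density on a 0.01–1.5 grid with step 0.005
  (plateaus contribute their midpoint). A log-space variance floor of
  $10^{-6}$ rejects degenerate spikes. Histograms use half-open bins of
  width 0.05 over [0.2, 1.4) by default, with explicit under/overflow
  counts.
* **Enrichment** — classic one-term-at-a-time Fisher exact tests
  (one-sided, enrichment) with Benjamini–Hochberg correction. Graph-aware
  decorrelation of GO terms (as in topGO's weight algorithm) requires the
  GO DAG and is intentionally not included; with correlated terms the
  classic test is more liberal, which readers of the output tables should
  keep in mind.

## The simulator: what it emulates and what it does not

`simulation_config()` plants events on a time-calibrated species tree.
Each gene family descends from a single root locus. A WGD sits at the
midpoint of its named branch and is retained per family with probability
`retention`. Its copies begin diverging at the WGD time plus a
`divergence_onset` offset: this models **delayed rediploidization**, where
duplicated regions keep recombining under tetrasomic inheritance and the
paralogues' sequences only start to diverge once the region
rediploidizes. When the onset postdates a later speciation, the
bifurcation replays independently in each descendant lineage, so LCA
reconciliation — correctly — assigns those duplications to daughter
branches. This reproduces, with known truth, the branch-assignment
"leakage" that complicates the interpretation of reconciliation-based
duplication counts on real data.

Sequence divergence is simulated only where 4dTv reads it: third
positions of fourfold codons evolve under Jukes–Cantor with rate $\mu$,
first two positions held fixed. This gives a closed-form oracle: between
two leaves separated by total path time $T$, the expected raw 4dTv is
$\tfrac12(1-e^{-4\mu T/3})$ and the expected corrected 4dTv is $2\mu T/3$,
which the test suite checks to within three standard errors.

Genomes are built by laying families out in a fixed ancestral order; each
locus copy occupies its own mirrored scaffold (so WGD pairs sit on
different scaffolds surrounded by shared families) and tandem copies are
inserted adjacent to their source. Copy labels are event-deterministic
(one bit per WGD), so the same scaffold collects the same event's copies
in every family. Degradation is modelled as independent gene loss
(`loss_frac`) followed by local position swaps within three positions
(`shuffle_frac`); truth labels account for it, downgrading pairs to
NO_INFO when a member is lost or when fewer than two annotated neighbour
families survive around either member. A tandem pair whose members were
later separated onto different scaffolds by a WGD is expected
SOME_SYNTENY, not CLOSE.

The simulator deliberately omits indels, codon-usage bias, rate
variation across lineages, chromosome-scale rearrangements and
coalescent effects. Passing tests on these simulations therefore show
that the *inference machinery* is correct under its own assumptions —
they do not show that real transcriptome data satisfy those assumptions,
and none of the simulator's parameters should be read as estimates for
any real lineage.

## The two-burst demonstration scenario

`two_burst_scenario()` uses a four-taxon tree of depth 3 with an old WGD
on the basal branch of the (A,B,C) clade and a younger WGD on the (A,B)
branch, with $\mu = 0.225$ chosen so the expected corrected 4dTv is 0.75
between old-event copies and 0.40 between young-event copies — a bimodal
age distribution qualitatively similar to teleost data, where an old
fish-specific WGD peak coexists with younger lineage-specific bursts.
Defaults are 120 families, 500 fourfold sites per gene and retention 0.8
per event, giving roughly 800 young-burst and 2,500 old-burst usable
pairs — enough for stable mixture maxima while the whole pipeline runs in
well under a minute. The old-burst peak is intrinsically wide: at raw
distance 0.42 of the saturation bound 0.5, the correction multiplies
sampling noise about sixfold, so its density maximum scatters a few
hundredths around 0.75 between seeds while the young peak sits tightly at
0.40.

```{r, eval = FALSE}
dir <- tempfile()
cfg <- pipeline_config(rng_seed = 1)
run_stage("simulate", dir, cfg,
          sim_config = two_burst_scenario(seed = 1, n_families = 120))
run_stage("all", dir, cfg)
read.table(file.path(dir, "density_maxima.tsv"), header = TRUE)
```

## Numerical and degenerate-input choices

* Distances with zero qualifying sites are UNDEFINED, never 0 — an
  absent measurement is not agreement.
* `fit_lognormal_mixture()` refuses non-positive values, fewer than
  $10\,k_{\max}$ observations, and (near-)constant inputs, each with an
  error naming the offending condition.
* Natural logarithms throughout; BIC selection is deterministic given
  the data and seed, which the suite checks bit-for-bit.
* Isoform clustering and reconciliation results are invariant to input
  order; pair tables are normalised (`gene_a < gene_b`, sorted) so that
  file-level diffs between runs are meaningful.
* Gene positions are 0-based order ordinals per scaffold, not base-pair
  coordinates: synteny windows count *genes*, so ordinals are the
  faithful representation, and position tables with gaps in the ordinals
  are rejected at read time.

## Problem sizes used by the test suite

The suite validates against independent oracles at sizes chosen to keep
a full run around two minutes: 1,000 random codon-row pairs against a
naive per-column recount; 500 random gene/species tree pairs (up to 10
leaves) against a leaf-set LCA oracle; 200 Jukes–Cantor pairs at 500
sites for the closed form; 150-family degraded-genome runs (30% loss,
10% shuffling) for synteny recovery with at least 500 surviving
block-duplicate pairs; 50 replicates of two-component mixture recovery
at $n = 2000$; 1,000 random enrichment tables against the explicit
hypergeometric tail plus a 100-replicate null FDR calibration; and two
independent end-to-end pipeline runs compared checksum-for-checksum.

## Known limitations

* The 4dTv site rule (identical prefixes) makes distances slightly
  conservative relative to scripts that only require both codons to be
  fourfold; comparisons across tools should verify the site rule first.
* LCA reconciliation takes the input trees as true. Gene-tree estimation
  error translates directly into spurious duplications; the package does
  not model reconciliation uncertainty, losses or transfers.
* The enrichment module tests terms independently; correlated
  annotation hierarchies inflate the number of nominally enriched terms.
* Mixture maxima are reported on the 4dTv scale only; no absolute-time
  calibration is attempted.
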