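---
title: "Inferring flagellar motility from gene content and metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring flagellar motility from gene content and metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flagmot` infers the capacity for bacterial flagellar motility at the
genome scale (a boosted-tree classifier on gene presence/absence) and at
the community scale (a calibrated index computed from shotgun metagenomic
reads). This vignette explains the models, their assumptions, the
parameters that matter, and the design decisions taken where the
methodology left room.

## The genome tier

### Panel selection

Building a flagellum requires a well-defined gene repertoire, but many
nonmotile taxa retain parts of it, so single genes are poor predictors.
The predictor panel is selected from a labelled binary gene-content matrix
by two prevalence criteria: a gene family is retained when it is present
in more than 80% of genomes with experimentally demonstrated motility
*and* not present in more than 50% of nonmotile genomes
(`panel_criteria()`, defaults 0.80/0.50).

Boundary semantics are strict on the motile side and inclusive on the
nonmotile side: a gene at exactly 80% motile prevalence is dropped, one at
exactly 50% nonmotile prevalence is retained. The prevalence rules are
phrased as strict inequalities and the boundaries themselves are
arbitrary, so both bounds are configurable (`strict = FALSE` relaxes the
motile bound to `>=`). Selection can be restricted to a candidate list —
in practice the ~35 flagellar-assembly families from which the 21-gene
panel is drawn — via the `candidates` argument; the package does not
decide that biological list, it takes it as input.

Copy numbers are collapsed to presence/absence first (`binarize()`):
flagellar genes are usually single-copy, and copy-number noise across
annotation pipelines would otherwise leak into the features.

### The classifier

`train_motility_model()` fits gradient-boosted regression trees with a
binary logistic objective (xgboost), so the prediction is a probability in
(0, 1). Choices made where nothing was prescribed:

* **Decision threshold 0.5**, with a tie at exactly 0.5 labelled
  nonmotile — the conservative direction given that nonmotile genomes
  outnumber motile ones roughly 2:1 in the reference phenotype sets.
* **Stratified 70:30 split** (`split_train_test()`): the total train size
  is `floor(0.7 n)` allocated to classes by largest remainder, keeping each
  class's train fraction within one genome of the global one. Plain random
  splitting is available (`stratified = FALSE`) but class imbalance makes
  stratification the safer default.
* **k = 5 cross-validation folds** to pick the boosting round count
  (`cross_validate()` minimizes mean held-out logistic loss, early
  stopping after 25 stagnant rounds).
* **Hyperparameter search** (`tune_hyperparameters()`): a Latin-hypercube
  design anchored at the package defaults seeds a Gaussian-process
  surrogate (squared-exponential kernel, fixed length-scale 0.3 on the
  unit cube, small nugget) whose expected improvement proposes points;
  below a 10-evaluation budget the search is purely random. Anchoring at
  the defaults guarantees the tuned point is never worse than the defaults
  on the same folds. Search box: `eta` 0.01–0.3, `max_depth` 2–8,
  `min_child_weight` 1–10, `subsample` and `colsample_bytree` 0.5–1,
  `gamma` 0–5; default budget 30 evaluations.
* **Importance = gain** (normalized total loss reduction per feature),
  summing to 1 over used features.

Feature vectors missing panel genes are scored with those genes set to
absent, with a warning — silent zero-filling hides upstream annotation
problems, but refusing to predict would make partially annotated genomes
unusable.

## The community tier

### Index and standard curve

Reads are assigned to protein variants of two gene sets held in a
`protein_registry`: the flagellar panel (21 families) and 120 single-copy
marker families (the taxonomic basis set of GTDB). Hits are filtered with
the removal rules *bit score < 50*, *identity < 60%*, *e-value > 0.001*,
and reads not *above* 100 bp are dropped; boundary-equal hits are kept
because the rules are phrased as strict removals. Per family,

```
RPK = hit count / (3 * median variant amino-acid length / 1000)
```

and the flagellar motility index is the ratio of the median RPK over the
21 flagellar families to the median RPK over the 120 marker families.
Numerical choices:

* **Zero-count families enter the medians.** The two medians must be
  taken over fixed denominators (21 and 120) for the index scale — and
  hence the standard curve — to be transferable between samples.
* **One best hit per read**, chosen by bit score, then e-value, then
  lexicographic protein id. Counting every hit would multiply-count reads
  matching several variants of the same family.
* **Gene length = 3 × median variant amino-acid length.** Families carry
  many variants (7–633 in the reference database); the median length is
  robust to truncated variants.
* **A zero marker median is an error**, not a zero index: a metagenome
  with no marker signal cannot be normalized and must not silently return
  an estimate.
* **Percent estimates are not clamped by default.** The published line
  `% = 3650 × index − 0.321` is slightly negative at index 0 by
  construction; truncation to [0, 100] is available (`clamp = TRUE`) and
  logged, but distorting the estimator silently would bias averages of
  many samples.

`fit_calibration()` refits the curve by ordinary least squares of true
percent on index and reports the Pearson r of the points; with exactly two
points the fit is an interpolation and r is reported as 1 with a warning.

### What the simulator emulates — and what it does not

`generate_genome()` builds genomes that carry each marker family exactly
once and the flagellar families iff the genome is motile (optional dropout
and contamination rates relax this). Genes are uniform random sense-codon
sequences, 300–1800 nt (drawn from one shared length distribution for
markers and flagellar families so the two RPK medians are comparable),
placed without overlap on random strands with ~5% intergenic sequence.
`simulate_reads()` draws per-genome read counts as
`floor(abundance × total mixture length × coverage / read length)` — i.e.
total read bases equal the fold coverage times the mixture's genome bases,
the fold-coverage reading of "50% coverage" — with uniform start
positions, strand flips at probability 0.5, optional substitution errors,
and constant phred+33 `I` qualities. `build_gradient()` spans flagellated
proportions evenly over [0, 1] (default 14 points, endpoints included,
endpoint mixtures class-pure).

The naive annotator (`annotate_reads_naive()`) translates each read in six
frames, anchors candidate proteins by exact 7-aa seeds, and scores the
full ungapped diagonal overlap with surrogate statistics
(`bit = 2 × matched aa`, `e = 10^(−matched/2)`, identity =
matches/aligned). These surrogates are *not* BLOSUM-based: they are
calibrated only so that genuine matches of error-free reads clear the
standard filters and random seed collisions do not. Real metagenomes must
be annotated with a genuine translated search and imported via
`read_hits_tabular()`.

Synthetic genomes are ~150 kb rather than ~4 Mb, so the synthetic index
scale (slope ~100) differs from the published slope 3650, which was fitted
on real genome mixtures where the 141 reference families are a far smaller
genome fraction. What the simulation *does* establish is the property the
method rests on: the index is linear in the true flagellated proportion
(Pearson r ≥ 0.99 across a 14-point gradient) and a curve fitted on a
gradient recovers that gradient's truth to within ~3 percentage points.
Passing these checks says nothing about sequencing error profiles,
uneven coverage, eukaryotic reads, or taxa whose flagellar genes diverge
from the reference variants — limitations that apply to real data.

## Trait ecology

`estimate_D()` implements the D statistic for binary traits: tip values
are propagated to internal nodes by averaging daughters, the observed
statistic is the sum of absolute sister differences, and it is scaled
between the means of two nulls — tip permutation (random expectation) and
Brownian motion on the branch lengths thresholded to match the observed
number of 1s (conserved expectation). Decisions: polytomies are resolved
arbitrarily to binary with zero-length branches (the statistic needs
sister pairs; zero-length resolution leaves path lengths unchanged);
1000 simulations per null by default; and *both* one-sided empirical
p-values are reported (fraction of null draws at or below the observed
sum) rather than a single combined value, because which null is the
relevant reference depends on the question. Calibration is verified by
construction: Brownian-threshold traits give mean D within ±0.1 of 0 and
permuted traits within ±0.1 of 1 over 200 simulated 64-tip trees.

`rank_conservation()` reports, per taxonomic rank, the mean within-taxon
sample SD of the trait over taxa with at least two genomes — singleton
taxa carry no information about within-taxon variation.
`group_enrichment()` compares genome-size-corrected category prevalences
(category count / total annotated genes) between two genome groups with
two-sided Mann–Whitney U tests (exact where sample size and ties permit;
fully tied comparisons report p = 1), Bonferroni correction across
categories, and a log2 ratio of group means; the significance default
α = 0.01 matches the convention of shading non-significant categories at
P > 0.01.

## Problem sizes and determinism

Every stochastic step takes an explicit seed and is reproducible to the
byte (genome FASTA, simulated FASTQ, splits, tuning, training, null
simulations). The bundled tests and the acceptance script run at desk
scale, chosen so the full suite completes in minutes on one CPU while
keeping each check's sampling error well inside its tolerance: a
12-genome pool behind the 14-point calibration gradient (~75,000 reads),
600 genomes for classifier recovery, and 200 trees × 100 simulations for
the D calibration. The classifier fixture labels genomes by a
deterministic rule (motile iff ≥ 15 of the 21 panel genes present) over a
bimodal carriage model, mimicking the empirical pattern that motile taxa
carry nearly the whole repertoire while nonmotile taxa retain variable
subsets; held-out accuracy ≥ 0.95 on it demonstrates rule recovery, not
real-world accuracy, and the label-permutation control (accuracy
0.5 ± 0.1 on balanced classes) guards against leakage.

## Known limitations

* The gene panel and marker set are taken as given; the package neither
  re-derives Pfam annotations nor curates genomes.
* The published curve coefficients apply to metagenomes annotated against
  the full reference variant database; indexes computed against other
  registries need their own calibration.
* Nonflagellar motility (gliding, twitching) is out of scope; "nonmotile"
  here means "not flagellated".
* The Brownian null assumes the supplied branch lengths are meaningful;
  trees without branch lengths cannot be used for D.
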