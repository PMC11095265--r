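# flagmot

Inference of bacterial flagellar motility from genomes and metagenomes.

Flagellar motility — swimming or swarming powered by the flagellum — is a
key bacterial trait, but phenotypic observations exist for only a small
fraction of known taxa. `flagmot` infers the trait at two scales:

* **Per genome.** A panel of flagellar-assembly gene families is selected
  from a labelled gene presence/absence matrix by dual prevalence criteria
  (retained when present in > 80% of motile genomes and in no more than 50%
  of nonmotile genomes), and a gradient-boosted decision-tree classifier
  with a binary logistic objective is tuned (Bayesian hyperparameter
  search, k-fold cross-validation), trained and evaluated on the binary
  gene features.
* **Per community.** From shotgun metagenomic reads, the *flagellar
  motility index* is

  ```
  index = median RPK(21 flagellar gene families) / median RPK(120 single-copy marker families)
  ```

  where RPK is the gene-length-corrected hit count (reads per kilobase),
  medians are taken over *all* families of each set including zero-count
  ones, and single-copy markers act as the normalization denominator
  because nearly every bacterial genome carries each of them once. The
  index maps to a percent of flagellated bacteria through a linear
  standard curve

  ```
  % flagellated = 3650 * index - 0.321
  ```

  calibrated on mock metagenomes; the package both ships these published
  coefficients and refits curves from simulated gradients
  (`calibrate_from_gradient()`).
* **Trait ecology.** The phylogenetic D statistic for binary traits
  (sister-clade difference sum scaled between permutation and
  Brownian-threshold nulls; D near 0 means conservatism, near 1 a random
  pattern), within-rank trait conservation, and gene-category enrichment
  between trait classes (Mann–Whitney U with Bonferroni correction).

A mock-metagenome simulator (synthetic genomes carrying each of the 120
marker families exactly once, uniform error-free or error-prone read
sampling at a chosen fold coverage, and a naive six-frame translated-search
annotator) lets the whole community tier run and be calibrated with no
external aligner. For real data, use genuine BLASTx/DIAMOND 12-column
tabular output via `read_hits_tabular()`.

## Worked example

Simulate a 12-genome pool, build a 14-point gradient of flagellated
proportions, calibrate a standard curve, and quantify one mixture:

```r
library(flagmot)

pool     <- generate_genome_pool(n_motile = 6, n_nonmotile = 6, seed = 101)
gradient <- build_gradient(pool, n_points = 14, seed = 101)
cal      <- calibrate_from_gradient(gradient, pool$genomes, pool$registry)
print(cal$curve)
#> <calibration_curve> percent = 102.484 * index + 1.82413 (r = 0.9985, n = 14)

reads <- simulate_reads(gradient[[8]], pool$genomes)
res   <- quantify_metagenome(registry = pool$registry, reads = reads,
                             curve = cal$curve)
print(res)
#> <motility_index_result> index 0.51475 (flagellar 20.76 / marker 40.33) -> 54.58% flagellated
```

The mixture was assembled with 53.8% flagellated genomes, so the estimate
lands within a percentage point. The r = 0.9985 of the fitted curve is the
linearity between index and true proportion across the whole gradient; the
synthetic slope (~100 per unit index) differs from the published 3650
because synthetic genomes are three orders of magnitude smaller than real
ones, which changes the scale of the index, not the linearity that the
method relies on.

The same steps are available from a shell through the installed CLI script
(`inst/scripts/flagmot`): `simulate`, `calibrate`, `quantify`,
`build-panel`, `train`, `predict`, `evaluate`, `phylo-d`, `rank-sd`,
`enrich`; every run drops a `run_manifest.json` with options, seed and
input checksums.

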