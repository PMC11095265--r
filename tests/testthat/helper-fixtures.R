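# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small genome pool (3 motile + 3 nonmotile) with registry
small_pool <- function() {
  fixture("small_pool", function() generate_genome_pool(3, 3, seed = 42))
}

# rule-labelled gene-content data: motile iff >= 15 of the 21 panel genes
rule_data <- function() {
  fixture("rule_data", function() simulate_gene_content(600, seed = 5))
}

# a mixed mixture over the small pool with its simulated reads and hits
small_mixture <- function() {
  fixture("small_mixture", function() {
    pool <- small_pool()
    mx <- mock_mixture(names(pool$genomes), seed = 7)
    reads <- simulate_reads(mx, pool$genomes)
    hits <- annotate_reads_naive(reads, pool$registry)
    list(mixture = mx, reads = reads, hits = hits,
         read_lengths = setNames(nchar(reads), names(reads)))
  })
}

random_hit_lines <- function(n, seed) {
  set.seed(seed)
  sprintf("r%03d\tp%02d\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%.1f",
          seq_len(n), sample(20, n, replace = TRUE),
          runif(n, 0, 100), sample(20:50, n, replace = TRUE),
          sample(0:5, n, replace = TRUE), sample(0:2, n, replace = TRUE),
          sample(150, n, replace = TRUE), sample(150, n, replace = TRUE),
          sample(500, n, replace = TRUE), sample(500, n, replace = TRUE),
          10^-runif(n, 0, 30), runif(n, 20, 200))
}

# desk-scale calibration experiment: 12-genome pool, 14-point gradient
desk_calibration <- function() {
  fixture("desk_calibration", function() {
    pool <- generate_genome_pool(6, 6, seed = 101)
    gradient <- build_gradient(pool, n_points = 14, seed = 101)
    cal <- calibrate_from_gradient(gradient, pool$genomes, pool$registry)
    list(pool = pool, gradient = gradient, cal = cal)
  })
}

# back-translate a protein deterministically (first codon per residue)
codons_for <- function(aa) {
  tab <- Biostrings::GENETIC_CODE
  paste0(vapply(strsplit(aa, "")[[1]],
                function(a) names(tab)[tab == a][1], character(1)),
         collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
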