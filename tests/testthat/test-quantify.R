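test_that("hit filters keep boundary-equal hits and remove strictly-failing ones", {
  cfg <- hit_filter_config()
  h <- hit_table(read_id = c("r1", "r2", "r3", "r4", "r5"),
                 protein_id = paste0("p", 1:5),
                 pct_identity = c(60, 99, 59.9, 60, 60),
                 aln_length = 50L,
                 bit_score = c(50, 49.9, 100, 50, 50),
                 e_value = c(0.001, 1e-20, 1e-20, 0.0011, 0.001))
  rl <- c(r1 = 101L, r2 = 150L, r3 = 150L, r4 = 150L, r5 = 100L)
  kept <- filter_hits(h, rl, cfg)
  # r1 sits exactly on every boundary (bit 50, id 60, e 0.001, len 101): kept
  # r2 fails bit, r3 fails identity, r4 fails e-value, r5 is not above 100 bp
  expect_equal(kept$read_id, "r1")
  expect_warning(filter_hits(h, NULL, cfg), "skipping")
  expect_error(filter_hits(h, rl[-1], cfg), "missing")
})

test_that("RPK profiles correct by gene length and include zero-count genes", {
  # gene lengths 900/450/1800 nt (aa 300/150/600) with 9/0/18 hits
  reg <- protein_registry(paste0("p", 1:3), c("gA", "gB", "gC"), "marker",
                          aa_length = c(300L, 150L, 600L))
  h <- hit_table(read_id = sprintf("r%02d", 1:27),
                 protein_id = c(rep("p1", 9), rep("p3", 18)),
                 pct_identity = 100, aln_length = 50L,
                 bit_score = 100, e_value = 1e-20)
  pr <- rpk_profile(h, reg, "marker")
  expect_equal(pr$table$rpk[match(c("gA", "gB", "gC"), pr$table$gene_id)],
               c(10, 0, 10))
  expect_equal(pr$median_rpk, 10)
  # all-zero profile has median 0; doubling counts doubles the median
  empty <- rpk_profile(hit_table(), reg, "marker")
  expect_equal(empty$median_rpk, 0)
  h2 <- hit_table(read_id = sprintf("s%02d", 1:54),
                  protein_id = rep(c(rep("p1", 9), rep("p3", 18)), 2),
                  pct_identity = 100, aln_length = 50L,
                  bit_score = 100, e_value = 1e-20)
  expect_equal(rpk_profile(h2, reg, "marker")$median_rpk, 20)
  expect_error(rpk_profile(h, reg, "flagellar"), "no gene families")
  expect_warning(rpk_profile(hit_table(read_id = c("r1", "r1"),
                                       protein_id = c("p1", "p2"),
                                       pct_identity = 100, aln_length = 50L,
                                       bit_score = 100, e_value = 0),
                             reg, "marker"), "one best hit")
})

test_that("RPK profiling matches a brute-force per-gene tally on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    ngene <- sample(3:8, 1)
    genes <- sprintf("g%02d", seq_len(ngene))
    nv <- sample(1:4, ngene, replace = TRUE)
    reg <- protein_registry(
      protein_id = sprintf("v%03d", seq_len(sum(nv))),
      gene_id = rep(genes, nv),
      role = "marker",
      aa_length = sample(100:600, sum(nv), replace = TRUE))
    nh <- sample(0:60, 1)
    h <- hit_table(read_id = sprintf("r%04d", seq_len(nh)),
                   protein_id = sample(reg$protein_id, nh, replace = TRUE),
                   pct_identity = 100, aln_length = 50L,
                   bit_score = 100, e_value = 0)
    pr <- rpk_profile(h, reg, "marker")
    # brute force: per gene, loop over hits and variants
    rpk_bf <- vapply(genes, function(g) {
      vars <- reg$protein_id[reg$gene_id == g]
      cnt <- sum(h$protein_id %in% vars)
      len_kb <- 3 * median(reg$aa_length[reg$gene_id == g]) / 1000
      cnt / len_kb
    }, numeric(1))
    expect_equal(setNames(pr$table$rpk, pr$table$gene_id)[genes], rpk_bf)
    expect_equal(pr$median_rpk, median(rpk_bf))
  }
})

test_that("the motility index is the flagellar/marker median-RPK ratio", {
  mk <- function(role, med) structure(list(role = role, median_rpk = med),
                                      class = "gene_set_profile")
  expect_equal(motility_index(mk("flagellar", 0.5), mk("marker", 50))$index, 0.01)
  expect_equal(motility_index(mk("flagellar", 0), mk("marker", 50))$index, 0)
  expect_equal(motility_index(mk("flagellar", 7), mk("marker", 7))$index, 1)
  expect_error(motility_index(mk("flagellar", 1), mk("marker", 0)),
               "insufficient marker signal")
})

test_that("the published standard curve maps index to percent as printed", {
  cc <- default_calibration()
  expect_identical(apply_calibration(cc, 0), -0.321)
  expect_equal(apply_calibration(cc, 0.01), 36.179)
  expect_equal(apply_calibration(cc, 0.03), 109.179)
  expect_equal(apply_calibration(cc, 0.03, clamp = TRUE), 100)
  expect_equal(apply_calibration(cc, 0.001, clamp = TRUE), 3.329)
  expect_error(apply_calibration(cc, -1))
})

test_that("curve fitting recovers exact lines and reacts to outliers", {
  fc <- fit_calibration(c(0, 0.01, 0.02), c(0, 36.5, 73))
  expect_equal(fc$slope, 3650)
  expect_equal(fc$intercept, 0, tolerance = 1e-10)
  expect_equal(fc$pearson_r, 1)
  expect_equal(fc$n_points, 3L)

  expect_warning(fc2 <- fit_calibration(c(0, 0.02), c(0, 73)),
                 "2 calibration points")
  expect_equal(fc2$slope, 3650)
  expect_equal(fc2$pearson_r, 1)

  expect_error(fit_calibration(c(0.01, 0.01), c(1, 2)), "identical")

  # one outlier pulls the OLS slope between the clean fit and itself
  x <- c(0, 0.01, 0.02, 0.03); y <- c(0, 36.5, 73, 60)
  fc3 <- fit_calibration(x, y)
  expect_lt(fc3$slope, 3650)
  expect_gt(fc3$slope, 1000)
  expect_lt(fc3$pearson_r, 1)
  # closed-form OLS check
  expect_equal(fc3$slope, cov(x, y) / var(x))
})

test_that("index and percent are invariant to duplicating the library", {
  sm <- small_mixture()
  pool <- small_pool()
  res1 <- quantify_metagenome(sm$hits, pool$registry,
                              read_lengths = sm$read_lengths)
  dup_hits <- sm$hits
  dup_hits$read_id <- paste0(dup_hits$read_id, "_dup")
  both <- rbind(sm$hits, dup_hits)
  class(both) <- class(sm$hits)
  rl2 <- c(sm$read_lengths,
           setNames(sm$read_lengths, paste0(names(sm$read_lengths), "_dup")))
  res2 <- quantify_metagenome(both, pool$registry, read_lengths = rl2)
  expect_equal(res2$index, res1$index)
  expect_equal(res2$percent_flagellated, res1$percent_flagellated)
  expect_equal(res2$flagellar_median_rpk, 2 * res1$flagellar_median_rpk)
})

test_that("end-to-end quantification recovers gradient endpoints with a self-fitted curve", {
  dc <- desk_calibration()
  expect_gte(dc$cal$curve$pearson_r, 0.99)
  for (i in c(1L, 14L)) {
    reads <- simulate_reads(dc$gradient[[i]], dc$pool$genomes)
    res <- quantify_metagenome(registry = dc$pool$registry, reads = reads,
                               curve = dc$cal$curve)
    truth <- 100 * proportion_flagellated(dc$gradient[[i]], dc$pool$genomes)
    expect_lt(abs(res$percent_flagellated - truth), 5)
  }
  # an empty read set carries no marker signal
  expect_error(quantify_metagenome(registry = small_pool()$registry,
                                   reads = character(0)),
               "insufficient marker signal")
})
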