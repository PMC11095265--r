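#' Hit filter thresholds
#'
#' Quality filters applied to translated-search hits before profiling. The
#' boundary semantics mirror the removal rules "strictly below / strictly
#' above": hits with bit score < `min_bit_score`, identity <
#' `min_pct_identity` or e-value > `max_e_value` are removed, so
#' boundary-equal hits are kept. Reads are kept only when strictly longer
#' than `min_read_length_bp`.
#'
#' @param min_bit_score default 50.
#' @param min_pct_identity default 60 (percent).
#' @param max_e_value default 0.001.
#' @param min_read_length_bp default 100; reads must be *above* this length.
#' @return a `hit_filter_config` list.
#' @export
hit_filter_config <- function(min_bit_score = 50, min_pct_identity = 60,
                              max_e_value = 0.001, min_read_length_bp = 100) {
  stopifnot(min_bit_score >= 0, min_pct_identity >= 0, max_e_value >= 0,
            min_read_length_bp >= 0)
  structure(list(min_bit_score = min_bit_score,
                 min_pct_identity = min_pct_identity,
                 max_e_value = max_e_value,
                 min_read_length_bp = min_read_length_bp),
            class = "hit_filter_config")
}

#' Filter translated-search hits
#'
#' @param hits a `hit_table`.
#' @param read_lengths named integer vector of read lengths (bp) keyed by
#'   read id; when `NULL` the read-length rule is skipped with a warning.
#' @param cfg a [hit_filter_config()].
#' @return the filtered `hit_table` (possibly empty).
#' @export
filter_hits <- function(hits, read_lengths = NULL, cfg = hit_filter_config()) {
  stopifnot(inherits(hits, "hit_table"), inherits(cfg, "hit_filter_config"))
  keep <- hits$bit_score >= cfg$min_bit_score &
    hits$pct_identity >= cfg$min_pct_identity &
    hits$e_value <= cfg$max_e_value
  if (is.null(read_lengths)) {
    warning("read lengths unavailable; skipping the minimum read length rule")
  } else {
    rl <- read_lengths[hits$read_id]
    if (anyNA(rl)) stop("read lengths missing for some hit read ids")
    keep <- keep & rl > cfg$min_read_length_bp
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set RPK profile
#'
#' Tallies filtered, one-best-hit-per-read hits into gene families of one
#' role and computes each family's reads per kilobase. The gene length is
#' the median variant amino-acid length times 3 (nucleotides); the median
#' RPK is taken over *every* family of the role, including zero-count
#' families, so the flagellar and marker medians share fixed denominators.
#'
#' @param hits a filtered `hit_table`, at most one hit per read.
#' @param registry a [protein_registry()].
#' @param role `"flagellar"` or `"marker"`.
#' @return a `gene_set_profile`: list with `role`, per-gene `table`
#'   (`gene_id`, `hit_count`, `length_kb`, `rpk`) and `median_rpk`.
#' @export
rpk_profile <- function(hits, registry, role) {
  stopifnot(inherits(hits, "hit_table"))
  if (anyDuplicated(hits$read_id)) {
    warning("multiple hits per read; expected one best hit per read")
  }
  genes <- registry_genes(registry, role)
  prot2gene <- setNames(registry$gene_id, registry$protein_id)
  gene_of_hit <- prot2gene[hits$protein_id]
  counts <- table(factor(gene_of_hit, levels = genes$gene_id))
  tab <- data.frame(gene_id = genes$gene_id,
                    hit_count = as.integer(counts[genes$gene_id]),
                    length_kb = genes$length_kb,
                    stringsAsFactors = FALSE)
  tab$rpk <- tab$hit_count / tab$length_kb
  structure(list(role = role, table = tab, median_rpk = median(tab$rpk)),
            class = "gene_set_profile")
}

#' @export
print.gene_set_profile <- function(x, ...) {
  cat(sprintf("<gene_set_profile> role %s: %d gene families, %d hits, median RPK %.4g\n",
              x$role, nrow(x$table), sum(x$table$hit_count), x$median_rpk))
  invisible(x)
}

#' Flagellar motility index of a metagenome
#'
#' Ratio of the flagellar median RPK to the single-copy marker median RPK.
#' A zero marker median means the metagenome carries no usable normalization
#' signal and is an error.
#'
#' @param flagellar,marker `gene_set_profile`s of the respective roles.
#' @return a `motility_index_result`: list with `flagellar_median_rpk`,
#'   `marker_median_rpk` and `index` (percent slot unset until
#'   [apply_calibration()]).
#' @export
motility_index <- function(flagellar, marker) {
  stopifnot(inherits(flagellar, "gene_set_profile"),
            inherits(marker, "gene_set_profile"))
  if (marker$median_rpk <= 0) {
    stop("insufficient marker signal: marker median RPK is 0")
  }
  structure(list(flagellar_median_rpk = flagellar$median_rpk,
                 marker_median_rpk = marker$median_rpk,
                 index = flagellar$median_rpk / marker$median_rpk,
                 percent_flagellated = NA_real_,
                 calibration = NULL),
            class = "motility_index_result")
}

#' @export
print.motility_index_result <- function(x, ...) {
  cat(sprintf("<motility_index_result> index %.5g (flagellar %.4g / marker %.4g)",
              x$index, x$flagellar_median_rpk, x$marker_median_rpk))
  if (!is.na(x$percent_flagellated)) {
    cat(sprintf(" -> %.2f%% flagellated", x$percent_flagellated))
  }
  cat("\n")
  invisible(x)
}

#' Linear standard curve index -> percent flagellated
#'
#' The published coefficients (slope 3650, intercept -0.321, fitted on a
#' 14-point mock-metagenome gradient) are the defaults; fitted curves carry
#' their own coefficients and Pearson r.
#'
#' @param slope,intercept linear coefficients.
#' @param pearson_r Pearson correlation of the calibration points.
#' @param n_points number of calibration points behind the curve.
#' @return a `calibration_curve` list.
#' @export
calibration_curve <- function(slope = 3650, intercept = -0.321,
                              pearson_r = NA_real_, n_points = 14L) {
  if (!is.na(pearson_r) && n_points < 2L) {
    stop("a fitted curve needs n_points >= 2")
  }
  structure(list(slope = slope, intercept = intercept,
                 pearson_r = pearson_r, n_points = as.integer(n_points)),
            class = "calibration_curve")
}

#' @rdname calibration_curve
#' @export
default_calibration <- function() calibration_curve()

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> percent = %.6g * index + %.6g (r = %s, n = %d)\n",
              x$slope, x$intercept,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.4f", x$pearson_r),
              x$n_points))
  invisible(x)
}

#' Convert a motility index to percent flagellated bacteria
#'
#' Evaluates `percent = slope * index + intercept`. The line can produce
#' values slightly below 0 near index 0 (its intercept is negative) or above
#' 100; these are returned as-is unless `clamp = TRUE`, which truncates to
#' `[0, 100]` and logs the truncation.
#'
#' @param curve a [calibration_curve()].
#' @param index non-negative finite motility index, or a
#'   `motility_index_result`.
#' @param clamp truncate to `[0, 100]` (default `FALSE`).
#' @return numeric percent, or the updated `motility_index_result`.
#' @export
apply_calibration <- function(curve, index, clamp = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (inherits(index, "motility_index_result")) {
    res <- index
    res$percent_flagellated <- apply_calibration(curve, res$index, clamp)
    res$calibration <- curve
    return(res)
  }
  stopifnot(is.finite(index), index >= 0)
  pct <- curve$slope * index + curve$intercept
  if (clamp) {
    clamped <- pmin(100, pmax(0, pct))
    if (any(clamped != pct)) {
      flagmot_log("info", sprintf("clamped percent estimate %.3f to %.3f",
                                  pct, clamped))
    }
    pct <- clamped
  }
  pct
}

#' Fit a standard curve from calibration points
#'
#' Ordinary least squares of true percent on index, with the Pearson
#' correlation of the points. With exactly two points the fit is an exact
#' interpolation and r is reported as 1 with a warning.
#'
#' @param index motility indices of the calibration mixtures.
#' @param true_percent known percent flagellated of each mixture.
#' @return a fitted [calibration_curve()].
#' @export
fit_calibration <- function(index, true_percent) {
  stopifnot(length(index) == length(true_percent), length(index) >= 2L)
  if (length(unique(index)) < 2L) {
    stop("all calibration indices are identical; cannot fit a line")
  }
  fit <- lm(true_percent ~ index)
  r <- if (length(index) == 2L) {
    warning("only 2 calibration points: exact interpolation, r reported as 1")
    1.0
  } else {
    cor(index, true_percent)
  }
  calibration_curve(slope = unname(coef(fit)[2L]),
                    intercept = unname(coef(fit)[1L]),
                    pearson_r = r, n_points = length(index))
}

#' Quantify flagellar motility prevalence in one metagenome
#'
#' Full composition: filter hits, profile the flagellar and marker gene
#' sets, form the motility index and apply the standard curve. Input can be
#' reads (annotated here with the naive translated search) or a precomputed
#' hit table from real translated-search output.
#'
#' @param hits a `hit_table`, or `NULL` when `reads` are given.
#' @param registry a [protein_registry()].
#' @param reads optional named character vector of reads (or a FASTQ path);
#'   annotated with [annotate_reads_naive()].
#' @param read_lengths named read lengths for the length filter; derived
#'   from `reads` automatically when those are given.
#' @param cfg a [hit_filter_config()].
#' @param curve a [calibration_curve()], or `NULL` to skip conversion.
#' @param clamp passed to [apply_calibration()].
#' @return a `motility_index_result` with profiles attached
#'   (`$flagellar_profile`, `$marker_profile`).
#' @export
quantify_metagenome <- function(hits = NULL, registry, reads = NULL,
                                read_lengths = NULL,
                                cfg = hit_filter_config(),
                                curve = default_calibration(),
                                clamp = FALSE) {
  if (is.null(hits)) {
    if (is.null(reads)) stop("provide hits or reads")
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
      reads <- read_fastq(reads)$sequences
    }
    hits <- annotate_reads_naive(reads, registry)
    read_lengths <- setNames(nchar(reads), names(reads))
  }
  filtered <- filter_hits(hits, read_lengths, cfg)
  flag <- rpk_profile(filtered, registry, "flagellar")
  mark <- rpk_profile(filtered, registry, "marker")
  res <- motility_index(flag, mark)
  res$flagellar_profile <- flag
  res$marker_profile <- mark
  if (!is.null(curve)) res <- apply_calibration(curve, res, clamp)
  res
}

#' Run the mock-metagenome calibration experiment
#'
#' Simulates reads for every mixture of a [build_gradient()] design,
#' annotates them naively, quantifies each mixture's motility index and fits
#' the standard curve against the known flagellated proportions.
#'
#' @param gradient a `gradient_design`.
#' @param genomes named list of `synthetic_genome`s backing the design.
#' @param registry the pool's [protein_registry()].
#' @param cfg a [hit_filter_config()].
#' @return list with `curve` (fitted [calibration_curve()]) and `points`
#'   (data frame `mixture`, `true_proportion`, `index`,
#'   `flagellar_median_rpk`, `marker_median_rpk`, `n_reads`).
#' @export
calibrate_from_gradient <- function(gradient, genomes, registry,
                                    cfg = hit_filter_config()) {
  stopifnot(inherits(gradient, "gradient_design"))
  rows <- lapply(seq_along(gradient), function(i) {
    mx <- gradient[[i]]
    reads <- simulate_reads(mx, genomes)
    res <- quantify_metagenome(registry = registry, reads = reads,
                               cfg = cfg, curve = NULL)
    data.frame(mixture = names(gradient)[i],
               true_proportion = proportion_flagellated(mx, genomes),
               index = res$index,
               flagellar_median_rpk = res$flagellar_median_rpk,
               marker_median_rpk = res$marker_median_rpk,
               n_reads = length(reads),
               stringsAsFactors = FALSE)
  })
  points <- do.call(rbind, rows)
  curve <- fit_calibration(points$index, 100 * points$true_proportion)
  list(curve = curve, points = points)
}
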