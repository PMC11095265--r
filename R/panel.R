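#' Binarize a gene-content matrix
#'
#' Collapses copy numbers to presence/absence: a cell becomes 1 iff the count
#' is greater than zero. Already-binary input is returned unchanged, so the
#' operation is idempotent.
#'
#' @param matrix integer matrix of non-negative counts (genomes x genes).
#' @return integer 0/1 matrix with the same dimnames and `is_binary = TRUE`.
#' @export
binarize <- function(matrix) {
  if (!is.numeric(matrix)) stop("gene-content matrix must be numeric")
  if (any(matrix < 0)) stop("gene-content counts must be >= 0")
  out <- matrix
  out[] <- as.integer(matrix > 0)
  attr(out, "is_binary") <- TRUE
  out
}

#' Per-gene prevalence in motile and nonmotile genomes
#'
#' For each gene family, the fraction of genomes of each phenotype class in
#' which the gene is present. Input must be binary (run [binarize()] first).
#'
#' @param matrix binary gene-content matrix (genomes x genes).
#' @param phenotypes named character vector of labels (`motile`/`nonmotile`)
#'   covering every genome in `matrix`.
#' @return data frame with columns `gene_id`, `prev_motile`,
#'   `prev_nonmotile`, in matrix column order.
#' @export
gene_prevalence <- function(matrix, phenotypes) {
  if (!all(matrix %in% c(0L, 1L))) {
    stop("matrix must be binary; call binarize() first")
  }
  missing <- setdiff(rownames(matrix), names(phenotypes))
  if (length(missing)) {
    stop("genomes without phenotype: ", paste(missing, collapse = ", "))
  }
  lab <- phenotypes[rownames(matrix)]
  mot <- lab == "motile"
  if (!any(mot) || all(mot)) {
    stop("both phenotype classes must be non-empty")
  }
  data.frame(gene_id = colnames(matrix),
             prev_motile = colMeans(matrix[mot, , drop = FALSE]),
             prev_nonmotile = colMeans(matrix[!mot, , drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Panel selection criteria
#'
#' The dual prevalence rule for retaining a predictor gene family: present in
#' more than `min_prevalence_motile` of motile genomes, and not present in
#' more than `max_prevalence_nonmotile` of nonmotile genomes. With
#' `strict = TRUE` (default) the motile bound is a strict inequality
#' (`> 0.80`) and a gene is dropped only when its nonmotile prevalence
#' strictly exceeds the bound (so `<= 0.50` is retained); with
#' `strict = FALSE` the motile bound becomes `>=`.
#'
#' @param min_prevalence_motile fraction in `[0, 1]`, default 0.80.
#' @param max_prevalence_nonmotile fraction in `[0, 1]`, default 0.50.
#' @param strict logical, default `TRUE`.
#' @return a `panel_criteria` list.
#' @export
panel_criteria <- function(min_prevalence_motile = 0.80,
                           max_prevalence_nonmotile = 0.50,
                           strict = TRUE) {
  stopifnot(min_prevalence_motile >= 0, min_prevalence_motile <= 1,
            max_prevalence_nonmotile >= 0, max_prevalence_nonmotile <= 1,
            is.logical(strict), length(strict) == 1L)
  structure(list(min_prevalence_motile = min_prevalence_motile,
                 max_prevalence_nonmotile = max_prevalence_nonmotile,
                 strict = strict),
            class = "panel_criteria")
}

#' Select the predictor gene panel
#'
#' Applies [panel_criteria()] to per-gene prevalences, optionally restricted
#' to a candidate gene list (e.g. the flagellar-assembly families). Retained
#' genes keep their input order. An empty selection is returned as an empty
#' panel with a warning, not an error.
#'
#' @param prevalences data frame from [gene_prevalence()].
#' @param criteria a [panel_criteria()].
#' @param candidates optional character vector restricting the candidate
#'   pool; genes outside it are never selected.
#' @return a `gene_panel`: data frame of retained genes with their two
#'   prevalences, plus attributes `criteria` and `candidate_pool_size`.
#' @export
select_panel <- function(prevalences, criteria = panel_criteria(),
                         candidates = NULL) {
  stopifnot(inherits(criteria, "panel_criteria"))
  pool <- prevalences
  if (!is.null(candidates)) {
    pool <- pool[pool$gene_id %in% candidates, , drop = FALSE]
  }
  pm <- pool$prev_motile
  pn <- pool$prev_nonmotile
  keep_motile <- if (criteria$strict) pm > criteria$min_prevalence_motile
                 else pm >= criteria$min_prevalence_motile
  keep_nonmotile <- !(pn > criteria$max_prevalence_nonmotile)
  out <- pool[keep_motile & keep_nonmotile, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) {
    warning("no gene satisfies the panel criteria; returning an empty panel")
  }
  attr(out, "criteria") <- criteria
  attr(out, "candidate_pool_size") <- nrow(pool)
  class(out) <- c("gene_panel", class(out))
  out
}

#' @export
print.gene_panel <- function(x, ...) {
  cr <- attr(x, "criteria")
  cat(sprintf("<gene_panel> %d of %d candidate genes (motile prev %s %.2f, nonmotile prev <= %.2f)\n",
              nrow(x), attr(x, "candidate_pool_size"),
              if (cr$strict) ">" else ">=",
              cr$min_prevalence_motile, cr$max_prevalence_nonmotile))
  print.data.frame(x)
  invisible(x)
}

#' Write / read a gene panel TSV
#'
#' @param panel a `gene_panel`.
#' @param path TSV path.
#' @return invisibly, `path` (writer); data frame (reader).
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
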