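#' Protein reference registry
#'
#' The registry is the community-tier reference database: every protein
#' variant of every gene family the pipeline can assign reads to, with its
#' gene family, its role and its amino-acid length. Roles partition gene
#' families into the flagellar predictor set, the single-copy marker set used
#' as normalization denominator, and anything else (`"other"`). A gene family
#' typically has many protein variants, one per reference genome.
#'
#' @param protein_id character, unique per variant.
#' @param gene_id character, the gene family of each variant.
#' @param role character, one of `"flagellar"`, `"marker"`, `"other"`;
#'   recycled if length 1. All variants of a gene family must share a role.
#' @param aa_length integer amino-acid lengths (> 0). May be omitted when
#'   `sequence` is given.
#' @param sequence optional amino-acid sequences; when present,
#'   `aa_length` must equal `nchar(sequence)`.
#' @return an object of class `protein_registry`: a data frame with columns
#'   `protein_id`, `gene_id`, `role`, `aa_length`, `sequence`.
#' @export
protein_registry <- function(protein_id, gene_id, role, aa_length = NULL,
                             sequence = NULL) {
  protein_id <- as.character(protein_id)
  gene_id <- as.character(gene_id)
  n <- length(protein_id)
  if (length(gene_id) != n) stop("protein_id and gene_id lengths differ")
  role <- rep_len(as.character(role), n)
  bad_role <- setdiff(unique(role), c("flagellar", "marker", "other"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  if (is.null(sequence)) {
    sequence <- rep(NA_character_, n)
  } else {
    sequence <- as.character(sequence)
    if (length(sequence) != n) stop("sequence length mismatch")
  }
  if (is.null(aa_length)) {
    if (all(is.na(sequence))) stop("need aa_length or sequence")
    aa_length <- nchar(sequence)
  }
  aa_length <- as.integer(aa_length)
  if (anyNA(aa_length) || any(aa_length <= 0)) {
    stop("aa_length must be positive integers")
  }
  has_seq <- !is.na(sequence)
  if (any(aa_length[has_seq] != nchar(sequence[has_seq]))) {
    stop("aa_length disagrees with sequence length")
  }
  if (anyDuplicated(protein_id)) {
    stop("duplicate protein_id: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  }
  role_per_gene <- tapply(role, gene_id, function(r) length(unique(r)))
  if (any(role_per_gene > 1L)) {
    stop("gene families with conflicting roles: ",
         paste(names(role_per_gene)[role_per_gene > 1L], collapse = ", "))
  }
  out <- data.frame(protein_id = protein_id, gene_id = gene_id, role = role,
                    aa_length = aa_length, sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_registry", class(out))
  out
}

#' @export
print.protein_registry <- function(x, ...) {
  cat(sprintf("<protein_registry> %d variants, %d gene families (%s)\n",
              nrow(x), length(unique(x$gene_id)),
              paste(sprintf("%s: %d", names(table(x$role[!duplicated(x$gene_id)])),
                            table(x$role[!duplicated(x$gene_id)])),
                    collapse = ", ")))
  invisible(x)
}

#' Per-gene summary of a registry role
#'
#' Collapses the protein variants of one role into gene families, with the
#' variant count and the median variant amino-acid length used as the gene
#' length for RPK correction.
#'
#' @param registry a [protein_registry()].
#' @param role `"flagellar"` or `"marker"` (or `"other"`).
#' @return data frame with `gene_id`, `n_variants`, `median_aa_length`,
#'   `length_kb` (nucleotide kilobases, `3 * median_aa_length / 1000`).
#' @export
registry_genes <- function(registry, role) {
  stopifnot(inherits(registry, "protein_registry"))
  role <- match.arg(role, c("flagellar", "marker", "other"))
  sub <- registry[registry$role == role, , drop = FALSE]
  if (!nrow(sub)) stop("registry has no gene families with role '", role, "'")
  med <- tapply(sub$aa_length, sub$gene_id, median)
  nv <- tapply(sub$aa_length, sub$gene_id, length)
  out <- data.frame(gene_id = names(med),
                    n_variants = as.integer(nv[names(med)]),
                    median_aa_length = as.numeric(med),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$length_kb <- 3 * out$median_aa_length / 1000
  out
}

#' Read a protein registry from disk
#'
#' The on-disk form is a TSV with columns `protein_id`, `gene_id`, `role`
#' (and optionally `aa_length`) plus an optional amino-acid FASTA keyed by
#' `protein_id` supplying the sequences.
#'
#' @param table_path path to the registry TSV.
#' @param fasta_path optional path to an amino-acid FASTA of the variants.
#' @return a [protein_registry()].
#' @export
read_registry <- function(table_path, fasta_path = NULL) {
  tab <- read.table(table_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
  need <- c("protein_id", "gene_id", "role")
  if (!all(need %in% names(tab))) {
    stop("registry table needs columns: ", paste(need, collapse = ", "))
  }
  seqs <- NULL
  if (!is.null(fasta_path)) {
    aa <- Biostrings::readAAStringSet(fasta_path)
    nm <- sub("\\s.*$", "", names(aa))
    seqs <- setNames(as.character(aa), nm)[tab$protein_id]
    if (anyNA(seqs)) {
      stop("registry FASTA missing variants: ",
           paste(head(tab$protein_id[is.na(seqs)]), collapse = ", "))
    }
  }
  protein_registry(tab$protein_id, tab$gene_id, tab$role,
                   aa_length = if ("aa_length" %in% names(tab)) tab$aa_length,
                   sequence = seqs)
}

#' Write a protein registry to disk
#'
#' Inverse of [read_registry()]: writes the table TSV and, when sequences are
#' present, the variant FASTA.
#'
#' @param registry a [protein_registry()].
#' @param table_path output TSV path.
#' @param fasta_path optional output FASTA path for the variant sequences.
#' @return invisibly, `table_path`.
#' @export
write_registry <- function(registry, table_path, fasta_path = NULL) {
  stopifnot(inherits(registry, "protein_registry"))
  tab <- registry[, c("protein_id", "gene_id", "role", "aa_length")]
  write.table(tab, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    if (anyNA(registry$sequence)) {
      stop("registry has variants without sequences; cannot write FASTA")
    }
    write_fasta(setNames(registry$sequence, registry$protein_id), fasta_path,
                type = "AA")
  }
  invisible(table_path)
}
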