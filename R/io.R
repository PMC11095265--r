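#' Read translated-search hits in 12-column tabular form
#'
#' Parses the standard 12-column tabular output of BLASTx/DIAMOND
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, the `outfmt 6` convention) into a hit table. Extra
#' columns beyond the twelfth are ignored with a logged warning; lines with
#' fewer than 12 columns are an error naming the line.
#'
#' @param path path to the tabular file.
#' @return a `hit_table` data frame with columns `read_id`, `protein_id`,
#'   `pct_identity`, `aln_length`, `bit_score`, `e_value`, in file order.
#' @export
read_hits_tabular <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop(sprintf("malformed hit line %d: expected 12 tab-separated columns, got %d",
                 bad, nf[bad]))
  }
  if (any(nf > 12L)) {
    flagmot_log("warn", sprintf("%d hit line(s) carry more than 12 columns; extras ignored",
                                sum(nf > 12L)))
  }
  m <- vapply(fields, function(f) f[1:12], character(12L))
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(m[i, ]))
    if (anyNA(v)) {
      stop(sprintf("malformed hit line %d: non-numeric %s", which(is.na(v))[1L], what))
    }
    v
  }
  out <- hit_table(read_id = m[1, ], protein_id = m[2, ],
                   pct_identity = num(3, "pident"),
                   aln_length = as.integer(num(4, "length")),
                   bit_score = num(12, "bitscore"),
                   e_value = num(11, "evalue"))
  out
}

#' Construct a hit table
#'
#' @param read_id,protein_id character identifiers.
#' @param pct_identity percent identity in `[0, 100]`.
#' @param aln_length alignment length (aligned positions).
#' @param bit_score finite bit scores.
#' @param e_value e-values, `>= 0`.
#' @return a `hit_table` data frame.
#' @export
hit_table <- function(read_id = character(), protein_id = character(),
                      pct_identity = numeric(), aln_length = integer(),
                      bit_score = numeric(), e_value = numeric()) {
  out <- data.frame(read_id = as.character(read_id),
                    protein_id = as.character(protein_id),
                    pct_identity = as.numeric(pct_identity),
                    aln_length = as.integer(aln_length),
                    bit_score = as.numeric(bit_score),
                    e_value = as.numeric(e_value),
                    stringsAsFactors = FALSE)
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("pct_identity outside [0, 100]")
  }
  if (any(!is.finite(out$bit_score))) stop("non-finite bit_score")
  if (any(out$e_value < 0)) stop("negative e_value")
  class(out) <- c("hit_table", class(out))
  out
}

#' Write a hit table in 12-column tabular form
#'
#' Columns not represented in the hit table (`mismatch`, `gapopen`, query and
#' subject coordinates) are written as 0 placeholders; [read_hits_tabular()]
#' recovers the stored fields exactly.
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hits_tabular <- function(hits, path) {
  stopifnot(inherits(hits, "hit_table"))
  lines <- sprintf("%s\t%s\t%s\t%d\t0\t0\t0\t0\t0\t0\t%s\t%s",
                   hits$read_id, hits$protein_id,
                   format(hits$pct_identity, trim = TRUE, digits = 15),
                   hits$aln_length,
                   format(hits$e_value, trim = TRUE, digits = 15),
                   format(hits$bit_score, trim = TRUE, digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-content matrix
#'
#' TSV with the genome id in the first column and one column per gene family;
#' cells are non-negative integer copy numbers (or 0/1 after binarization).
#'
#' @param path path to the TSV.
#' @return an integer matrix (genomes x genes) with row/column names in file
#'   order and attribute `is_binary`.
#' @export
read_gene_content <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("gene-content TSV needs a genome id column and >= 1 gene column")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate genome id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- colnames(tab)[-1L]
  if (anyDuplicated(genes)) {
    stop("duplicate gene column(s): ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    stop("gene-content cells must be non-negative integers")
  }
  m <- matrix(as.integer(vals), nrow = nrow(vals),
              dimnames = list(ids, genes))
  attr(m, "is_binary") <- all(m %in% c(0L, 1L))
  m
}

#' Write a gene-content matrix
#'
#' @param matrix integer matrix as returned by [read_gene_content()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_gene_content <- function(matrix, path) {
  tab <- data.frame(genome_id = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns `genome_id` and `label`; labels must be `motile` or
#' `nonmotile`.
#'
#' @param path path to the TSV.
#' @return named character vector of labels, names are genome ids.
#' @export
read_phenotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (!all(c("genome_id", "label") %in% names(tab))) {
    stop("phenotype TSV needs columns genome_id and label")
  }
  ids <- as.character(tab$genome_id)
  if (anyDuplicated(ids)) {
    stop("duplicate genome id(s) in phenotypes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lab <- as.character(tab$label)
  bad <- setdiff(unique(lab), c("motile", "nonmotile"))
  if (length(bad)) stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  setNames(lab, ids)
}

#' Write a phenotype table
#'
#' @param phenotypes named character vector (`motile`/`nonmotile`).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(data.frame(genome_id = names(phenotypes), label = unname(phenotypes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping record order and names. Sequences
#' are handled as named character vectors so synthetic-genome code and tests
#' can stay format-agnostic.
#'
#' @param path file path.
#' @param type `"DNA"` or `"AA"`.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- switch(type,
              DNA = Biostrings::readDNAStringSet(path),
              AA = Biostrings::readAAStringSet(path))
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @return `write_fasta`: invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- switch(type,
              DNA = Biostrings::DNAStringSet(sequences),
              AA = Biostrings::AAStringSet(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ (phred+33)
#'
#' Qualities use the phred+33 encoding throughout. A record whose quality
#' string length differs from its sequence length is an error.
#'
#' @param path file path.
#' @return `read_fastq`: list with named character vectors `sequences` and
#'   `qualities` (same names, same order).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  s <- as.character(x)
  if (any(nchar(q) != nchar(s))) {
    stop("FASTQ record with quality length != sequence length: ",
         names(x)[which(nchar(q) != nchar(s))[1L]])
  }
  nm <- sub("\\s.*$", "", names(x))
  list(sequences = setNames(s, nm), qualities = setNames(q, nm))
}

#' @rdname read_fastq
#' @param sequences named character vector of reads.
#' @param qualities character vector of phred+33 quality strings; default is
#'   constant `"I"` (Q40).
#' @return `write_fastq`: invisibly, `path`.
#' @export
write_fastq <- function(sequences, path, qualities = NULL) {
  if (is.null(qualities)) {
    qualities <- vapply(nchar(sequences),
                        function(n) strrep("I", n), character(1))
  }
  if (any(nchar(qualities) != nchar(sequences))) {
    stop("quality length != sequence length")
  }
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(unname(qualities)))
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an `ape::phylo` tree with branch lengths and tip labels preserved.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop("failed to parse Newick file: ", path)
  tr
}
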