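#' Naive translated-search annotation of reads
#'
#' Assigns each read to at most one registry protein by a seed-and-extend
#' translated search: every read is translated in all six frames, exact
#' amino-acid k-mers (default k = 7) anchor candidate protein diagonals, and
#' each candidate is scored over the full ungapped overlap of the translated
#' frame with the protein. Scoring uses simple surrogates, not a BLOSUM
#' model: `pct_identity = matches / aligned_aa * 100`, bit score
#' `2 * matched_aa`, e-value `10^(-matched_aa / 2)`. The best hit per read
#' is kept (highest bit score; ties broken by lower e-value, then
#' lexicographic protein id). Intended for synthetic mock metagenomes; real
#' data should use genuine translated-search tabular output via
#' [read_hits_tabular()].
#'
#' @param reads named character vector of reads (or the `sequences` element
#'   of [read_fastq()]).
#' @param registry a [protein_registry()] with variant sequences.
#' @param k amino-acid seed length (default 7).
#' @return a `hit_table` (see [hit_table()]), one row per read with a hit.
#' @export
annotate_reads_naive <- function(reads, registry, k = 7L) {
  stopifnot(inherits(registry, "protein_registry"))
  if (!nrow(registry) || all(is.na(registry$sequence))) {
    stop("registry has no protein sequences")
  }
  if (!length(reads)) return(hit_table())
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))

  prot <- registry[!is.na(registry$sequence), , drop = FALSE]
  index <- .protein_kmer_index(prot$sequence, k)

  qk <- .read_frame_kmers(reads, k)
  if (!nrow(qk$kmers)) return(hit_table())

  kmer <- qpos <- spos <- prot_idx <- read_idx <- frame <- diag <- NULL # NSE
  cand <- merge(qk$kmers, index, by = "kmer", allow.cartesian = TRUE)
  if (!nrow(cand)) return(hit_table())
  cand[, diag := spos - qpos]
  cand <- unique(cand[, list(read_idx, frame, prot_idx, diag)])

  aa <- qk$frames[cbind(cand$read_idx, cand$frame)]
  pseq <- prot$sequence[cand$prot_idx]
  Lq <- nchar(aa)
  Lp <- prot$aa_length[cand$prot_idx]
  qa <- pmax(1L, 1L - cand$diag)
  qb <- pmin(Lq, Lp - cand$diag)
  aligned <- qb - qa + 1L
  qs <- substr(aa, qa, qb)
  ps <- substr(pseq, qa + cand$diag, qb + cand$diag)
  matched <- mapply(function(a, b) sum(charToRaw(a) == charToRaw(b)),
                    qs, ps, USE.NAMES = FALSE)

  res <- data.table::data.table(
    read_idx = cand$read_idx,
    protein_id = prot$protein_id[cand$prot_idx],
    pct_identity = 100 * matched / aligned,
    aln_length = aligned,
    bit_score = 2 * matched,
    e_value = 10^(-matched / 2))
  data.table::setorder(res, read_idx, -bit_score, e_value, protein_id)
  best <- res[!duplicated(res$read_idx)]
  hit_table(read_id = names(reads)[best$read_idx],
            protein_id = best$protein_id,
            pct_identity = best$pct_identity,
            aln_length = best$aln_length,
            bit_score = best$bit_score,
            e_value = best$e_value)
}

# k-mer index over protein sequences: one row per (kmer, protein, position)
.protein_kmer_index <- function(sequences, k) {
  lens <- nchar(sequences)
  npos <- pmax(0L, lens - k + 1L)
  prot_idx <- rep(seq_along(sequences), npos)
  spos <- unlist(lapply(npos, seq_len), use.names = FALSE)
  data.table::data.table(
    kmer = substring(sequences[prot_idx], spos, spos + k - 1L),
    prot_idx = prot_idx, spos = spos)
}

# translate reads in 6 frames and enumerate query k-mers
.read_frame_kmers <- function(reads, k) {
  n <- length(reads)
  rc <- .revcomp(unname(reads))
  frames <- matrix("", n, 6L)
  src <- list(unname(reads), rc)
  for (s in 1:2) {
    for (off in 0:2) {
      x <- substring(src[[s]], 1L + off)
      w <- nchar(x) - nchar(x) %% 3L
      x <- substring(x, 1L, w)
      tr <- character(n)
      ok <- w >= 3L
      if (any(ok)) tr[ok] <- .translate_chr(x[ok])
      frames[, (s - 1L) * 3L + off + 1L] <- tr
    }
  }
  flens <- nchar(frames)
  maxp <- max(0L, max(flens) - k + 1L)
  parts <- vector("list", 6L * max(maxp, 0L))
  pi <- 0L
  for (f in 1:6) {
    lim <- flens[, f] - k + 1L
    p_max <- max(0L, max(lim))
    for (p in seq_len(p_max)) {
      idx <- which(lim >= p)
      if (!length(idx)) next
      pi <- pi + 1L
      parts[[pi]] <- data.table::data.table(
        kmer = substring(frames[idx, f], p, p + k - 1L),
        read_idx = idx, frame = f, qpos = p)
    }
  }
  kmers <- if (pi) data.table::rbindlist(parts[seq_len(pi)])
           else data.table::data.table(kmer = character(), read_idx = integer(),
                                       frame = integer(), qpos = integer())
  list(frames = frames, kmers = kmers)
}
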