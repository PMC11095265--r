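#' Default synthetic gene-family names
#'
#' `flagellar_gene_families()` returns 21 flagellar-assembly family names
#' (basal body, rod, hook, rotor, M-ring, export apparatus and flagellins)
#' used as the default predictor panel of the synthetic reference;
#' `marker_gene_families()` returns 120 generic single-copy marker family
#' names emulating the bac120 normalization set. Both are overridable in
#' [genome_config()].
#'
#' @return character vector of gene family names.
#' @export
flagellar_gene_families <- function() {
  c("FlaE", "FliL", "Flg_bbr_C", "Flg_bb_rod", "FliG_C", "FlgD", "Flg_hook",
    "FliD_C", "FliE", "YscJ_FliF_C", "Flagellin_N", "Flagellin_C", "FliP",
    "FliQ", "FliR", "FlhA", "FlhB", "FliH", "FliI", "FliM", "FliN")
}

#' @rdname flagellar_gene_families
#' @export
marker_gene_families <- function() {
  sprintf("bac120_m%03d", seq_len(120L))
}

#' Configuration for synthetic genome generation
#'
#' @param motile logical; motile genomes carry the flagellar families,
#'   nonmotile genomes do not (subject to the noise rates below).
#' @param flagellar_genes,marker_genes gene family name vectors.
#' @param gene_length_range nucleotide gene length range (uniform draw,
#'   rounded to codons); default 300-1800 nt, shared by marker and
#'   flagellar families so RPK medians are comparable.
#' @param intergenic_fraction fraction of the genome occupied by random
#'   intergenic sequence (default 0.05).
#' @param genome_length optional fixed genome length; an error if the
#'   requested genes do not fit.
#' @param flagellar_dropout probability a motile genome lacks a given
#'   flagellar family (default 0).
#' @param contamination probability a nonmotile genome carries a given
#'   flagellar family (default 0).
#' @return a `genome_config` list.
#' @export
genome_config <- function(motile,
                          flagellar_genes = flagellar_gene_families(),
                          marker_genes = marker_gene_families(),
                          gene_length_range = c(300L, 1800L),
                          intergenic_fraction = 0.05,
                          genome_length = NULL,
                          flagellar_dropout = 0,
                          contamination = 0) {
  stopifnot(is.logical(motile), length(motile) == 1L,
            length(gene_length_range) == 2L,
            gene_length_range[1] >= 3, intergenic_fraction >= 0,
            flagellar_dropout >= 0, flagellar_dropout <= 1,
            contamination >= 0, contamination <= 1)
  structure(list(motile = motile, flagellar_genes = flagellar_genes,
                 marker_genes = marker_genes,
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_fraction = intergenic_fraction,
                 genome_length = genome_length,
                 flagellar_dropout = flagellar_dropout,
                 contamination = contamination),
            class = "genome_config")
}

.SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.random_gene <- function(len_nt) {
  n_codons <- max(2L, round(len_nt / 3))
  paste0(sample(.SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

.random_dna <- function(n) {
  if (n <= 0) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.translate_chr <- function(x) {
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(x),
                          if.fuzzy.codon = "X")))
}

#' Generate one synthetic genome
#'
#' Builds a genome carrying each of the 120 marker families exactly once and
#' the flagellar families iff `config$motile` (subject to the dropout and
#' contamination rates). Genes are random sense-codon sequences placed
#' without overlap on random strands, separated by random intergenic DNA.
#' Emitted protein sequences are the translations of the embedded genes.
#' Coordinates are 0-based half-open. Byte-identical output under a fixed
#' seed.
#'
#' @param genome_id genome identifier.
#' @param config a [genome_config()].
#' @param seed integer seed.
#' @return a `synthetic_genome`: list with `genome_id`, `length_bp`,
#'   `motile`, `sequence`, `features` (data frame `gene_id`, `start`, `end`,
#'   `strand`, `protein_id`) and `proteins` (named amino-acid vector).
#' @export
generate_genome <- function(genome_id, config, seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  set.seed(seed)
  genes <- config$marker_genes
  if (config$motile) {
    keep <- runif(length(config$flagellar_genes)) >= config$flagellar_dropout
    genes <- c(genes, config$flagellar_genes[keep])
  } else if (config$contamination > 0) {
    keep <- runif(length(config$flagellar_genes)) < config$contamination
    genes <- c(genes, config$flagellar_genes[keep])
  }
  lens <- round(runif(length(genes), config$gene_length_range[1],
                      config$gene_length_range[2]) / 3) * 3
  seqs <- vapply(lens, .random_gene, character(1))
  lens <- nchar(seqs)
  order_idx <- sample(length(genes))
  genes <- genes[order_idx]; seqs <- seqs[order_idx]; lens <- lens[order_idx]
  total_gene <- sum(lens)
  if (!is.null(config$genome_length)) {
    if (total_gene > config$genome_length) {
      stop("requested genes (", total_gene, " bp) exceed genome length ",
           config$genome_length)
    }
    slack <- config$genome_length - total_gene
  } else {
    slack <- round(total_gene * config$intergenic_fraction /
                   max(1e-9, 1 - config$intergenic_fraction))
  }
  # split the intergenic slack across the n+1 gaps
  cuts <- sort(sample.int(slack + 1L, length(genes), replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts, slack))
  strand <- sample(c("+", "-"), length(genes), replace = TRUE)
  pieces <- character(2L * length(genes) + 1L)
  starts <- integer(length(genes))
  pos <- 0L
  for (i in seq_along(genes)) {
    pieces[2L * i - 1L] <- .random_dna(gaps[i])
    pos <- pos + gaps[i]
    starts[i] <- pos
    pieces[2L * i] <- if (strand[i] == "+") seqs[i] else .revcomp(seqs[i])
    pos <- pos + lens[i]
  }
  pieces[2L * length(genes) + 1L] <- .random_dna(gaps[length(gaps)])
  genome_seq <- paste0(pieces, collapse = "")
  protein_id <- sprintf("%s.%s", genes, genome_id)
  features <- data.frame(gene_id = genes, start = starts,
                         end = starts + lens, strand = strand,
                         protein_id = protein_id,
                         stringsAsFactors = FALSE)
  proteins <- setNames(.translate_chr(seqs), protein_id)
  structure(list(genome_id = genome_id, length_bp = nchar(genome_seq),
                 motile = config$motile, sequence = genome_seq,
                 features = features, proteins = proteins),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %d bp, %d genes, %s\n", x$genome_id,
              x$length_bp, nrow(x$features),
              if (x$motile) "motile" else "nonmotile"))
  invisible(x)
}

#' Generate a pool of synthetic genomes with its protein registry
#'
#' @param n_motile,n_nonmotile genome counts per class.
#' @param seed integer seed; each genome gets a sub-seed derived from it.
#' @param ... passed to [genome_config()] (except `motile`).
#' @return list with `genomes` (named list of `synthetic_genome`),
#'   `registry` (a [protein_registry()] over all emitted variants) and
#'   `phenotypes` (named label vector).
#' @export
generate_genome_pool <- function(n_motile, n_nonmotile, seed = 1L, ...) {
  stopifnot(n_motile >= 0, n_nonmotile >= 0, n_motile + n_nonmotile > 0)
  flags <- rep(c(TRUE, FALSE), c(n_motile, n_nonmotile))
  ids <- sprintf("%s%02d", ifelse(flags, "mot", "non"),
                 c(seq_len(n_motile), seq_len(n_nonmotile)))
  genomes <- lapply(seq_along(ids), function(i) {
    generate_genome(ids[i], genome_config(motile = flags[i], ...),
                    seed = seed * 1000L + i)
  })
  names(genomes) <- ids
  registry <- build_registry(genomes)
  list(genomes = genomes, registry = registry,
       phenotypes = setNames(ifelse(flags, "motile", "nonmotile"), ids))
}

#' Build a protein registry from synthetic genomes
#'
#' Each genome contributes one protein variant per gene family it carries;
#' roles are assigned from the default family lists (flagellar families,
#' marker families, anything else `"other"`).
#'
#' @param genomes list of `synthetic_genome` objects.
#' @param flagellar_genes,marker_genes family name vectors defining roles.
#' @return a [protein_registry()].
#' @export
build_registry <- function(genomes,
                           flagellar_genes = flagellar_gene_families(),
                           marker_genes = marker_gene_families()) {
  rows <- lapply(genomes, function(g) {
    data.frame(protein_id = g$features$protein_id,
               gene_id = g$features$gene_id,
               sequence = unname(g$proteins[g$features$protein_id]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  role <- ifelse(tab$gene_id %in% flagellar_genes, "flagellar",
                 ifelse(tab$gene_id %in% marker_genes, "marker", "other"))
  protein_registry(tab$protein_id, tab$gene_id, role, sequence = tab$sequence)
}

#' Specify a mock metagenome mixture
#'
#' @param genome_ids member genome ids.
#' @param abundances relative abundances, summing to 1 (default uniform).
#' @param coverage_fold fold coverage of the mixture: total read bases are
#'   `coverage_fold` times the summed member genome lengths (default 0.5).
#' @param read_length_bp read length (default 150).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer seed for read sampling.
#' @return a `mock_mixture` list.
#' @export
mock_mixture <- function(genome_ids, abundances = NULL, coverage_fold = 0.5,
                         read_length_bp = 150L, error_rate = 0, seed = 1L) {
  if (is.null(abundances)) abundances <- rep(1 / length(genome_ids), length(genome_ids))
  stopifnot(length(abundances) == length(genome_ids),
            all(abundances >= 0), error_rate >= 0, error_rate <= 1)
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  structure(list(genome_ids = as.character(genome_ids),
                 abundances = as.numeric(abundances),
                 coverage_fold = coverage_fold,
                 read_length_bp = as.integer(read_length_bp),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "mock_mixture")
}

#' Proportion of flagellated members of a mixture
#'
#' Abundance-weighted proportion of members whose genome is motile.
#'
#' @param mixture a [mock_mixture()].
#' @param genomes named list of `synthetic_genome` objects.
#' @return a fraction in `[0, 1]`.
#' @export
proportion_flagellated <- function(mixture, genomes) {
  motile <- vapply(genomes[mixture$genome_ids], `[[`, logical(1), "motile")
  sum(mixture$abundances[motile])
}

#' Simulate shotgun reads from a genome mixture
#'
#' Per member genome the read count is
#' `floor(abundance * total_mixture_length * coverage_fold / read_length)`,
#' so the total read bases equal `coverage_fold` times the mixture's genome
#' bases. Read start positions are uniform on the genome, each read is
#' reverse-complemented with probability 0.5, substitution errors are
#' applied at `error_rate`, and qualities are constant phred+33 `"I"`.
#' Reproducible under the mixture seed.
#'
#' @param mixture a [mock_mixture()].
#' @param genomes named list of `synthetic_genome` objects containing every
#'   member.
#' @return named character vector of reads (names
#'   `<genome_id>_r<k>`), with attribute `read_length`.
#' @export
simulate_reads <- function(mixture, genomes) {
  stopifnot(inherits(mixture, "mock_mixture"))
  if (mixture$coverage_fold <= 0) stop("coverage_fold must be > 0")
  missing <- setdiff(mixture$genome_ids, names(genomes))
  if (length(missing)) stop("missing genomes: ", paste(missing, collapse = ", "))
  rl <- mixture$read_length_bp
  lens <- vapply(genomes[mixture$genome_ids], `[[`, numeric(1), "length_bp")
  if (any(rl > lens)) stop("read_length exceeds a member genome length")
  total_len <- sum(lens)
  n_reads <- floor(mixture$abundances * total_len *
                   mixture$coverage_fold / rl)
  set.seed(mixture$seed)
  out <- vector("list", length(mixture$genome_ids))
  for (i in seq_along(mixture$genome_ids)) {
    gid <- mixture$genome_ids[i]
    n <- n_reads[i]
    if (n == 0) { out[[i]] <- character(0); next }
    g <- genomes[[gid]]
    starts <- sample.int(g$length_bp - rl + 1L, n, replace = TRUE)
    reads <- substring(g$sequence, starts, starts + rl - 1L)
    flip <- runif(n) < 0.5
    if (any(flip)) reads[flip] <- .revcomp(reads[flip])
    if (mixture$error_rate > 0) {
      reads <- .mutate_reads(reads, mixture$error_rate)
    }
    out[[i]] <- setNames(reads, sprintf("%s_r%06d", gid, seq_len(n)))
  }
  reads <- unlist(out)
  if (is.null(reads)) reads <- character(0)
  attr(reads, "read_length") <- rl
  reads
}

.mutate_reads <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (j in hit) {
      ch[j] <- sample(setdiff(bases, ch[j]), 1L)
    }
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a gradient of mock mixtures spanning 0-100% flagellated taxa
#'
#' Produces `n_points` mixtures whose flagellated proportions are evenly
#' spaced on `[0, 1]` (endpoints included). Within each mixture, abundance
#' `p` is split equally among the sampled motile members and `1 - p` among
#' the sampled nonmotile members; zero-weight members are dropped, so the
#' endpoint mixtures contain a single class.
#'
#' @param pool result of [generate_genome_pool()] (or a list with `genomes`).
#' @param n_points number of gradient points (default 14).
#' @param members_per_class genomes sampled per class per mixture (default:
#'   all available).
#' @param coverage_fold,read_length_bp,error_rate see [mock_mixture()].
#' @param seed integer seed (member draws and per-mixture read seeds).
#' @return a `gradient_design`: list of [mock_mixture()] with attribute
#'   `proportions`.
#' @export
build_gradient <- function(pool, n_points = 14L, members_per_class = NULL,
                           coverage_fold = 0.5, read_length_bp = 150L,
                           error_rate = 0, seed = 1L) {
  genomes <- pool$genomes
  motile_ids <- names(genomes)[vapply(genomes, `[[`, logical(1), "motile")]
  nonmotile_ids <- setdiff(names(genomes), motile_ids)
  if (!length(motile_ids) || !length(nonmotile_ids)) {
    stop("genome pool must contain both motile and nonmotile genomes")
  }
  if (n_points < 2L) stop("n_points must be >= 2")
  props <- seq(0, 1, length.out = n_points)
  set.seed(seed)
  mixtures <- lapply(seq_along(props), function(i) {
    p <- props[i]
    mo <- if (is.null(members_per_class)) motile_ids
          else sample(motile_ids, min(members_per_class, length(motile_ids)))
    no <- if (is.null(members_per_class)) nonmotile_ids
          else sample(nonmotile_ids, min(members_per_class, length(nonmotile_ids)))
    ids <- c(mo, no)
    ab <- c(rep(p / length(mo), length(mo)), rep((1 - p) / length(no), length(no)))
    keep <- ab > 0
    mock_mixture(ids[keep], ab[keep] / sum(ab[keep]),
                 coverage_fold = coverage_fold,
                 read_length_bp = read_length_bp, error_rate = error_rate,
                 seed = seed + i)
  })
  names(mixtures) <- sprintf("mix%02d", seq_along(props))
  structure(mixtures, proportions = props, class = "gradient_design")
}

#' Simulate a labelled gene presence/absence matrix
#'
#' Genome-tier synthetic data for the classifier: each genome draws a latent
#' carrier state (it resembles a flagellated taxon with probability
#' `prob_carrier`), then carries each panel gene independently with a
#' per-genome carriage probability drawn from `carriage_carrier` or
#' `carriage_noncarrier`. The phenotype label is the deterministic rule
#' "motile iff at least `rule_min_genes` of the panel genes are present",
#' mimicking the empirical pattern that motile taxa carry nearly the whole
#' flagellar-assembly repertoire while many nonmotile taxa retain a subset.
#'
#' @param n_genomes number of genomes.
#' @param genes panel gene names (default the 21 synthetic flagellar
#'   families).
#' @param rule_min_genes minimum panel genes for the motile label
#'   (default 15).
#' @param prob_carrier probability of the carrier latent state.
#' @param carriage_carrier,carriage_noncarrier ranges for the per-genome
#'   carriage probability under each latent state.
#' @param seed integer seed.
#' @return list with `matrix` (binary genomes x genes), `phenotypes`
#'   (named `motile`/`nonmotile` vector) and `rule_min_genes`.
#' @export
simulate_gene_content <- function(n_genomes, genes = flagellar_gene_families(),
                                  rule_min_genes = 15L, prob_carrier = 0.35,
                                  carriage_carrier = c(0.85, 0.98),
                                  carriage_noncarrier = c(0.05, 0.55),
                                  seed = 1L) {
  set.seed(seed)
  carrier <- rbinom(n_genomes, 1L, prob_carrier) == 1L
  q <- ifelse(carrier,
              runif(n_genomes, carriage_carrier[1], carriage_carrier[2]),
              runif(n_genomes, carriage_noncarrier[1], carriage_noncarrier[2]))
  m <- matrix(rbinom(n_genomes * length(genes), 1L, rep(q, length(genes))),
              n_genomes, length(genes),
              dimnames = list(sprintf("g%04d", seq_len(n_genomes)), genes))
  attr(m, "is_binary") <- TRUE
  y <- rowSums(m) >= rule_min_genes
  list(matrix = m,
       phenotypes = setNames(ifelse(y, "motile", "nonmotile"), rownames(m)),
       rule_min_genes = rule_min_genes)
}
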