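#' Sum of sister-clade trait differences
#'
#' The raw statistic behind the phylogenetic D index: tip trait values are
#' propagated to internal nodes by averaging daughter values (post-order),
#' and the statistic is the sum over internal nodes of the absolute
#' difference between the two daughter values. Polytomies are resolved to
#' binary with zero-length branches first. `X` may be a matrix to evaluate
#' many trait vectors (e.g. permutations) on the same tree at once.
#'
#' @param tree an `ape::phylo` tree.
#' @param X numeric vector (length = tips, in `tree$tip.label` order) or a
#'   tips x m matrix.
#' @return numeric vector of sister-difference sums, one per column of `X`.
#' @export
sister_diff_sum <- function(tree, X) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  nt <- length(tree$tip.label)
  stopifnot(nrow(X) == nt)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  vals <- matrix(0, nt + tree$Nnode, ncol(X))
  vals[seq_len(nt), ] <- X
  d <- numeric(ncol(X))
  kids <- split(po[, 2L], po[, 1L])
  for (p in unique(po[, 1L])) {
    k <- kids[[as.character(p)]]
    v1 <- vals[k[1L], ]; v2 <- vals[k[2L], ]
    d <- d + abs(v1 - v2)
    vals[p, ] <- (v1 + v2) / 2
  }
  d
}

#' Phylogenetic D statistic for a binary trait
#'
#' Computes the observed sister-clade difference sum of the binary trait and
#' scales it between two simulated expectations: a random null (trait values
#' permuted across tips) and a Brownian null (Brownian motion on the branch
#' lengths, thresholded so each simulation has exactly the observed number
#' of 1s). `D = (d_obs - mean_d_brownian) / (mean_d_random -
#' mean_d_brownian)`, so D near 0 indicates Brownian-like phylogenetic
#' conservatism and D near 1 a phylogenetically random trait. Two one-sided
#' empirical p-values are reported, each the fraction of null simulations
#' with a difference sum at or below the observed one.
#'
#' @param tree rooted `ape::phylo` tree with branch lengths, >= 4 tips.
#' @param traits named 0/1 vector covering every tip; both states must be
#'   present.
#' @param n_sims simulations per null (>= 100; default 1000).
#' @param seed integer seed.
#' @return a `d_result`: list with `D`, `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `p_random`, `p_brownian`, `n_sims`, `seed`.
#' @export
estimate_D <- function(tree, traits, n_sims = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (nt < 4L) stop("need >= 4 tips")
  if (n_sims < 100L) stop("n_sims must be >= 100")
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing)) {
    stop("tips without trait values: ", paste(head(missing), collapse = ", "))
  }
  x <- as.numeric(traits[tree$tip.label])
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1")
  n1 <- sum(x)
  if (n1 == 0L || n1 == nt) stop("trait is monovalent; both states required")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)

  d_obs <- sister_diff_sum(tree, x)

  set.seed(seed)
  perms <- replicate(n_sims, sample(x))
  d_rand <- sister_diff_sum(tree, perms)

  V <- ape::vcv(tree)
  R <- chol(V + diag(1e-10, nt))
  Z <- matrix(rnorm(nt * n_sims), nt, n_sims)
  B <- crossprod(R, Z) # tips x n_sims, covariance V
  Bbin <- apply(B, 2L, function(col) {
    as.numeric(col >= sort(col, decreasing = TRUE)[n1])
  })
  d_brown <- sister_diff_sum(tree, Bbin)

  mr <- mean(d_rand); mb <- mean(d_brown)
  structure(list(D = (d_obs - mb) / (mr - mb),
                 d_obs = d_obs,
                 mean_d_random = mr, mean_d_brownian = mb,
                 p_random = mean(d_rand <= d_obs),
                 p_brownian = mean(d_brown <= d_obs),
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("<d_result> D = %.4f (d_obs %.3f; random null %.3f, Brownian null %.3f)\n",
              x$D, x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("  p(random null <= obs) = %.4g, p(Brownian null <= obs) = %.4g (%d sims)\n",
              x$p_random, x$p_brownian, x$n_sims))
  invisible(x)
}

#' Trait conservation across taxonomic ranks
#'
#' For each rank, the mean of the sample standard deviations of the binary
#' trait within taxa of that rank; taxa represented by a single genome are
#' excluded. An SD near 0 at a rank means members of a taxon at that rank
#' nearly always share the trait state.
#'
#' @param taxonomy data frame with a `genome_id` column and one column per
#'   rank (default ranks `phylum`, `class`, `order`, `family`, `genus`);
#'   ranks absent from the table are skipped with a warning.
#' @param traits named 0/1 vector keyed by genome id.
#' @param ranks rank column names to use.
#' @return data frame with `rank`, `mean_sd`, `n_taxa` (multi-genome taxa
#'   used) and `n_genomes`.
#' @export
rank_conservation <- function(taxonomy, traits,
                              ranks = c("phylum", "class", "order",
                                        "family", "genus")) {
  stopifnot("genome_id" %in% names(taxonomy))
  tr <- traits[taxonomy$genome_id]
  if (anyNA(tr)) stop("genomes without trait values")
  rows <- lapply(ranks, function(rk) {
    if (!rk %in% names(taxonomy)) {
      warning("rank '", rk, "' absent from taxonomy; skipped")
      return(NULL)
    }
    groups <- split(as.numeric(tr), taxonomy[[rk]])
    groups <- groups[lengths(groups) >= 2L]
    if (!length(groups)) {
      return(data.frame(rank = rk, mean_sd = NA_real_, n_taxa = 0L,
                        n_genomes = 0L, stringsAsFactors = FALSE))
    }
    sds <- vapply(groups, sd, numeric(1))
    data.frame(rank = rk, mean_sd = mean(sds), n_taxa = length(groups),
               n_genomes = sum(lengths(groups)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-category enrichment between trait classes
#'
#' Compares the genome-size-corrected prevalence of each feature category
#' (e.g. COG functional categories) between two groups of genomes.
#' Per-genome prevalence is the category count divided by the genome's total
#' annotated genes; groups are compared per category with a two-sided
#' Mann-Whitney U test (exact where the sample permits) and Bonferroni
#' correction across categories. The effect is reported as the log2 ratio
#' of group mean prevalences (first group level over second); categories
#' absent from both groups have an undefined ratio and are reported with
#' `NA` statistics.
#'
#' @param feature_counts genomes x categories count matrix.
#' @param genome_sizes named vector of total annotated genes per genome.
#' @param groups named character/factor of group membership (two groups,
#'   each >= 2 genomes); the first level is the numerator of the ratio.
#' @param alpha significance level on the Bonferroni-adjusted p (default
#'   0.01).
#' @return data frame with `category`, `mean_prev_<group1>`,
#'   `mean_prev_<group2>`, `log2_ratio`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
group_enrichment <- function(feature_counts, genome_sizes, groups,
                             alpha = 0.01) {
  ids <- rownames(feature_counts)
  sizes <- genome_sizes[ids]
  if (anyNA(sizes)) stop("genome sizes missing for some genomes")
  g <- groups[ids]
  if (anyNA(g)) stop("group membership missing for some genomes")
  g <- factor(g)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("each group needs >= 2 genomes")
  prev <- sweep(feature_counts, 1L, sizes, "/")
  lv <- levels(g)
  a <- g == lv[1L]
  rows <- lapply(colnames(prev), function(cat) {
    pa <- prev[a, cat]; pb <- prev[!a, cat]
    ma <- mean(pa); mb <- mean(pb)
    if (ma == 0 && mb == 0) {
      return(data.frame(category = cat, mean_a = ma, mean_b = mb,
                        log2_ratio = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ratio <- log2(ma / mb)
    p <- if (identical(sort(unname(pa)), sort(unname(pb)))) {
      1   # identical distributions carry no evidence either way
    } else {
      suppressWarnings(wilcox.test(pa, pb, exact = NULL)$p.value)
    }
    if (is.nan(p)) p <- 1   # fully tied samples degenerate the approximation
    data.frame(category = cat, mean_a = ma, mean_b = mb, log2_ratio = ratio,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_prev_", lv)
  out$p_adjusted <- p.adjust(out$p_value, method = "bonferroni")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}
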