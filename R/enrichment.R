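#' Hypergeometric over-representation test
#'
#' One-sided test for over-representation of `set` among `hits`, both
#' intersected with `universe` first. The odds ratio comes from the 2x2
#' table, with a Haldane 0.5 correction applied only when some cell is zero.
#'
#' @param hits character vector of selected genes.
#' @param set character vector, the gene set.
#' @param universe background gene ids.
#' @return list: `odds_ratio`, `p_value`, `overlap`, `n_hits`, `n_set`,
#'   `n_universe`.
#' @export
hypergeom_enrich <- function(hits, set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- intersect(hits, universe)
  set <- intersect(set, universe)
  q <- length(intersect(hits, set))
  m <- length(set)
  n <- length(universe) - m
  k <- length(hits)
  p <- stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
  a <- q; b <- m - q; c_ <- k - q; d <- n - (k - q)
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  list(odds_ratio = (a * d) / (b * c_), p_value = p, overlap = q,
       n_hits = k, n_set = m, n_universe = length(universe))
}

#' Permutation fold-enrichment curve of a gene list in variance fractions
#'
#' At each of `n_cutoffs` quantile-spaced cutoffs of the per-gene variance
#' fractions for `variable`, computes the overlap between genes exceeding
#' the cutoff and the top eQTL gene list, and compares it to the mean
#' overlap across permutations of the variance fractions over genes:
#' `fold enrichment = overlap_observed / overlap_permuted`. The curve is
#' truncated at the first cutoff where `min_genes` or fewer genes pass.
#' Confidence bounds are permutation quantiles of the fold enrichment under
#' the permutation null.
#'
#' @param varfracs `fractions` data.frame from [partition_matrix()], or a
#'   named numeric vector of fractions.
#' @param variable column of `varfracs` to use (ignored for a vector).
#' @param top_genes gene ids of the eQTL list (smallest eQTL p-values).
#' @param n_top number of top genes used (list truncated to this length).
#' @param n_cutoffs number of cutoffs spanning the fraction range.
#' @param n_perm number of permutations.
#' @param min_genes curve truncation threshold (strictly more than
#'   `min_genes` genes must pass a cutoff).
#' @param ci confidence level of the permutation interval.
#' @param seed optional integer seed for the permutations.
#' @return data.frame of class `EnrichmentCurve`: cutoff, n_pass, observed,
#'   expected (mean permuted overlap), fold_enrichment, ci_lo, ci_hi.
#' @export
eqtl_fold_enrichment <- function(varfracs, variable = "donor", top_genes,
                                 n_top = 2000, n_cutoffs = 40,
                                 n_perm = 10000, min_genes = 100,
                                 ci = 0.90, seed = NULL) {
  if (is.data.frame(varfracs)) {
    x <- stats::setNames(varfracs[[variable]], varfracs$gene_id)
  } else {
    x <- varfracs
  }
  if (all(is.na(x))) stop("variance fractions are all NA")
  x <- x[!is.na(x)]
  if (n_perm < 100) warning("n_perm < 100; fold-enrichment CI is unstable")
  if (!is.null(seed)) set.seed(seed)
  top_genes <- utils::head(top_genes, n_top)
  dropped <- setdiff(top_genes, names(x))
  if (length(dropped)) {
    warning(length(dropped), " top genes absent from variance fractions")
    top_genes <- setdiff(top_genes, dropped)
  }
  topind <- names(x) %in% top_genes
  n <- length(x)

  cutoffs <- unname(stats::quantile(x, probs = seq(0, 1, length.out = n_cutoffs)))
  n_pass <- vapply(cutoffs, function(ct) sum(x > ct), integer(1))
  keep <- n_pass > min_genes
  if (any(!keep)) keep[which(!keep)[1]:n_cutoffs] <- FALSE  # truncate, don't resume
  cutoffs <- cutoffs[keep]
  n_pass <- n_pass[keep]
  if (!length(cutoffs)) stop("no cutoff leaves more than min_genes genes")
  observed <- vapply(cutoffs, function(ct) sum(topind & x > ct), numeric(1))

  # A permutation of the fractions over genes makes the pass set at each
  # cutoff a uniformly random subset of its observed size, so one shuffled
  # indicator + cumulative sum serves every cutoff of that permutation.
  perm_overlap <- matrix(0, n_perm, length(cutoffs))
  for (b in seq_len(n_perm)) {
    cs <- cumsum(sample(topind))
    perm_overlap[b, ] <- cs[n_pass]
  }
  expected <- colMeans(perm_overlap)
  fe <- observed / expected
  alpha <- (1 - ci) / 2
  fe_perm <- sweep(perm_overlap, 2, expected, `/`)
  ci_lo <- apply(fe_perm, 2, stats::quantile, probs = alpha)
  ci_hi <- apply(fe_perm, 2, stats::quantile, probs = 1 - alpha)

  out <- data.frame(cutoff = cutoffs, n_pass = n_pass, observed = observed,
                    expected = expected, fold_enrichment = fe,
                    ci_lo = ci_lo, ci_hi = ci_hi, row.names = NULL)
  class(out) <- c("EnrichmentCurve", class(out))
  out
}
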