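#' Concordance of differential expression between two result tables
#'
#' Spearman and Pearson correlation of the chosen statistic over the gene
#' intersection, with one-sided p-values (H1: correlation greater than
#' zero) from the t approximation.
#'
#' @param de_a,de_b `DEResult` data.frames (need `gene_id` and the
#'   statistic column).
#' @param stat "t" or "log2FC".
#' @return list of class `ConcordanceReport`: spearman, pearson,
#'   p_spearman, p_pearson, n_genes.
#' @export
concordance <- function(de_a, de_b, stat = c("t", "log2FC")) {
  stat <- match.arg(stat)
  shared <- intersect(de_a$gene_id, de_b$gene_id)
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  if (length(shared) < 100) warning("fewer than 100 shared genes")
  a <- de_a[[stat]][match(shared, de_a$gene_id)]
  b <- de_b[[stat]][match(shared, de_b$gene_id)]
  n <- length(shared)
  one_sided <- function(r) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    stats::pt(tt, n - 2, lower.tail = FALSE)
  }
  rs <- stats::cor(a, b, method = "spearman")
  rp <- stats::cor(a, b, method = "pearson")
  structure(list(spearman = rs, pearson = rp,
                 p_spearman = one_sided(rs), p_pearson = one_sided(rp),
                 n_genes = n),
            class = "ConcordanceReport")
}

#' Quantile normalization to the sorted-mean reference distribution
#'
#' After normalization every sample has the same sorted value vector (ties
#' receive the average of the interpolated reference values).
#'
#' @param x matrix, genes x samples.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(v) {
    stats::approx(seq_along(ref), ref,
                  xout = rank(v, ties.method = "average"))$y
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Category-summarized hierarchical clustering across studies
#'
#' Restricts all matrices to their common genes, quantile-normalizes the
#' merged samples, computes the pairwise sample distance `1 - Pearson
#' correlation`, summarizes it as the median distance between samples of
#' each pair of categories, and clusters the summary matrix with complete
#' linkage. The tree is also serialized as a Newick string.
#'
#' @param expr_list named list of expression matrices (genes x samples,
#'   log2 scale) from one or more studies.
#' @param categories character vector, one label per sample across the
#'   concatenated matrices (in list order).
#' @return list: `summary_dist` (category x category matrix), `hclust`,
#'   `newick`.
#' @export
category_summary_clustering <- function(expr_list, categories) {
  if (is.matrix(expr_list)) expr_list <- list(expr_list)
  shared <- Reduce(intersect, lapply(expr_list, rownames))
  if (length(shared) < 2) stop("fewer than 2 genes shared across matrices")
  merged <- do.call(cbind, lapply(expr_list, function(m) m[shared, , drop = FALSE]))
  if (length(categories) != ncol(merged)) {
    stop("one category label per sample required")
  }
  if (any(table(categories) < 1)) stop("empty category")
  merged <- quantile_normalize(merged)
  d <- 1 - stats::cor(merged)
  cats <- unique(categories)
  s <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_along(cats)) {
    for (j in seq_len(i)) {
      di <- d[categories == cats[i], categories == cats[j], drop = FALSE]
      if (i == j) {
        v <- di[lower.tri(di)]
        s[i, j] <- if (length(v)) stats::median(v) else 0
      } else {
        s[i, j] <- s[j, i] <- stats::median(di)
      }
    }
  }
  diag(s) <- 0
  hc <- stats::hclust(stats::as.dist(s), method = "complete")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(summary_dist = s, hclust = hc, newick = newick)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds samples with classical metric scaling of a distance matrix; an
#' expression matrix is first converted to the `1 - Pearson correlation`
#' sample distance. Delegates the double-centering eigen-decomposition to
#' `stats::cmdscale`; coordinates are deterministic up to sign.
#'
#' @param x distance matrix (symmetric, zero diagonal), `dist` object, or
#'   expression matrix (genes x samples).
#' @param k number of dimensions.
#' @return sample x k coordinate matrix.
#' @export
classical_mds <- function(x, k = 2) {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    x <- as.matrix(x)
    if (isSymmetric(unname(x)) && all(abs(diag(x)) < 1e-12)) {
      d <- stats::as.dist(x)
    } else {
      d <- stats::as.dist(1 - stats::cor(x))
    }
  }
  mds <- stats::cmdscale(d, k = min(k, attr(d, "Size") - 1), eig = TRUE)
  pos <- sum(mds$eig > 1e-8)
  if (pos < k) {
    warning("only ", pos, " positive eigenvalues; returning ", pos,
            " dimensions")
    mds$points <- mds$points[, seq_len(max(pos, 1)), drop = FALSE]
  }
  mds$points
}
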