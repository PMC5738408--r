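#' Select marker genes for a signature panel
#'
#' Top genes per reference profile ranked by linear-scale fold over the mean
#' of the other profiles.
#'
#' @param panel `SignaturePanel`.
#' @param n_markers markers per profile.
#' @return character vector of marker gene ids (union over profiles).
#' @export
panel_markers <- function(panel, n_markers = 50) {
  sig <- panel$profiles
  p <- ncol(sig)
  unique(unlist(lapply(seq_len(p), function(j) {
    other <- rowMeans(sig[, -j, drop = FALSE])
    fold <- (sig[, j] + 1) / (other + 1)
    rownames(sig)[order(fold, decreasing = TRUE)[seq_len(n_markers)]]
  })))
}

#' Cell-type composition scores by non-negative least squares
#'
#' Each sample's linear-scale expression over the panel's marker genes is
#' regressed on the reference profiles under non-negativity constraints;
#' genes are weighted by the inverse of their expression s.d. across
#' profiles (so that every gene contributes comparably); profile
#' coefficients are summed within cell types and renormalized to sum 1.
#' Scores are comparative composition scores, not absolute percentages: the
#' scale is deliberately ignored, and the final renormalization makes them
#' invariant to rescaling a sample's expression.
#'
#' @param norm `NormalizedMatrix`, or log2-scale matrix, of expression.
#' @param panel `SignaturePanel`.
#' @param n_markers marker genes per profile used in the fit.
#' @return object of class `CTCScores`: sample x cell-type matrix, rows
#'   summing to 1. Attribute `n_genes_used` records the fit size.
#' @export
ctc_scores <- function(norm, panel, n_markers = 50) {
  x <- 2^as_log2cpm(norm)
  markers <- panel_markers(panel, n_markers)
  genes <- intersect(markers, rownames(x))
  if (!length(genes)) stop("no shared genes between panel and matrix")
  if (length(genes) < 100) {
    warning("only ", length(genes), " shared signature genes")
  }
  sig <- panel$profiles[genes, , drop = FALSE]
  sds <- apply(sig, 1, stats::sd)
  keep <- sds > 0
  sig <- sig[keep, , drop = FALSE] / sds[keep]
  y <- x[genes, , drop = FALSE][keep, , drop = FALSE] / sds[keep]

  coefs <- apply(y, 2, function(v) {
    if (all(v == 0)) stop("all-zero sample in deconvolution input")
    pracma::lsqnonneg(sig, v)$x
  })
  rownames(coefs) <- colnames(sig)
  scores <- collapse_columns(t(coefs), panel$map)
  tot <- rowSums(scores)
  if (any(tot == 0)) {
    warning("sample(s) with all-zero composition scores: ",
            paste(rownames(scores)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  scores <- scores / tot
  structure(scores, class = c("CTCScores", class(scores)),
            n_genes_used = sum(keep))
}

#' Residualize expression on covariates
#'
#' Per-gene ordinary least squares on an intercept plus the supplied
#' covariates; returns the residual matrix. Residuals are orthogonal to
#' every covariate column.
#'
#' @param norm `NormalizedMatrix` or expression matrix (genes x samples).
#' @param covariates data.frame or matrix, one row per sample (in the
#'   matrix's column order): e.g. selected CTC score columns.
#' @return residual matrix, genes x samples.
#' @export
residualize <- function(norm, covariates) {
  x <- as_log2cpm(norm)
  cv <- as.matrix(as.data.frame(covariates))
  if (nrow(cv) != ncol(x)) stop("covariate rows must match samples")
  design <- cbind(`(Intercept)` = 1, cv)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  t(qr.resid(qrd, t(x)))
}

#' Screen composition scores against expression principal components
#'
#' Pearson correlation of every composition score with the first `n_pcs`
#' principal components of each supplied expression matrix, with a
#' Bonferroni cutoff over the whole family
#' (`n_scores * n_pcs * n_matrices` tests).
#'
#' @param scores `CTCScores` or sample x score matrix.
#' @param expr_matrices named list of `NormalizedMatrix`/matrices sharing
#'   samples with `scores`.
#' @param n_pcs number of leading PCs per matrix.
#' @param alpha familywise significance level.
#' @return data.frame: matrix, pc, score, correlation, p_value, significant;
#'   attribute `family_size`.
#' @export
score_pc_screen <- function(scores, expr_matrices, n_pcs = 2, alpha = 0.05) {
  scores <- unclass(scores)
  if (is.null(names(expr_matrices))) {
    names(expr_matrices) <- paste0("matrix", seq_along(expr_matrices))
  }
  family <- ncol(scores) * n_pcs * length(expr_matrices)
  rows <- list()
  for (mn in names(expr_matrices)) {
    x <- as_log2cpm(expr_matrices[[mn]])
    shared <- intersect(colnames(x), rownames(scores))
    if (length(shared) <= n_pcs) stop("fewer samples than requested PCs")
    # PCs of centered (not scaled) expression, samples as observations
    pcs <- stats::prcomp(t(x[, shared, drop = FALSE]), center = TRUE,
                         scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
    for (k in seq_len(n_pcs)) {
      for (sc in colnames(scores)) {
        ct <- stats::cor.test(scores[shared, sc], pcs[, k])
        rows[[length(rows) + 1]] <- data.frame(
          matrix = mn, pc = paste0("PC", k), score = sc,
          correlation = unname(ct$estimate), p_value = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha / family
  attr(out, "family_size") <- family
  out
}
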