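#' Partition one gene's expression variance
#'
#' Fits a linear mixed model with a random intercept per categorical
#' variable and fixed slopes for continuous variables (REML, variance
#' components constrained nonnegative). The fraction attributed to a random
#' effect is its variance component over the total; the fraction for a fixed
#' effect is the empirical variance of its fitted contribution `X_k b_k`
#' across samples over the total; the total is the sum of all components
#' plus the residual variance.
#'
#' @param y numeric expression vector (one gene).
#' @param metadata data.frame, one row per element of `y`.
#' @param categorical names of metadata columns modeled as random effects.
#' @param continuous names of metadata columns modeled as fixed effects.
#' @return named numeric vector of fractions (one per variable plus
#'   `residual`) summing to 1, or all-NA with attribute `reason` when the
#'   gene cannot be fit.
#' @export
partition_gene <- function(y, metadata,
                           categorical = c("cell_type", "donor"),
                           continuous = character(0)) {
  vars <- c(categorical, continuous)
  frac_na <- stats::setNames(rep(NA_real_, length(vars) + 1),
                             c(vars, "residual"))
  if (stats::var(y) < 1e-12) {
    attr(frac_na, "reason") <- "zero variance"
    return(frac_na)
  }
  for (v in categorical) {
    if (length(unique(metadata[[v]])) < 2) {
      stop("categorical variable '", v, "' has fewer than 2 levels")
    }
  }
  dat <- metadata[, vars, drop = FALSE]
  dat$.y <- y
  fml <- stats::as.formula(paste(
    ".y ~", paste(c("1", continuous,
                    sprintf("(1 | %s)", categorical)), collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.conv.grad = "ignore",
                   check.conv.hess = "ignore",
                   calc.derivs = FALSE)))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    attr(frac_na, "reason") <- conditionMessage(fit)
    return(frac_na)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  rand <- stats::setNames(vc$vcov[match(categorical, vc$grp)], categorical)
  resid_var <- vc$vcov[vc$grp == "Residual"]
  fixed <- numeric(0)
  if (length(continuous)) {
    beta <- lme4::fixef(fit)
    fixed <- vapply(continuous, function(v) {
      if (!v %in% names(beta)) return(0)
      stats::var(dat[[v]] * beta[[v]])
    }, numeric(1))
  }
  total <- sum(rand) + sum(fixed) + resid_var
  c(rand, fixed, residual = resid_var) / total
}

#' Partition expression variance for every gene
#'
#' Maps [partition_gene()] over the rows of an expression matrix and reports
#' per-variable medians. Genes with (near-)zero variance are skipped and
#' counted.
#'
#' @param norm `NormalizedMatrix` or expression matrix (genes x samples).
#' @param metadata data.frame with a `sample_id` column matching the matrix
#'   columns.
#' @inheritParams partition_gene
#' @return list with `fractions` (data.frame, one row per gene),
#'   `medians` (named vector over non-NA genes), `n_skipped`.
#' @export
partition_matrix <- function(norm, metadata,
                             categorical = c("cell_type", "donor"),
                             continuous = character(0)) {
  x <- as_log2cpm(norm)
  metadata <- metadata[match(colnames(x), metadata$sample_id), ]
  res <- t(apply(x, 1, partition_gene, metadata = metadata,
                 categorical = categorical, continuous = continuous))
  fractions <- data.frame(gene_id = rownames(x), res, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ok <- stats::complete.cases(res)
  medians <- apply(res[ok, , drop = FALSE], 2, stats::median)
  list(fractions = fractions, medians = medians, n_skipped = sum(!ok))
}

#' Compare a variable's variance fractions between two partitions
#'
#' One-sided paired Wilcoxon signed-rank test of whether the fractions for
#' `variable` are larger in `fracs_b` than in `fracs_a`, paired by gene.
#'
#' @param fracs_a,fracs_b `fractions` data.frames from [partition_matrix()]
#'   (or any data.frame with `gene_id` and the variable column) over the
#'   same gene set.
#' @param variable column to compare.
#' @return list with `p_value`, `median_difference` (b - a), `n_genes`.
#' @export
compare_partitions <- function(fracs_a, fracs_b, variable = "donor") {
  shared <- intersect(fracs_a$gene_id, fracs_b$gene_id)
  a <- fracs_a[[variable]][match(shared, fracs_a$gene_id)]
  b <- fracs_b[[variable]][match(shared, fracs_b$gene_id)]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 10) stop("fewer than 10 paired genes")
  wt <- suppressWarnings(
    stats::wilcox.test(b[ok], a[ok], paired = TRUE, alternative = "greater"))
  list(p_value = wt$p.value,
       median_difference = stats::median(b[ok] - a[ok]),
       n_genes = sum(ok))
}

#' Balanced one-way ANOVA intraclass correlation
#'
#' Method-of-moments estimator `(MSB - MSW) / (MSB + (k - 1) MSW)`,
#' truncated at 0; the closed-form oracle for a single balanced random
#' effect, against which the mixed-model partition is validated.
#'
#' @param y numeric vector.
#' @param group grouping factor (balanced).
#' @return scalar ICC estimate in `[0, 1]`.
#' @export
anova_icc <- function(y, group) {
  group <- factor(group)
  k <- length(y) / nlevels(group)
  if (abs(k - round(k)) > 1e-8) stop("anova_icc requires a balanced design")
  fit <- stats::aov(y ~ group)
  ms <- summary(fit)[[1]]$`Mean Sq`
  icc <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  max(icc, 0)
}
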