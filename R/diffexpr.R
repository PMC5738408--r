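#' Precision weights from the mean-variance trend
#'
#' Fits a per-gene linear model on log2-CPM, smooths the square-root
#' residual standard deviation against mean log2 count with a locally
#' weighted regression, and returns inverse predicted variances at each
#' observation's fitted log2 count. Counts with low expression, whose
#' log-scale variance is inflated, receive small weights.
#'
#' @param counts filtered gene x sample count matrix.
#' @param design model matrix (samples x coefficients).
#' @param span lowess span of the trend fit.
#' @return weight matrix, same dimensions as `counts`; strictly positive.
#' @export
precision_weights <- function(counts, design, span = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 10) stop("need at least 10 genes for a stable trend")
  lib <- colSums(counts)
  y <- log2(sweep(counts + 0.5, 2, lib + 1, `/`) * 1e6)
  fit <- stats::lm.fit(design, t(y))
  s <- sqrt(colSums(as.matrix(fit$residuals)^2) / fit$df.residual)
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(s)
  lo <- stats::lowess(sx, sy, f = span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_cpm <- t(design %*% fit$coefficients)     # genes x samples
  fitted_count <- sweep(fitted_cpm, 2, log2(lib + 1) - log2(1e6), `+`)
  w <- 1 / pmax(trend(fitted_count), 1e-4)^4
  dim(w) <- dim(counts)
  dimnames(w) <- dimnames(counts)
  w
}

# Unbalanced one-way ANOVA intra-block correlation of a residual vector.
block_icc <- function(r, block, n0) {
  gm <- tapply(r, block, mean)
  ni <- tabulate(block)
  m <- length(gm)
  ssb <- sum(ni * (gm - mean(r))^2)
  ssw <- sum((r - gm[block])^2)
  msb <- ssb / (m - 1)
  msw <- ssw / (length(r) - m)
  if (msw <= 0) return(0.999)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

#' Consensus intra-donor correlation
#'
#' Estimates, for every gene, the intra-block (donor) correlation of the
#' residuals from the fixed-effect design via a one-way random-effect
#' moment estimator, and pools the per-gene estimates with a trimmed mean
#' on the Fisher-z scale. The single consensus value feeds the
#' generalized-least-squares fit in [fit_de()].
#'
#' @param expr expression matrix (genes x samples), log2 scale, or
#'   `NormalizedMatrix`.
#' @param design model matrix.
#' @param block donor (block) identifier per sample.
#' @param trim trim fraction of the Fisher-z mean.
#' @return scalar consensus correlation in (-1, 1); 0 with a warning when
#'   no block has replicates.
#' @export
consensus_correlation <- function(expr, design, block, trim = 0.15) {
  x <- as_log2cpm(expr)
  block <- factor(block)
  ni <- tabulate(block)
  if (!any(ni >= 2)) {
    warning("no replicated blocks; consensus correlation set to 0")
    return(0)
  }
  if (sum(ni >= 2) < 2) warning("fewer than 2 replicated blocks")
  n <- ncol(x)
  m <- nlevels(block)
  n0 <- (n - sum(ni^2) / n) / (m - 1)
  res <- stats::lm.fit(design, t(x))$residuals
  iccs <- apply(res, 2, block_icc, block = block, n0 = n0)
  iccs <- pmin(pmax(iccs, -0.999), 0.999)
  tanh(mean(atanh(iccs), trim = trim))
}

#' Per-gene generalized least squares with intra-donor correlation
#'
#' Fits every gene by GLS under a block compound-symmetry correlation
#' `rho` within donors, optionally with per-observation precision weights.
#' With `rho = 0` and unit weights this reduces exactly to ordinary least
#' squares.
#'
#' @param expr expression matrix (genes x samples, log2 scale) or
#'   `NormalizedMatrix`.
#' @param design model matrix (samples x p), full rank.
#' @param contrast coefficient name, or numeric contrast vector of length p.
#' @param block donor ids per sample (NULL: independent samples).
#' @param rho intra-block correlation.
#' @param weights optional weight matrix from [precision_weights()].
#' @return data.frame: gene_id, log2FC, se, t (unmoderated), df, sigma,
#'   stdev_unscaled, avg_expr. Input for [ebayes_moderate()].
#' @export
fit_de <- function(expr, design, contrast, block = NULL, rho = 0,
                   weights = NULL) {
  x <- as_log2cpm(expr)
  design <- as.matrix(design)
  n <- ncol(x); p <- ncol(design)
  if (qr(design)$rank < p) stop("design is not full rank")
  if (is.character(contrast)) {
    cv <- as.numeric(colnames(design) == contrast)
    if (sum(cv) != 1) stop("contrast coefficient not found: ", contrast)
  } else {
    cv <- as.numeric(contrast)
    stopifnot(length(cv) == p)
  }
  if (abs(rho) > 0.99) {
    warning("rho near +/-1; shrunk to 0.99 to keep the covariance invertible")
    rho <- sign(rho) * 0.99
  }
  R <- diag(n)
  if (!is.null(block) && rho != 0) {
    same <- outer(block, block, `==`)
    R <- (1 - rho) * diag(n) + rho * same
  }
  U <- chol(R)                      # R = t(U) %*% U
  A <- backsolve(U, diag(n), transpose = TRUE)  # A = t(U)^{-1}, whitening

  if (is.null(weights)) {
    Xw <- A %*% design
    Yw <- A %*% t(x)
    fit <- stats::lm.fit(Xw, Yw)
    xtxi <- chol2inv(chol(crossprod(Xw)))
    u <- sqrt(drop(t(cv) %*% xtxi %*% cv))
    beta <- drop(cv %*% fit$coefficients)
    df <- fit$df.residual
    s2 <- colSums(as.matrix(fit$residuals)^2) / df
    df <- rep(df, nrow(x))
  } else {
    beta <- s2 <- u_all <- numeric(nrow(x))
    df <- integer(nrow(x))
    for (g in seq_len(nrow(x))) {
      sw <- sqrt(weights[g, ])
      Xw <- A %*% (design * sw)
      yw <- drop(A %*% (x[g, ] * sw))
      fg <- stats::lm.fit(Xw, yw)
      xtxi <- chol2inv(chol(crossprod(Xw)))
      beta[g] <- drop(cv %*% fg$coefficients)
      df[g] <- fg$df.residual
      s2[g] <- sum(fg$residuals^2) / fg$df.residual
      u_all[g] <- sqrt(drop(t(cv) %*% xtxi %*% cv))
    }
    u <- u_all
  }
  sigma <- sqrt(s2)
  se <- sigma * u
  data.frame(gene_id = rownames(x), log2FC = beta, se = se,
             t = beta / se, df = df, sigma = sigma,
             stdev_unscaled = rep_len(u, nrow(x)),
             avg_expr = rowMeans(x), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Solve trigamma(y) = x by Newton iteration on the monotone decreasing
# trigamma function.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates a scaled inverse-chi-square prior (d0, s0^2) for the residual
#' variances by moment matching on the log scale (Fisher-z/scaled-F
#' moments), shrinks each gene's variance toward the prior,
#' `s~^2 = (d0 s0^2 + df s^2) / (d0 + df)`, and recomputes t, p and the
#' standard error (`se = |log2FC / t|`) with `d0 + df` degrees of freedom.
#'
#' @param fit data.frame from [fit_de()].
#' @return `DEResult` data.frame: gene_id, log2FC, se, t, p_value, df_total,
#'   avg_expr; attributes `d0` and `s0_sq`.
#' @export
ebayes_moderate <- function(fit) {
  if (nrow(fit) < 10) stop("need at least 10 genes for moderation")
  s2 <- fit$sigma^2
  df <- fit$df
  ok <- s2 > 0 & df > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (!is.finite(evar) || evar <= 0) {
    # no excess spread beyond sampling noise: infinite prior df, and the
    # pooled (mean) variance is the natural point estimate
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, nrow(fit))
    df_total <- rep(Inf, nrow(fit))
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  t_mod <- fit$log2FC / (sqrt(s2_post) * fit$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  out <- data.frame(gene_id = fit$gene_id, log2FC = fit$log2FC,
                    se = sqrt(s2_post) * fit$stdev_unscaled,
                    t = t_mod, p_value = p, df_total = df_total,
                    avg_expr = fit$avg_expr, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("DEResult", class(out))
  out
}

#' Estimate the null proportion pi0 from a p-value distribution
#'
#' Storey's smoother: `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`
#' over a lambda grid, smoothed with a cubic smoothing spline and evaluated
#' at the largest lambda, clamped to (0, 1].
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda grid of tuning values.
#' @return scalar pi0 estimate.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  sp <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(sp, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up, or Storey q-values
#' `q_i = min_{j >= i} pi0 m p_(j) / j` with pi0 from [estimate_pi0()].
#'
#' @param p p-values (no NAs).
#' @param method "BH" or "qvalue".
#' @param lambda lambda grid for the pi0 estimate.
#' @return adjusted values in input order; for `qvalue` the estimate of the
#'   null proportion is attached as attribute `pi0`.
#' @export
fdr_adjust <- function(p, method = c("BH", "qvalue"),
                       lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1], no NAs")
  if (method == "BH") return(stats::p.adjust(p, method = "BH"))
  m <- length(p)
  pi0 <- estimate_pi0(p, lambda)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  attr(q, "pi0") <- pi0
  q
}
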