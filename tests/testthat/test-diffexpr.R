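test_that("precision weights track the mean-variance relation", {
  set.seed(40)
  G <- 500; n <- 30
  mu <- 2^runif(G, 1, 12)
  cts <- matrix(rnbinom(G * n, size = 5, mu = rep(mu, n)), G, n,
                dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  w <- precision_weights(cts, matrix(1, n, 1))
  expect_true(all(is.finite(w) & w > 0))
  # low counts are noisier on the log scale: weights grow with expression
  expect_gt(cor(rowMeans(w), mu, method = "spearman"), 0.8)
  # homoskedastic data: approximately constant weights
  Yh <- matrix(round(2^rnorm(200 * n, 10, 0.05)), 200, n,
               dimnames = list(paste0("h", 1:200), paste0("s", 1:n)))
  wh <- precision_weights(Yh, matrix(1, n, 1))
  expect_lt(sd(wh) / mean(wh), 0.2)
  expect_error(precision_weights(cts[1:5, ], matrix(1, n, 1)), "10")
})

test_that("precision weights agree with the reference voom trend", {
  skip_if_not_installed("limma")
  sc <- small_cohort()
  keep <- filter_genes(sc$sim$counts)
  cts <- sc$sim$counts[keep, ]
  design <- model.matrix(~ diagnosis, data = sc$sim$metadata)
  w <- precision_weights(cts, design)
  v <- limma::voom(cts, design)
  expect_gt(cor(as.vector(w), as.vector(v$weights)), 0.99)
})

test_that("consensus correlation recovers the intra-donor correlation", {
  gb <- gauss_blocks(800, 40, 2, rho = 0.4, seed = 41)
  rho_hat <- consensus_correlation(gb$y, gb$design, gb$donor)
  expect_lt(abs(rho_hat - 0.4), 0.08)
  # destroying the block structure kills the correlation
  set.seed(42)
  rho_shuf <- consensus_correlation(gb$y, gb$design, sample(gb$donor))
  expect_lt(abs(rho_shuf), 0.08)
  # all-singleton blocks: zero with a warning
  expect_warning(
    rho0 <- consensus_correlation(gb$y[, 1:20], gb$design[1:20, ],
                                  paste0("U", 1:20)),
    "replicated")
  expect_equal(rho0, 0)
})

test_that("consensus correlation is close to the reference implementation", {
  skip_if_not_installed("limma")
  skip_if_not_installed("statmod")
  gb <- gauss_blocks(400, 30, 3, rho = 0.3, seed = 43)
  mine <- consensus_correlation(gb$y, gb$design, gb$donor)
  ref <- limma::duplicateCorrelation(gb$y, gb$design,
                                     block = gb$donor)$consensus.correlation
  expect_lt(abs(mine - ref), 0.05)
})

test_that("GLS reduces to OLS and matches the matrix-algebra oracle", {
  gb <- gauss_blocks(50, 10, 2, rho = 0.5, seed = 44)
  # rho = 0, unit weights: exactly OLS
  fit0 <- fit_de(gb$y, gb$design, "case", block = gb$donor, rho = 0)
  ols <- lm.fit(gb$design, t(gb$y))
  expect_equal(fit0$log2FC, unname(ols$coefficients["case", ]),
               tolerance = 1e-12)
  # single-gene oracle: explicit inverse of the block covariance
  rho <- 0.3
  fit <- fit_de(gb$y[1, , drop = FALSE], gb$design, "case",
                block = gb$donor, rho = rho)
  same <- outer(gb$donor, gb$donor, `==`)
  V <- (1 - rho) * diag(20) + rho * same
  Vi <- solve(V)
  X <- gb$design
  xtvx_i <- solve(t(X) %*% Vi %*% X)
  beta <- xtvx_i %*% t(X) %*% Vi %*% gb$y[1, ]
  r <- gb$y[1, ] - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (20 - 2)
  expect_equal(fit$log2FC, unname(beta["case", 1]), tolerance = 1e-10)
  expect_equal(fit$se, unname(sqrt(s2 * xtvx_i[2, 2])), tolerance = 1e-10)
  # near-singular correlation is shrunk with a warning
  expect_warning(fit_de(gb$y[1:5, ], gb$design, "case",
                        block = gb$donor, rho = 0.999), "0.99")
})

test_that("blocking controls the type-I error that OLS inflates", {
  gb <- gauss_blocks(2000, 40, 2, rho = 0.3, seed = 45)
  rho_hat <- consensus_correlation(gb$y, gb$design, gb$donor)
  gls <- ebayes_moderate(fit_de(gb$y, gb$design, "case",
                                block = gb$donor, rho = rho_hat))
  ols <- ebayes_moderate(fit_de(gb$y, gb$design, "case"))
  expect_lt(abs(mean(gls$p_value < 0.05) - 0.05), 0.015)
  expect_gt(mean(ols$p_value < 0.05), 0.065)
})

test_that("moderation recovers prior parameters and bounds variances", {
  set.seed(46)
  G <- 5000; d0 <- 4; s0sq <- 2; df <- 10
  s2 <- s0sq * d0 / rchisq(G, d0)
  s2_obs <- s2 * rchisq(G, df) / df
  fit <- data.frame(gene_id = paste0("g", 1:G), log2FC = rnorm(G),
                    sigma = sqrt(s2_obs), df = df, stdev_unscaled = 0.2,
                    avg_expr = 5)
  mod <- ebayes_moderate(fit)
  expect_lt(abs(attr(mod, "d0") - d0), 1.5)
  expect_lt(abs(attr(mod, "s0_sq") - s0sq), 0.4)
  # posterior variance is a convex combination of s2_g and s0_sq
  s2_post <- (mod$se / fit$stdev_unscaled)^2
  lo <- pmin(s2_obs, attr(mod, "s0_sq"))
  hi <- pmax(s2_obs, attr(mod, "s0_sq"))
  expect_true(all(s2_post >= lo - 1e-10 & s2_post <= hi + 1e-10))
  # SE identity: se = |log2FC / t|
  nz <- mod$t != 0
  expect_equal(mod$se[nz], abs(mod$log2FC[nz] / mod$t[nz]), tolerance = 1e-12)
})

test_that("identical variances give the pooled-variance limit", {
  set.seed(47)
  fit <- data.frame(gene_id = paste0("g", 1:200), log2FC = rnorm(200),
                    sigma = 1.3, df = 8, stdev_unscaled = 0.3, avg_expr = 4)
  mod <- ebayes_moderate(fit)
  expect_true(is.infinite(attr(mod, "d0")))
  expect_equal(mod$t, fit$log2FC / (1.3 * 0.3), tolerance = 1e-6)
})

test_that("q-values are calibrated and dominated by BH via pi0", {
  set.seed(48)
  p_null <- runif(5000)
  q <- fdr_adjust(p_null, "qvalue")
  expect_lt(abs(attr(q, "pi0") - 1), 0.05)
  p_mix <- c(rbeta(1000, 0.1, 8), runif(4000))
  q_mix <- fdr_adjust(p_mix, "qvalue")
  expect_lt(abs(attr(q_mix, "pi0") - 0.8), 0.05)
  bh <- fdr_adjust(p_mix, "BH")
  expect_true(all(as.numeric(q_mix) <= bh + 1e-12))
  expect_true(all(q_mix >= attr(q_mix, "pi0") * bh - 1e-12))
  # both adjustments are monotone in p
  o <- order(p_mix)
  expect_true(all(diff(as.numeric(q_mix)[o]) >= -1e-12))
  expect_true(all(diff(bh[o]) >= -1e-12))
  expect_error(fdr_adjust(c(0.1, NA)), "NA")
})

test_that("with one sample per donor, blocking changes nothing", {
  gb <- gauss_blocks(100, 24, 1, rho = 0.4, seed = 49)
  rho_hat <- suppressWarnings(
    consensus_correlation(gb$y, gb$design, gb$donor))
  expect_equal(rho_hat, 0)
  with_block <- fit_de(gb$y, gb$design, "case", block = gb$donor,
                       rho = rho_hat)
  without <- fit_de(gb$y, gb$design, "case")
  expect_equal(with_block$log2FC, without$log2FC, tolerance = 1e-12)
  expect_equal(with_block$se, without$se, tolerance = 1e-12)
})
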