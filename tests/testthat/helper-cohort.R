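# Shared small fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default small cohort: 8+8 donors, 2 lines, both cell types, some DE signal.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- simulation_config(n_genes = 600, n_donors_case = 8,
                             n_donors_control = 8, lines_per_donor = 2,
                             icc_donor = 0.1, frac_de_genes = 0.1,
                             lfc_sd = 0.8, seed = 101)
    .fixtures$small <- list(cfg = cfg, sim = simulate_cohort(cfg))
  }
  .fixtures$small
}

# Gaussian repeated-measures matrix with known donor ICC on the residuals.
gauss_blocks <- function(n_genes, n_donors, k, rho, seed,
                         frac_case = 0.5) {
  set.seed(seed)
  n <- n_donors * k
  donor <- rep(sprintf("D%03d", seq_len(n_donors)), each = k)
  case <- rep(c(0, 1), c(ceiling(n_donors * (1 - frac_case)),
                         floor(n_donors * frac_case)))[
    rep(seq_len(n_donors), each = k)]
  d_eff <- matrix(rnorm(n_genes * n_donors, 0, sqrt(rho)), n_genes, n_donors)
  y <- d_eff[, rep(seq_len(n_donors), each = k), drop = FALSE] +
    matrix(rnorm(n_genes * n, 0, sqrt(1 - rho)), n_genes, n)
  rownames(y) <- sprintf("G%05d", seq_len(n_genes))
  colnames(y) <- sprintf("S%03d", seq_len(n))
  list(y = y, donor = donor,
       design = cbind(`(Intercept)` = 1, case = case))
}

# Block of genes sharing a latent factor (pairwise correlation ~ r).
correlated_block <- function(n_genes, n_samples, r, prefix = "b") {
  f <- rnorm(n_samples)
  y <- t(vapply(seq_len(n_genes), function(i) {
    sqrt(r) * f + sqrt(1 - r) * rnorm(n_samples)
  }, numeric(n_samples)))
  rownames(y) <- paste0(prefix, seq_len(n_genes))
  y
}
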