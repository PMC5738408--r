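test_that("gene filtering follows the CPM support rule", {
  # 10 samples, library size 1e6 each: counts of 2 give CPM exactly 2
  counts <- matrix(0, 3, 10,
                   dimnames = list(c("keep", "drop", "zero"), paste0("S", 1:10)))
  counts["keep", 1:3] <- 2
  counts["drop", 1:2] <- 2
  filler <- matrix(1, 1, 10, dimnames = list("filler", paste0("S", 1:10)))
  counts <- rbind(counts, filler * (1e6 - colSums(counts) - 1) + 0)
  counts["filler", ] <- 1e6 - colSums(counts[1:3, ])
  stopifnot(all(colSums(counts) == 1e6))
  kept <- filter_genes(counts, min_cpm = 1, min_frac = 0.30)
  expect_true("keep" %in% kept)        # 3/10 = 30%, tie counts as retained
  expect_false("drop" %in% kept)       # 2/10 = 20%
  expect_false("zero" %in% kept)       # all-zero gene removed
})

test_that("gene filtering is idempotent and flags zero libraries", {
  sc <- small_cohort()
  kept <- filter_genes(sc$sim$counts)
  kept2 <- filter_genes(sc$sim$counts[kept, , drop = FALSE])
  expect_identical(kept, kept2)
  bad <- sc$sim$counts
  bad[, 3] <- 0
  expect_error(filter_genes(bad), colnames(bad)[3])
})

test_that("TMM reproduces the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  counts <- matrix(rnbinom(2000 * 6, mu = 100, size = 2), 2000, 6,
                   dimnames = list(sprintf("G%04d", 1:2000), paste0("S", 1:6)))
  counts[1:200, 6] <- counts[1:200, 6] * 10
  mine <- tmm_normalize(counts)
  er <- edgeR::calcNormFactors(edgeR::DGEList(counts), method = "TMM")
  expect_equal(unname(mine$factors), er$samples$norm.factors,
               tolerance = 1e-10)
})

test_that("TMM factors behave under scaling and composition change", {
  set.seed(43)
  counts <- matrix(rnbinom(1500 * 5, mu = 50, size = 3), 1500, 5,
                   dimnames = list(sprintf("G%04d", 1:1500), paste0("S", 1:5)))
  # identical columns: all factors 1
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("T", 1:3)
  expect_equal(unname(tmm_normalize(same)$factors), rep(1, 3))
  # doubling every count is absorbed by the library size
  c2 <- counts
  c2[, 2] <- counts[, 1] * 2
  f2 <- tmm_normalize(c2)$factors
  expect_lt(abs(f2[[2]] / f2[[1]] - 1), 0.05)
  # global rescaling of all libraries leaves factors unchanged
  f_a <- tmm_normalize(counts)$factors
  f_b <- tmm_normalize(counts * 4)$factors
  expect_equal(f_a, f_b, tolerance = 1e-12)
  # a sample with 10% of genes at 10x is compositionally biased: factor < 1
  c3 <- counts
  c3[1:150, 5] <- c3[1:150, 5] * 10
  expect_lt(tmm_normalize(c3)$factors[[5]], 1)
  # factors positive with geometric mean 1
  expect_true(all(f_a > 0))
  expect_equal(exp(mean(log(f_a))), 1, tolerance = 1e-12)
})

test_that("sex is inferred from XIST and chrY expression", {
  sexg <- list(xist = "G00001", chry = paste0("G0000", 2:7))
  cfg <- simulation_config(n_genes = 400, sex_genes = sexg,
                           n_intermediate = 4, cell_types = "NPC", seed = 5)
  sim <- simulate_cohort(cfg)
  norm <- tmm_normalize(sim$counts)
  ann <- setNames(sim$metadata$sex, sim$metadata$sample_id)
  calls <- infer_sex(norm, sexg$xist, sexg$chry, annotated_sex = ann)
  truth <- sim$metadata$sex[match(calls$sample_id, sim$metadata$sample_id)]
  interm <- calls$sample_id %in% sim$truth$intermediate_samples
  expect_true(all(calls$call[interm] == "intermediate"))
  expect_true(all(calls$call[!interm] == truth[!interm]))
  expect_false(any(calls$mismatch))
  # a mislabeled male (annotated male, female pattern) is flagged
  fem <- setdiff(calls$sample_id[calls$call == "female"], character(0))[1]
  ann[fem] <- "male"
  calls2 <- infer_sex(norm, sexg$xist, sexg$chry, annotated_sex = ann)
  expect_true(calls2$mismatch[calls2$sample_id == fem])
  expect_error(infer_sex(norm, "NOT_A_GENE", sexg$chry), "NOT_A_GENE")
})

test_that("constructed extreme profiles get the expected sex call", {
  x <- matrix(0, 8, 2, dimnames = list(c("XIST", paste0("Y", 1:6), "AUT"),
                                       c("f", "m")))
  x["XIST", ] <- c(6, 0)
  x[paste0("Y", 1:6), ] <- rep(c(0, 5), each = 6)
  x["AUT", ] <- 5
  calls <- infer_sex(x, "XIST", paste0("Y", 1:6))
  expect_equal(calls$call, c("female", "male"))
})

test_that("CNV z-scores localize a deletion and behave under permutation", {
  cnv <- data.frame(donor = "D001", chrom = "autosome",
                    start = 100001, end = 200000, dosage = 0.5)
  cfg <- simulation_config(n_genes = 400, cnv_events = cnv, seed = 6)
  sim <- simulate_cohort(cfg)
  norm <- tmm_normalize(sim$counts)
  bed <- data.frame(chrom = "autosome", start = 100000, end = 200000,
                    name = "del1")
  z <- cnv_zscores(norm, sim$metadata, bed, sim$gene_coords)
  carrier <- sim$metadata$sample_id[sim$metadata$donor == "D001"]
  expect_lt(mean(z$z[z$sample_id %in% carrier]), -1)
  # per-gene z has mean 0, sd 1
  for (g in unique(z$gene_id)[1:3]) {
    zi <- z$z[z$gene_id == g]
    expect_equal(mean(zi), 0, tolerance = 1e-10)
    expect_equal(sd(zi), 1, tolerance = 1e-10)
  }
  # permuting sample columns permutes z identically
  perm <- sample(colnames(norm$log2cpm))
  normp <- norm
  normp$log2cpm <- norm$log2cpm[, perm]
  zp <- cnv_zscores(normp, sim$metadata, bed, sim$gene_coords)
  key <- paste(z$gene_id, z$sample_id)
  keyp <- paste(zp$gene_id, zp$sample_id)
  expect_equal(zp$z[match(key, keyp)], z$z, tolerance = 1e-12)
})

test_that("constant genes get z = 0 with a flag", {
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  x[2, ] <- 7
  md <- data.frame(sample_id = paste0("s", 1:10),
                   cell_type = rep(c("a", "b"), 5))
  coords <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                       start = (1:4) * 1000 + 1, end = (1:4) * 1000 + 500)
  bed <- data.frame(chrom = "chr1", start = 0, end = 10000, name = "r")
  z <- cnv_zscores(x, md, bed, coords)
  expect_true(all(z$z[z$gene_id == "g2"] == 0))
  expect_true(all(z$zero_variance[z$gene_id == "g2"]))
  expect_false(any(z$zero_variance[z$gene_id != "g2"]))
})
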