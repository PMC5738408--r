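test_that("soft adjacency follows the power rule", {
  set.seed(60)
  # two perfectly correlated genes
  f <- rnorm(20)
  x <- rbind(a = f, b = 2 * f + 3, c = rnorm(20))
  adj <- soft_adjacency(x, beta = 9)
  expect_equal(adj["a", "b"], 1, tolerance = 1e-12)
  expect_true(isSymmetric(adj))
  expect_true(all(adj >= 0 & adj <= 1))
  expect_equal(unname(diag(adj)), rep(1, 3))
  # cor 0.5 at beta 9 gives 0.5^9 exactly
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  x2 <- t(chol(r)) %*% matrix(rnorm(2 * 5000), 2, 5000)
  rownames(x2) <- c("p", "q")
  a2 <- soft_adjacency(x2, beta = 9)
  expect_equal(a2["p", "q"], abs(cor(x2["p", ], x2["q", ]))^9,
               tolerance = 1e-12)
  # raising beta weakly sparsifies the network
  a_lo <- soft_adjacency(x2, beta = 3)
  expect_true(all(a2 <= a_lo + 1e-12))
  # zero-variance genes are rejected
  x3 <- rbind(x, flat = rep(1, 20))
  expect_error(soft_adjacency(x3, 9), "flat")
})

test_that("TOM matches hand-computed values and the brute-force oracle", {
  # worked 3-gene examples
  a_ones <- matrix(1, 3, 3)
  expect_equal(topological_overlap(a_ones), matrix(1, 3, 3),
               ignore_attr = TRUE)
  a3 <- matrix(c(1, 0.5, 0.5,
                 0.5, 1, 0,
                 0.5, 0, 1), 3, 3)
  tom3 <- topological_overlap(a3)
  expect_equal(tom3[2, 3], 0.25 / 1.5, tolerance = 1e-12)
  # brute-force double-loop oracle on random 20-gene networks
  brute_tom <- function(a) {
    n <- nrow(a)
    k <- rowSums(a) - diag(a)
    out <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    out
  }
  set.seed(61)
  for (rep in 1:3) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- topological_overlap(a)
    expect_lt(max(abs(tom - brute_tom(a))), 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0))
  }
})

test_that("planted blocks become modules and noise stays grey", {
  set.seed(62)
  x <- rbind(correlated_block(50, 30, 0.9, "u"),
             correlated_block(50, 30, 0.9, "v"),
             matrix(rnorm(30 * 30), 30, 30,
                    dimnames = list(paste0("n", 1:30), NULL)))
  colnames(x) <- paste0("s", 1:30)
  tom <- topological_overlap(soft_adjacency(x, 9))
  mods <- detect_modules(tom, min_module_size = 20)
  lab <- mods$modules
  non_grey <- setdiff(unique(lab), "grey")
  expect_length(non_grey, 2)
  # each planted block is recovered intact in a single module
  expect_length(unique(lab[paste0("u", 1:50)]), 1)
  expect_length(unique(lab[paste0("v", 1:50)]), 1)
  expect_false(unique(lab[paste0("u", 1:50)]) ==
                 unique(lab[paste0("v", 1:50)]))
  # largest module takes the first color in the conventional order
  expect_true("turquoise" %in% non_grey)
  # gene order does not change the assignment
  perm <- sample(nrow(tom))
  mods_p <- detect_modules(tom[perm, perm], min_module_size = 20)
  expect_equal(mods_p$modules[names(lab)], lab)
})

test_that("independent genes and undersized blocks go grey", {
  set.seed(63)
  xn <- matrix(rnorm(100 * 30), 100, 30,
               dimnames = list(paste0("n", 1:100), paste0("s", 1:30)))
  tn <- topological_overlap(soft_adjacency(xn, 9))
  expect_warning(mn <- detect_modules(tn, min_module_size = 20), "grey")
  expect_true(all(mn$modules == "grey"))
  # a correlated block smaller than min_module_size is not a module
  xs <- rbind(correlated_block(10, 30, 0.9, "t"),
              matrix(rnorm(60 * 30), 60, 30,
                     dimnames = list(paste0("n", 1:60), NULL)))
  colnames(xs) <- paste0("s", 1:30)
  ts_ <- topological_overlap(soft_adjacency(xs, 9))
  ms <- suppressWarnings(detect_modules(ts_, min_module_size = 20))
  expect_true(all(ms$modules[paste0("t", 1:10)] == "grey"))
})

test_that("module enrichment flags the matching set and includes grey", {
  set.seed(64)
  x <- rbind(correlated_block(40, 25, 0.9, "u"),
             matrix(rnorm(30 * 25), 30, 25,
                    dimnames = list(paste0("n", 1:30), NULL)))
  colnames(x) <- paste0("s", 1:25)
  tom <- topological_overlap(soft_adjacency(x, 9))
  mods <- detect_modules(tom, min_module_size = 20)
  block_mod <- unique(mods$modules[paste0("u", 1:40)])
  expect_length(block_mod, 1)
  sets <- list(block = paste0("u", 1:40), rand = sample(rownames(x), 20))
  enr <- module_enrichment(mods, sets)
  expect_equal(attr(enr, "family_size"),
               length(unique(mods$modules)) * 2)
  # grey is tested too
  expect_true("grey" %in% enr$module)
  hit <- enr[enr$module == block_mod & enr$set == "block", ]
  expect_equal(hit$p_value, min(enr$p_value))
  expect_true(hit$significant)
})
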