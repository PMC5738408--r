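#!/usr/bin/env Rscript
# Cell-type-composition scoring of every sample against the reference
# signature panel, accuracy against the simulated mixing truth, the
# score-vs-principal-component screen, and residualization on the two
# fibroblast-like scores.

suppressMessages(library(ipscvar))
obj <- readRDS("results/cohort/cohort.rds")
norm <- readRDS("results/norm.rds")
sim <- obj$sim

sc <- ctc_scores(norm, obj$panel)
write_matrix_tsv(unclass(sc), "results/ctc_scores.tsv",
                 id_name = "sample_id")
truth <- sim$truth$mixing_cell_types[rownames(sc), colnames(sc)]
cat("CTC scores: MAE vs true mixing =",
    round(mean(abs(unclass(sc) - truth)), 3), "\n")

npc <- sim$metadata$sample_id[sim$metadata$cell_type == "NPC"]
neu <- sim$metadata$sample_id[sim$metadata$cell_type == "neuron"]
screen <- score_pc_screen(
  sc, list(all = norm$log2cpm,
           NPC = norm$log2cpm[, npc],
           neuron = norm$log2cpm[, neu]), n_pcs = 2)
write.table(screen, "results/score_pc_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("score-PC screen:", attr(screen, "family_size"), "tests,",
    sum(screen$significant), "pass the Bonferroni cutoff\n")

fib <- intersect(c("fibroblast_1", "fibroblast_2"), colnames(sc))
res <- residualize(norm, unclass(sc)[colnames(norm$log2cpm), fib])
write_matrix_tsv(res, "results/residual_expression.tsv")
pc_share <- function(x) {
  p <- prcomp(t(x), center = TRUE)
  100 * p$sdev[1]^2 / sum(p$sdev^2)
}
cat("PC1 variance share: raw", round(pc_share(norm$log2cpm), 1),
    "% -> residualized", round(pc_share(res), 1), "%\n")
saveRDS(sc, "results/ctc_scores.rds")
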