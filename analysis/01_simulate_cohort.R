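#!/usr/bin/env Rscript
# Build the synthetic study cohort used by the downstream analysis scripts:
# 11 case + 11 control donors, 2 clonal lines each, NPC and neuron cultures
# (88 samples), donor effect 2.2%, a small set of true diagnosis effects,
# sex-chromosome signatures, one embedded heterozygous deletion, and a
# handful of donors with residual reprogramming-vector (sendai) expression.

suppressMessages(library(ipscvar))

seed <- 20260930L
panel <- simulate_signature_panel(n_genes = 2000, seed = seed)
sex_genes <- list(xist = "G00001", chry = paste0("G0000", 2:7))
cnv <- data.frame(donor = "D003", chrom = "autosome",
                  start = 500001, end = 700000, dosage = 0.5)

cfg <- simulation_config(
  n_genes = 2000, n_donors_case = 11, n_donors_control = 11,
  lines_per_donor = 2, cell_types = c("NPC", "neuron"),
  icc_donor = 0.022, frac_de_genes = 0.05, lfc_sd = 0.5,
  signature = panel, sex_genes = sex_genes, cnv_events = cnv,
  sendai_donors = c("D005", "D012", "D019"), sendai_effect_sd = 0.3,
  n_intermediate = 6, seed = seed)

sim <- simulate_cohort(cfg)
dir.create("results", showWarnings = FALSE)
write_cohort(sim, "results/cohort")
saveRDS(list(cfg = cfg, sim = sim, panel = panel),
        "results/cohort/cohort.rds")

cat("cohort:", nrow(sim$metadata), "samples,",
    length(unique(sim$metadata$donor)), "donors,",
    nrow(sim$counts), "genes\n")
cat("true DE genes:", sum(sim$truth$de_gene),
    "| eQTL genes:", sum(sim$truth$eqtl_gene), "\n")
cat("written to results/cohort/\n")
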