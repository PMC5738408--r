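#' Run the full analysis workflow on a cohort
#'
#' Chains the stages in dependency order: filtering and TMM normalization,
#' sex inference, composition scoring and residualization, variance
#' partitioning, eQTL fold enrichment, repeated-measures differential
#' expression, coexpression modules, and the effective-sample-size design
#' report. Every enabled stage writes a TSV under `out_dir`, and a manifest
#' records parameters, seed and input checksums; identical inputs and seed
#' give identical outputs.
#'
#' @param counts gene x sample count matrix, or path to a counts TSV.
#' @param metadata sample metadata data.frame (sample_id, donor, cell_type,
#'   diagnosis, sex, ...), or path to a TSV.
#' @param out_dir output directory.
#' @param signature optional `SignaturePanel` for composition scoring.
#' @param eqtl_genes optional gene-id vector for the enrichment curve.
#' @param gene_sets optional named list of gene sets for module enrichment.
#' @param stages character vector of stages to run, a subset of
#'   `c("qc", "deconvolution", "varpart", "enrichment", "de",
#'   "coexpression", "design")`.
#' @param params named list overriding defaults: min_cpm (1), min_frac
#'   (0.30), beta (9), min_module_size (20), n_top (2000), n_perm (10000),
#'   n_cutoffs (40), min_genes (100), fdr_cutoffs (0.10, 0.30),
#'   n_coexpr_genes (1500), cost_donor (1), alpha_line (0.5), budget (30).
#' @param seed integer seed for the permutation stages.
#' @return named list of in-memory stage results, invisibly; side effect:
#'   TSV artifacts plus `manifest.txt` under `out_dir`.
#' @export
run_pipeline <- function(counts, metadata, out_dir,
                         signature = NULL, eqtl_genes = NULL,
                         gene_sets = NULL,
                         stages = c("qc", "deconvolution", "varpart",
                                    "enrichment", "de", "coexpression",
                                    "design"),
                         params = list(), seed = 1L) {
  defaults <- list(min_cpm = 1, min_frac = 0.30, beta = 9,
                   min_module_size = 20, n_top = 2000, n_perm = 10000,
                   n_cutoffs = 40, min_genes = 100,
                   fdr_cutoffs = c(0.10, 0.30), n_coexpr_genes = 1500,
                   cost_donor = 1, alpha_line = 0.5, budget = 30)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  if (is.character(counts)) counts <- read_matrix_tsv(counts)
  if (is.character(metadata)) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage_file <- function(s, f) file.path(out_dir, paste0(s, "_", f))

  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(out)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(out))
    }
    out
  }

  ## qc ---------------------------------------------------------------------
  keep <- run_stage("qc", function() {
    filter_genes(counts, p$min_cpm, p$min_frac)
  })
  norm <- tmm_normalize(counts[keep, , drop = FALSE])
  res$qc <- norm
  if ("qc" %in% stages) {
    write_matrix_tsv(norm$log2cpm, stage_file("qc", "log2cpm.tsv"))
    utils::write.table(
      data.frame(sample_id = colnames(counts), tmm_factor = norm$factors,
                 lib_size = norm$lib_size),
      stage_file("qc", "factors.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  ## deconvolution ----------------------------------------------------------
  ctc <- NULL
  if ("deconvolution" %in% stages && !is.null(signature)) {
    ctc <- run_stage("deconvolution", function() ctc_scores(norm, signature))
    res$deconvolution <- ctc
    write_matrix_tsv(unclass(ctc), stage_file("deconvolution", "scores.tsv"),
                     id_name = "sample_id")
  }

  ## varpart ----------------------------------------------------------------
  vp <- NULL
  continuous <- character(0)
  md <- metadata[match(colnames(norm$log2cpm), metadata$sample_id), ]
  if ("varpart" %in% stages) {
    if (!is.null(ctc)) {
      sc <- unclass(ctc)[md$sample_id, , drop = FALSE]
      keep_sc <- colnames(sc)[apply(sc, 2, stats::sd) > 0]
      keep_sc <- utils::head(keep_sc, 2)
      for (cn in keep_sc) md[[paste0("ctc_", cn)]] <- sc[, cn]
      continuous <- paste0("ctc_", keep_sc)
    }
    vp <- run_stage("varpart", function() {
      partition_matrix(norm, md,
                       categorical = c("cell_type", "donor", "diagnosis", "sex"),
                       continuous = continuous)
    })
    res$varpart <- vp
    utils::write.table(vp$fractions, stage_file("varpart", "fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## enrichment -------------------------------------------------------------
  if ("enrichment" %in% stages && !is.null(vp) && !is.null(eqtl_genes)) {
    curve <- run_stage("enrichment", function() {
      eqtl_fold_enrichment(vp$fractions, "donor", eqtl_genes,
                           n_top = p$n_top, n_cutoffs = p$n_cutoffs,
                           n_perm = p$n_perm, min_genes = p$min_genes,
                           seed = seed)
    })
    res$enrichment <- curve
    utils::write.table(curve, stage_file("enrichment", "eqtl_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## differential expression ------------------------------------------------
  if ("de" %in% stages) {
    de <- run_stage("de", function() {
      design <- stats::model.matrix(
        ~ diagnosis + cell_type + sex,
        data = transform(md, diagnosis = factor(diagnosis,
                                                c("control", "case"))))
      w <- precision_weights(counts[keep, md$sample_id], design)
      rho <- consensus_correlation(norm, design, md$donor)
      fit <- fit_de(norm, design, "diagnosiscase", block = md$donor,
                    rho = rho, weights = w)
      mod <- ebayes_moderate(fit)
      mod$fdr_bh <- fdr_adjust(mod$p_value, "BH")
      q <- fdr_adjust(mod$p_value, "qvalue")
      mod$q_value <- as.numeric(q)
      attr(mod, "pi0") <- attr(q, "pi0")
      attr(mod, "rho") <- rho
      mod
    })
    res$de <- de
    utils::write.table(as.data.frame(de), stage_file("de", "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## coexpression -----------------------------------------------------------
  if ("coexpression" %in% stages) {
    coex <- run_stage("coexpression", function() {
      out <- list()
      for (ct in unique(md$cell_type)) {
        x <- norm$log2cpm[, md$sample_id[md$cell_type == ct], drop = FALSE]
        sds <- apply(x, 1, stats::sd)
        top <- utils::head(order(sds, decreasing = TRUE), p$n_coexpr_genes)
        adj <- soft_adjacency(x[top, , drop = FALSE], beta = p$beta)
        tom <- topological_overlap(adj)
        mods <- detect_modules(tom, min_module_size = p$min_module_size)
        enr <- if (!is.null(gene_sets)) module_enrichment(mods, gene_sets)
        out[[ct]] <- list(modules = mods, enrichment = enr)
      }
      out
    })
    res$coexpression <- coex
    for (ct in names(coex)) {
      utils::write.table(
        data.frame(gene_id = names(coex[[ct]]$modules$modules),
                   module = coex[[ct]]$modules$modules),
        stage_file("coexpression", paste0(ct, "_modules.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## design -----------------------------------------------------------------
  if ("design" %in% stages) {
    des <- run_stage("design", function() {
      rho_med <- if (!is.null(vp)) {
        stats::median(vp$fractions$donor, na.rm = TRUE)
      } else 0.022
      opt <- optimize_design(p$budget, p$cost_donor, p$alpha_line, rho_med)
      list(rho = rho_med, optimum = opt)
    })
    res$design <- des
    utils::write.table(
      data.frame(donor_effect = des$rho,
                 n_donors = des$optimum$n_donors,
                 total_lines = des$optimum$ess$n,
                 ess = des$optimum$ess$ess,
                 cost = des$optimum$cost),
      stage_file("design", "report.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  ## manifest ---------------------------------------------------------------
  outputs <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.txt"))
  manifest <- c(
    paste0("package_version: ", as.character(utils::packageVersion("ipscvar"))),
    paste0("r_version: ", R.version.string),
    paste0("seed: ", seed),
    paste0("stages: ", paste(stages, collapse = ",")),
    paste0("varpart_continuous: ",
           if (length(continuous)) paste(continuous, collapse = ",") else "none"),
    vapply(names(p), function(k) {
      paste0("param ", k, ": ", paste(p[[k]], collapse = ","))
    }, character(1)),
    vapply(outputs, function(f) {
      paste0("output ", basename(f), " md5: ", unname(tools::md5sum(f)))
    }, character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(res)
}
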