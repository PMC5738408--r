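#' Filter genes by counts-per-million support
#'
#' A gene is retained when its CPM (computed from raw library sizes, before
#' any between-sample normalization) exceeds `min_cpm` in at least
#' `ceiling(min_frac * n_samples)` samples; a tie at exactly the fraction
#' counts as retained.
#'
#' @param counts nonnegative gene x sample count matrix with dimnames.
#' @param min_cpm CPM threshold (strictly greater than).
#' @param min_frac minimum fraction of samples.
#' @return character vector of retained gene ids, input order preserved.
#' @export
filter_genes <- function(counts, min_cpm = 1, min_frac = 0.30) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  cpm <- sweep(counts, 2, lib, `/`) * 1e6
  need <- ceiling(min_frac * ncol(counts))
  keep <- rowSums(cpm > min_cpm) >= need
  rownames(counts)[keep]
}

# Pairwise TMM factor of sample `obs` against `ref` (counts and library
# sizes), doubly trimmed by M-value and A-value ranks, inverse-variance
# weighted (delta-method binomial weights).
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_logratio, trim_abs) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(structure(1, fallback = TRUE))
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & v > 0
  m <- m[fin]; a <- a[fin]; w <- 1 / v[fin]
  n <- length(m)
  if (n == 0) return(structure(1, fallback = TRUE))
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- floor(n * trim_logratio) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_abs) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) {
    warning("all genes trimmed; falling back to factor 1")
    return(structure(1, fallback = TRUE))
  }
  f <- sum(w[keep2] * m[keep2]) / sum(w[keep2])
  2^f
}

#' TMM normalization and log2-CPM
#'
#' Trimmed-mean-of-M-values scaling: for every sample, a weighted trimmed
#' mean of gene-wise log2 ratios to a reference sample (genes zero in either
#' sample excluded; double trim on M and A values), rescaled so the factors
#' have geometric mean 1. The reference is the sample whose 75th CPM
#' percentile is closest to the mean of those percentiles.
#'
#' @param counts gene x sample count matrix.
#' @param trim_logratio two-sided trim fraction on M-values.
#' @param trim_abs two-sided trim fraction on A-values.
#' @param prior_count prior added when computing log2-CPM.
#' @param ref_sample optional reference sample name or index.
#' @return object of class `NormalizedMatrix`: list with `log2cpm`
#'   (gene x sample), `factors`, `lib_size`, `prior_count`.
#' @export
tmm_normalize <- function(counts, trim_logratio = 0.30, trim_abs = 0.05,
                          prior_count = 0.5, ref_sample = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (is.null(ref_sample)) {
    f75 <- apply(sweep(counts, 2, lib, `/`), 2, stats::quantile, probs = 0.75)
    ref_sample <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref_sample)) {
    ref_sample <- match(ref_sample, colnames(counts))
  }
  refc <- counts[, ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    as.numeric(tmm_pair(counts[, j], refc, lib[j], lib[ref_sample],
                        trim_logratio, trim_abs))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  eff <- lib * f
  log2cpm <- log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, `/`) * 1e6)
  structure(list(log2cpm = log2cpm, factors = f, lib_size = lib,
                 prior_count = prior_count),
            class = "NormalizedMatrix")
}

# Accept either a NormalizedMatrix or a plain log2-scale matrix.
as_log2cpm <- function(x) {
  if (inherits(x, "NormalizedMatrix")) x$log2cpm else as.matrix(x)
}

#' Infer sample sex from XIST and chrY expression
#'
#' Two-dimensional rule on (XIST log2-CPM, mean chrY log2-CPM): female when
#' XIST is high and chrY low, male when the reverse, otherwise intermediate
#' (consistent with contamination or aberrant X-inactivation).
#'
#' @param norm `NormalizedMatrix` or log2-CPM matrix.
#' @param xist_id XIST gene id.
#' @param chry_ids chrY gene ids (typically six).
#' @param annotated_sex optional named vector of recorded sexes; mismatches
#'   with a confident call are flagged.
#' @param xist_hi,xist_lo,chry_hi,chry_lo thresholds in log2-CPM units.
#' @return data.frame: sample_id, call, xist, chry_mean, mismatch.
#' @export
infer_sex <- function(norm, xist_id, chry_ids, annotated_sex = NULL,
                      xist_hi = 2, xist_lo = 1, chry_hi = 2, chry_lo = 1) {
  x <- as_log2cpm(norm)
  miss <- setdiff(c(xist_id, chry_ids), rownames(x))
  if (length(miss)) {
    stop("genes missing from matrix: ", paste(miss, collapse = ", "))
  }
  xist <- x[xist_id, ]
  chry <- colMeans(x[chry_ids, , drop = FALSE])
  call <- ifelse(xist >= xist_hi & chry < chry_lo, "female",
          ifelse(xist < xist_lo & chry >= chry_hi, "male", "intermediate"))
  out <- data.frame(sample_id = colnames(x), call = call,
                    xist = xist, chry_mean = chry,
                    mismatch = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(annotated_sex)) {
    ann <- annotated_sex[out$sample_id]
    out$mismatch <- call != "intermediate" & !is.na(ann) & call != ann
  }
  out
}

#' Z-scores of expression for genes inside CNV regions
#'
#' Residualizes log2-CPM on culture cell type (one-way linear model), then
#' standardizes each gene's residuals across samples. Only genes overlapping
#' a region are reported. Regions follow BED convention (0-based half-open);
#' gene coordinates are 1-based inclusive and converted internally.
#'
#' @param norm `NormalizedMatrix` or log2-CPM matrix.
#' @param metadata data.frame with `sample_id` and `cell_type`.
#' @param regions data.frame with chrom, start, end (BED) and optional name.
#' @param gene_coords data.frame with gene_id, chrom, start, end (1-based).
#' @return data.frame: gene_id, region, sample_id, z, zero_variance flag.
#' @export
cnv_zscores <- function(norm, metadata, regions, gene_coords) {
  x <- as_log2cpm(norm)
  metadata <- metadata[match(colnames(x), metadata$sample_id), ]
  if (anyNA(metadata$sample_id)) stop("metadata missing samples")
  gene_coords <- gene_coords[gene_coords$gene_id %in% rownames(x), ]
  if (is.null(regions$name)) {
    regions$name <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  gr_genes <- GenomicRanges::GRanges(
    gene_coords$chrom,
    IRanges::IRanges(gene_coords$start, gene_coords$end))
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_reg)
  if (!length(ov)) {
    return(data.frame(gene_id = character(0), region = character(0),
                      sample_id = character(0), z = numeric(0),
                      zero_variance = logical(0)))
  }
  hit_genes <- gene_coords$gene_id[S4Vectors::queryHits(ov)]
  hit_regions <- regions$name[S4Vectors::subjectHits(ov)]

  # residuals on cell type, then per-gene z
  design <- stats::model.matrix(~ factor(metadata$cell_type))
  sub <- x[unique(hit_genes), , drop = FALSE]
  res <- t(stats::lm.fit(design, t(sub))$residuals)
  sds <- apply(res, 1, stats::sd)
  degenerate <- sds < 1e-12
  z <- res / ifelse(degenerate, 1, sds)
  z[degenerate, ] <- 0
  sds[degenerate] <- 0

  out <- do.call(rbind, lapply(seq_along(hit_genes), function(i) {
    g <- hit_genes[i]
    data.frame(gene_id = g, region = hit_regions[i],
               sample_id = colnames(x), z = z[g, ],
               zero_variance = sds[g] == 0, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
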