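#' Build a synthetic reference signature panel
#'
#' Constructs a gene-by-profile expression matrix (linear scale) with marker
#' structure: every profile shares a log-normal baseline and carries a
#' disjoint block of marker genes with elevated expression. Multiple profiles
#' may collapse to the same cell type, mirroring reference panels assembled
#' from several single-cell data sets per cell type.
#'
#' @param n_genes total number of genes in the panel.
#' @param profiles character vector of profile names.
#' @param cell_type_map named character vector mapping profile -> cell type.
#'   Defaults to the identity map.
#' @param n_markers marker genes per profile.
#' @param marker_log2fc_range range of the log2 boost given to marker genes.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale baseline expression
#'   distribution shared across profiles.
#' @param gene_ids optional gene identifiers (length `n_genes`).
#' @param seed integer seed.
#' @return an object of class `SignaturePanel`: a list with `profiles`
#'   (gene x profile linear-scale matrix) and `map` (profile -> cell type).
#' @export
simulate_signature_panel <- function(n_genes = 2000,
                                     profiles = c("neuron_a", "neuron_b",
                                                  "npc", "hipsc",
                                                  "fibroblast_1", "fibroblast_2"),
                                     cell_type_map = NULL,
                                     n_markers = 50,
                                     marker_log2fc_range = c(2, 4),
                                     baseline_log2_mean = 5,
                                     baseline_log2_sd = 1.5,
                                     gene_ids = NULL,
                                     seed = 1L) {
  stopifnot(n_genes >= length(profiles) * n_markers)
  if (is.null(cell_type_map)) {
    cell_type_map <- sub("_[ab]$", "", profiles)
    names(cell_type_map) <- profiles
  }
  stopifnot(all(profiles %in% names(cell_type_map)))
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
  }
  set.seed(seed)
  base <- 2^stats::rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
  sig <- matrix(base, nrow = n_genes, ncol = length(profiles),
                dimnames = list(gene_ids, profiles))
  marker_idx <- split(seq_len(length(profiles) * n_markers),
                      rep(seq_along(profiles), each = n_markers))
  for (j in seq_along(profiles)) {
    idx <- marker_idx[[j]]
    boost <- stats::runif(length(idx), marker_log2fc_range[1], marker_log2fc_range[2])
    sig[idx, j] <- sig[idx, j] * 2^boost
  }
  new_signature_panel(sig, cell_type_map[profiles])
}

#' Create a SignaturePanel from a matrix and a profile map
#'
#' @param profiles nonnegative gene x profile matrix (linear scale).
#' @param map named character vector, profile name -> cell type.
#' @return `SignaturePanel` object.
#' @export
new_signature_panel <- function(profiles, map) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("signature panel must be nonnegative")
  if (is.null(names(map))) names(map) <- colnames(profiles)
  if (!all(colnames(profiles) %in% names(map))) {
    stop("every profile must be mapped to a cell type")
  }
  structure(list(profiles = profiles, map = map[colnames(profiles)]),
            class = "SignaturePanel")
}

#' Simulation configuration for a repeated-measures hiPSC cohort
#'
#' Defaults reproduce the structure of the cohort the workflow targets:
#' 11 case and 11 control donors with two clonal lines each, profiled as two
#' culture cell types (NPC and neuron), for 88 samples. The donor effect
#' (the fraction of log2-scale expression variance across donors) defaults
#' to 0.022, the median value observed in that cohort.
#'
#' @param n_genes number of genes (ignored when `signature` is supplied;
#'   then taken from the panel).
#' @param n_donors_case,n_donors_control donors per diagnosis group.
#' @param lines_per_donor clonal lines per donor; scalar or per-donor vector.
#' @param cell_types culture cell types profiled for every line.
#' @param icc_donor target donor variance fraction in `[0, 1)` relative to
#'   the residual log2-scale noise: `sigma2_d = icc * sigma2_res / (1 - icc)`.
#' @param frac_de_genes fraction of genes with a true diagnosis effect.
#' @param lfc_sd standard deviation (log2) of true diagnosis effects.
#' @param signature a `SignaturePanel`; defaults to
#'   [simulate_signature_panel()] with `n_genes` genes.
#' @param mixing_concentration named list: one positive Dirichlet parameter
#'   vector over reference profiles per culture cell type.
#' @param libsize_log_mean,libsize_log_sd natural-log library size
#'   distribution.
#' @param nb_dispersion negative-binomial dispersion phi (Var = mu + phi mu^2);
#'   0 gives the Poisson limit.
#' @param sigma_res residual log2-scale biological noise s.d.
#' @param mix_floor pseudo-floor added inside the log2 mixture.
#' @param frac_eqtl fraction of genes flagged as eQTL genes; these receive a
#'   donor s.d. multiplied by `eqtl_donor_mult`, so that donor-variable genes
#'   are enriched for the eQTL list, as observed in brain cohorts.
#' @param eqtl_donor_mult multiplier described above.
#' @param sex_genes list with elements `xist` (one id) and `chry` (six ids).
#' @param cnv_events data.frame with columns donor, chrom, start, end (1-based
#'   inclusive), dosage: genes inside the region have their mean multiplied
#'   by `dosage` in all samples of that donor. NULL for none.
#' @param sendai_donors donor ids carrying residual reprogramming-vector
#'   expression; their samples get a positive continuous `sendai` covariate.
#' @param sendai_effect_sd s.d. of per-gene log2 slopes on the sendai score
#'   for `frac_sendai_genes` of genes (0 disables the signal).
#' @param frac_sendai_genes see above.
#' @param n_intermediate number of female samples rendered "intermediate" by
#'   50/50 mixing of the male and female sex-gene profiles.
#' @param lfc_override optional vector of true log2 fold changes (advanced;
#'   used by [simulate_paired_cohorts()]).
#' @param seed integer seed; all randomness derives from it.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_donors_case = 11,
                              n_donors_control = 11,
                              lines_per_donor = 2,
                              cell_types = c("NPC", "neuron"),
                              icc_donor = 0.022,
                              frac_de_genes = 0.02,
                              lfc_sd = 0.5,
                              signature = NULL,
                              mixing_concentration = NULL,
                              libsize_log_mean = log(2e7),
                              libsize_log_sd = 0.25,
                              nb_dispersion = 0.1,
                              sigma_res = 0.5,
                              mix_floor = 1,
                              frac_eqtl = 0.2,
                              eqtl_donor_mult = 3,
                              sex_genes = NULL,
                              cnv_events = NULL,
                              sendai_donors = NULL,
                              sendai_effect_sd = 0,
                              frac_sendai_genes = 0.1,
                              n_intermediate = 0,
                              lfc_override = NULL,
                              seed = 1L) {
  if (icc_donor < 0 || icc_donor >= 1) stop("icc_donor must be in [0, 1)")
  if (n_donors_case < 0 || n_donors_control < 0 ||
      n_donors_case + n_donors_control < 1) {
    stop("need at least one donor")
  }
  if (is.null(signature)) {
    signature <- simulate_signature_panel(n_genes = n_genes, seed = seed + 1L)
  }
  if (nrow(signature$profiles) != n_genes) {
    stop("signature panel and n_genes disagree (", nrow(signature$profiles),
         " vs ", n_genes, ")")
  }
  if (is.null(mixing_concentration)) {
    mixing_concentration <- default_mixing(signature, cell_types)
  }
  for (ct in cell_types) {
    a <- mixing_concentration[[ct]]
    if (is.null(a) || any(a <= 0) ||
        length(a) != ncol(signature$profiles)) {
      stop("mixing_concentration must give one positive value per reference ",
           "profile for cell type ", ct)
    }
  }
  n_donors <- n_donors_case + n_donors_control
  lines_per_donor <- rep_len(lines_per_donor,
                             if (length(lines_per_donor) == 1) n_donors
                             else length(lines_per_donor))
  if (length(lines_per_donor) != n_donors || any(lines_per_donor < 1)) {
    stop("lines_per_donor must be positive, scalar or one per donor")
  }
  structure(list(
    n_genes = n_genes, n_donors_case = n_donors_case,
    n_donors_control = n_donors_control, lines_per_donor = lines_per_donor,
    cell_types = cell_types, icc_donor = icc_donor,
    frac_de_genes = frac_de_genes, lfc_sd = lfc_sd, signature = signature,
    mixing_concentration = mixing_concentration,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    nb_dispersion = nb_dispersion, sigma_res = sigma_res,
    mix_floor = mix_floor, frac_eqtl = frac_eqtl,
    eqtl_donor_mult = eqtl_donor_mult, sex_genes = sex_genes,
    cnv_events = cnv_events, sendai_donors = sendai_donors,
    sendai_effect_sd = sendai_effect_sd,
    frac_sendai_genes = frac_sendai_genes,
    n_intermediate = n_intermediate, lfc_override = lfc_override,
    seed = as.integer(seed)), class = "SimulationConfig")
}

# Dirichlet parameters concentrating each culture cell type on the matching
# reference profiles, with a diffuse floor over the rest of the panel.
default_mixing <- function(signature, cell_types) {
  profs <- colnames(signature$profiles)
  map <- signature$map
  out <- lapply(cell_types, function(ct) {
    a <- rep(1, length(profs))
    names(a) <- profs
    main <- switch(ct,
                   NPC = map %in% c("npc", "hipsc"),
                   neuron = map %in% c("neuron"),
                   map %in% ct)
    if (any(main)) a[main] <- 12 / sum(main)
    a
  })
  names(out) <- cell_types
  out
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a repeated-measures case/control cohort with ground truth
#'
#' Generates negative-binomial counts for a cohort of donors with multiple
#' clonal lines and culture cell types per donor. The per-gene log2 mean is
#' `log2(sum_c pi_c * signature + floor) + donor effect + diagnosis effect +
#' residual noise`, with sample mixing proportions drawn from cell-type-
#' specific Dirichlet distributions, sex-chromosome signatures, optional CNV
#' dosage events, and optional residual reprogramming-vector (sendai)
#' covariate effects. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (gene x sample integer matrix), `metadata`
#'   (one row per sample: sample_id, donor, line, cell_type, diagnosis, sex,
#'   batch, sendai), `truth` (per-gene true log2FC, DE/eQTL indicators,
#'   target donor ICC, realized variance fractions; per-sample mixing
#'   proportions at profile and cell-type level), and `gene_coords`
#'   (1-based inclusive gene coordinates used for CNV overlap).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  sig <- config$signature
  genes <- rownames(sig$profiles)
  n_genes <- length(genes)
  profs <- colnames(sig$profiles)

  ## ---- donors, lines, samples -------------------------------------------
  n_donors <- config$n_donors_case + config$n_donors_control
  donors <- sprintf("D%03d", seq_len(n_donors))
  diagnosis_d <- rep(c("case", "control"),
                     c(config$n_donors_case, config$n_donors_control))
  sex_d <- rep_len(c("male", "female"), n_donors)
  meta <- do.call(rbind, lapply(seq_len(n_donors), function(d) {
    kl <- config$lines_per_donor[d]
    expand.grid(line = seq_len(kl), cell_type = config$cell_types,
                donor = donors[d], KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  }))
  meta$diagnosis <- diagnosis_d[match(meta$donor, donors)]
  meta$sex <- sex_d[match(meta$donor, donors)]
  meta$sample_id <- sprintf("%s_L%d_%s", meta$donor, meta$line, meta$cell_type)
  meta$batch <- sample(paste0("B", 1:3), nrow(meta), replace = TRUE)
  n_samples <- nrow(meta)

  ## ---- gene-level effects -----------------------------------------------
  sigma2_res <- config$sigma_res^2
  sigma2_d <- config$icc_donor * sigma2_res / (1 - config$icc_donor)
  eqtl_gene <- stats::rbinom(n_genes, 1, config$frac_eqtl) == 1
  sd_donor_g <- sqrt(sigma2_d) *
    ifelse(eqtl_gene, config$eqtl_donor_mult, 1)
  donor_eff <- matrix(stats::rnorm(n_genes * n_donors), n_genes, n_donors) *
    sd_donor_g
  colnames(donor_eff) <- donors

  if (!is.null(config$lfc_override)) {
    stopifnot(length(config$lfc_override) == n_genes)
    lfc <- config$lfc_override
    de_gene <- lfc != 0
  } else {
    de_gene <- stats::rbinom(n_genes, 1, config$frac_de_genes) == 1
    lfc <- ifelse(de_gene, stats::rnorm(n_genes, 0, config$lfc_sd), 0)
  }

  ## ---- mixing proportions and log2 mixture term -------------------------
  pi_prof <- t(vapply(seq_len(n_samples), function(s) {
    rdirichlet1(config$mixing_concentration[[meta$cell_type[s]]])
  }, numeric(length(profs))))
  dimnames(pi_prof) <- list(meta$sample_id, profs)
  mix_lin <- sig$profiles %*% t(pi_prof)            # gene x sample
  log2mix <- log2(mix_lin + config$mix_floor)

  ## ---- sex-chromosome signal --------------------------------------------
  sexg <- config$sex_genes
  gene_chrom <- rep("autosome", n_genes)
  names(gene_chrom) <- genes
  if (!is.null(sexg)) {
    miss <- setdiff(c(sexg$xist, sexg$chry), genes)
    if (length(miss)) stop("sex genes not in panel: ", paste(miss, collapse = ", "))
    gene_chrom[sexg$xist] <- "chrX"
    gene_chrom[sexg$chry] <- "chrY"
  }
  interm <- character(0)
  if (config$n_intermediate > 0) {
    fem <- meta$sample_id[meta$sex == "female"]
    interm <- utils::head(fem, config$n_intermediate)
  }

  ## ---- sendai covariate --------------------------------------------------
  meta$sendai <- 0
  sendai_slope <- numeric(n_genes)
  if (!is.null(config$sendai_donors)) {
    hit <- meta$donor %in% config$sendai_donors
    meta$sendai[hit] <- stats::rexp(sum(hit), rate = 1)
    if (config$sendai_effect_sd > 0) {
      sg <- stats::rbinom(n_genes, 1, config$frac_sendai_genes) == 1
      sendai_slope[sg] <- stats::rnorm(sum(sg), 0, config$sendai_effect_sd)
    }
  }

  ## ---- assemble log2 means ----------------------------------------------
  is_case <- as.numeric(meta$diagnosis == "case")
  mu_log2 <- log2mix +
    donor_eff[, match(meta$donor, donors), drop = FALSE] +
    outer(lfc, is_case) +
    outer(sendai_slope, meta$sendai) +
    matrix(stats::rnorm(n_genes * n_samples, 0, config$sigma_res),
           n_genes, n_samples)
  colnames(mu_log2) <- meta$sample_id

  # sex signal: the active state sits at a well-expressed level, the
  # silenced state near zero CPM; intermediate samples are a 50/50 linear
  # mixture of the male and female profiles (as after contamination or
  # aberrant X-inactivation).
  if (!is.null(sexg)) {
    female_w <- ifelse(meta$sex == "female", 1, 0)
    female_w[meta$sample_id %in% interm] <- 0.5
    med <- stats::median(mu_log2)
    lin_on <- 2^(med + 2)
    lin_off <- 2^(med - 12)
    noise <- function(k) matrix(stats::rnorm(k * n_samples, 0, 0.2),
                                k, n_samples)
    mu_log2[sexg$xist, ] <-
      log2(female_w * lin_on + (1 - female_w) * lin_off) + noise(1)
    mu_log2[sexg$chry, ] <-
      rep(log2((1 - female_w) * lin_on + female_w * lin_off),
          each = length(sexg$chry)) + noise(length(sexg$chry))
  }

  ## ---- gene coordinates and CNV dosage ----------------------------------
  gene_coords <- synth_gene_coords(genes, gene_chrom)
  dosage <- matrix(1, n_genes, n_samples)
  if (!is.null(config$cnv_events) && nrow(config$cnv_events) > 0) {
    for (i in seq_len(nrow(config$cnv_events))) {
      ev <- config$cnv_events[i, ]
      in_reg <- gene_coords$chrom == ev$chrom &
        gene_coords$start <= ev$end & gene_coords$end >= ev$start
      cols <- meta$donor == ev$donor
      if (any(in_reg) && any(cols)) {
        dosage[in_reg, cols] <- dosage[in_reg, cols] * ev$dosage
      }
    }
  }

  ## ---- counts ------------------------------------------------------------
  lin_mean <- 2^mu_log2 * dosage
  frac <- sweep(lin_mean, 2, colSums(lin_mean), `/`)
  libsize <- exp(stats::rnorm(n_samples, config$libsize_log_mean,
                              config$libsize_log_sd))
  mu_count <- sweep(frac, 2, libsize, `*`)
  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(genes, meta$sample_id))
  if (config$nb_dispersion > 0) {
    counts[] <- stats::rnbinom(length(mu_count),
                               size = 1 / config$nb_dispersion,
                               mu = mu_count)
  } else {
    counts[] <- stats::rpois(length(mu_count), mu_count)
  }

  ## ---- ground truth -------------------------------------------------------
  pi_ct <- collapse_columns(pi_prof, sig$map)
  var_mix <- apply(log2mix, 1, stats::var)
  var_donor <- sd_donor_g^2
  tot <- var_mix + var_donor + sigma2_res
  truth <- list(
    lfc = stats::setNames(lfc, genes),
    de_gene = stats::setNames(de_gene, genes),
    eqtl_gene = stats::setNames(eqtl_gene, genes),
    icc_donor = stats::setNames(var_donor / (var_donor + sigma2_res), genes),
    var_fractions = data.frame(gene_id = genes,
                               cell_type = var_mix / tot,
                               donor = var_donor / tot,
                               residual = sigma2_res / tot,
                               row.names = NULL),
    mixing_profiles = pi_prof,
    mixing_cell_types = pi_ct,
    intermediate_samples = interm,
    libsize = stats::setNames(libsize, meta$sample_id))

  meta <- meta[, c("sample_id", "donor", "line", "cell_type", "diagnosis",
                   "sex", "batch", "sendai")]
  rownames(meta) <- meta$sample_id
  list(counts = counts, metadata = meta, truth = truth,
       gene_coords = gene_coords)
}

# Deterministic synthetic coordinates: autosomal genes tile chr1 in 10 kb
# steps; sex genes are placed on chrX/chrY. 1-based inclusive.
synth_gene_coords <- function(genes, gene_chrom) {
  n <- length(genes)
  start <- seq_len(n) * 10000 + 1
  data.frame(gene_id = genes, chrom = unname(gene_chrom),
             start = start, end = start + 4999,
             stringsAsFactors = FALSE)
}

# Sum columns of a sample x profile matrix within cell types.
collapse_columns <- function(mat, map) {
  cts <- unique(unname(map))
  out <- vapply(cts, function(ct) {
    rowSums(mat[, names(map)[map == ct], drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat))
  dimnames(out) <- list(rownames(mat), cts)
  out
}

#' Simulate two cohorts with correlated true diagnosis effects
#'
#' Both cohorts use the same DE gene set; on those genes the true log2 fold
#' changes are `lfc_sd * (sqrt(|r|) u + sqrt(1-|r|) v_i)` with shared `u`,
#' so the truth vectors have Pearson correlation approximately
#' `shared_effect_corr` (exactly equal vectors at r = 1).
#'
#' @param config cohort A configuration ([simulation_config()]).
#' @param shared_effect_corr target correlation in `[-1, 1]`.
#' @param config_b optional configuration for cohort B (defaults to
#'   `config` with a shifted seed); its gene panel must match cohort A's.
#' @return list with `cohort_a`, `cohort_b` (each as [simulate_cohort()])
#'   and `shared_effect_corr`.
#' @export
simulate_paired_cohorts <- function(config, shared_effect_corr,
                                    config_b = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (abs(shared_effect_corr) > 1) {
    stop("shared_effect_corr must be in [-1, 1]")
  }
  if (is.null(config_b)) {
    config_b <- config
    config_b$seed <- config$seed + 10000L
  }
  if (config_b$n_genes != config$n_genes) {
    stop("paired cohorts need a common gene panel")
  }
  set.seed(config$seed + 20000L)
  n <- config$n_genes
  de <- stats::rbinom(n, 1, config$frac_de_genes) == 1
  u <- stats::rnorm(n)
  v1 <- stats::rnorm(n)
  v2 <- stats::rnorm(n)
  r <- shared_effect_corr
  a <- sqrt(abs(r))
  b <- sqrt(1 - abs(r))
  lfc_a <- ifelse(de, config$lfc_sd * (a * u + b * v1), 0)
  lfc_b <- ifelse(de, config_b$lfc_sd * (sign(r + 1e-300) * a * u + b * v2), 0)
  if (abs(r) == 1) lfc_b <- sign(r) * lfc_a / config$lfc_sd * config_b$lfc_sd
  config$lfc_override <- lfc_a
  config_b$lfc_override <- lfc_b
  list(cohort_a = simulate_cohort(config),
       cohort_b = simulate_cohort(config_b),
       shared_effect_corr = r)
}
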