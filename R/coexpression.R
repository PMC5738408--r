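# WGCNA module color order; grey is reserved for unassigned genes.
WGCNA_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                  "black", "pink", "magenta", "purple", "greenyellow",
                  "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                  "grey60", "lightgreen", "lightyellow", "royalblue",
                  "darkred", "darkgreen", "darkturquoise", "darkgrey",
                  "orange", "darkorange", "white", "skyblue", "saddlebrown",
                  "steelblue", "paleturquoise", "violet", "darkolivegreen",
                  "darkmagenta")

#' Soft-threshold (unsigned) coexpression adjacency
#'
#' `a_ij = |cor(i, j)|^beta` with unit diagonal; raising the correlation to
#' a power suppresses weak correlations and yields an approximately
#' scale-free network.
#'
#' @param expr expression matrix, genes x samples (at least 3 samples).
#' @param beta soft-threshold power (>= 1).
#' @return symmetric gene x gene adjacency matrix with entries in `[0, 1]`.
#' @export
soft_adjacency <- function(expr, beta = 9) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance genes must be filtered before adjacency: ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  }
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu`, the sum running over `u` distinct
#' from both `i` and `j`; the diagonal is 1. High topological overlap means
#' two genes share neighbors as well as a direct connection.
#'
#' @param adj adjacency matrix from [soft_adjacency()].
#' @return TOM matrix, same dimension.
#' @export
topological_overlap <- function(adj) {
  adj <- as.matrix(adj)
  stopifnot(isSymmetric(unname(adj)), all(adj >= 0 & adj <= 1))
  a <- adj
  diag(a) <- 0
  l <- a %*% a                       # (A^2)_ij = sum_u a_iu a_uj, u != i,j after diag 0
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a fixed fraction of the tallest merge height; branches smaller than
#' `min_module_size` are assigned to "grey". Non-grey modules are labeled
#' by decreasing size in the conventional WGCNA color order. Gene input
#' order does not affect the assignment (genes are processed in stable
#' sorted-id order).
#'
#' @param tom TOM matrix with gene dimnames.
#' @param min_module_size minimum genes per non-grey module.
#' @param cut_height_frac static cut height as a fraction of the tallest
#'   merge height (branches joining above it are separated).
#' @return list of class `ModuleAssignment`: `modules` (named character,
#'   gene -> label), `sizes` (table), `cut_height`.
#' @export
detect_modules <- function(tom, min_module_size = 20,
                           cut_height_frac = 0.99) {
  genes <- rownames(tom)
  ord <- order(genes)
  tom <- tom[ord, ord]
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- cut_height_frac * max(hc$height)
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(big)) {
    big <- big[order(-sizes[big], as.integer(big))]
    cols <- c(WGCNA_COLORS,
              paste0("module_", seq_len(max(0, length(big) - length(WGCNA_COLORS)))))
    for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- cols[i]
  } else {
    warning("no module reaches min_module_size; all genes grey")
  }
  names(labels) <- rownames(tom)
  labels <- labels[genes]            # restore input order
  structure(list(modules = labels, sizes = table(labels),
                 cut_height = unname(cut_h)),
            class = "ModuleAssignment")
}

#' Gene-set enrichment of coexpression modules
#'
#' Hypergeometric over-representation of every gene set in every module
#' (including grey), with the clustered genes as the background and a
#' Bonferroni family of `n_modules * n_sets` tests.
#'
#' @param modules `ModuleAssignment` from [detect_modules()].
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param alpha familywise significance level.
#' @return data.frame: module, set, overlap, odds_ratio, p_value,
#'   significant; attribute `family_size`.
#' @export
module_enrichment <- function(modules, sets, alpha = 0.05) {
  universe <- names(modules$modules)
  mods <- unique(modules$modules)
  rows <- list()
  for (m in mods) {
    mg <- universe[modules$modules == m]
    for (sn in names(sets)) {
      h <- hypergeom_enrich(mg, sets[[sn]], universe)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, set = sn, overlap = h$overlap,
        odds_ratio = h$odds_ratio, p_value = h$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  family <- length(mods) * length(sets)
  out$significant <- out$p_value < alpha / family
  attr(out, "family_size") <- family
  out
}
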