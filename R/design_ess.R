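#' Effective sample size of a repeated-measures design
#'
#' For donors contributing `k_i` correlated samples with intra-donor
#' correlation `rho` (the donor effect: the fraction of expression variation
#' across donors), the design-effect formula under compound symmetry gives
#' `ESS = sum_i k_i / (1 + (k_i - 1) rho)`: the sample size of a study of
#' only independent samples with equivalent power. A new donor always adds
#' exactly one unit; an extra line from an existing donor adds a fraction
#' that shrinks as `rho` grows.
#'
#' @param k_list positive integer replicate counts, one per donor.
#' @param rho donor effect in `[0, 1]`.
#' @return list of class `ESSReport`: `n` (total samples), `ess`,
#'   `contributions` (per donor), `gain_next_donor`,
#'   `gain_next_replicate` (for the first donor in `k_list`).
#' @export
ess <- function(k_list, rho) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (any(k_list < 1) || any(k_list != round(k_list))) {
    stop("replicate counts must be positive integers")
  }
  contrib <- k_list / (1 + (k_list - 1) * rho)
  structure(list(n = sum(k_list), ess = sum(contrib),
                 contributions = contrib,
                 gain_next_donor = 1,
                 gain_next_replicate = ess_increment(k_list[1], rho)),
            class = "ESSReport")
}

#' Marginal ESS of one additional line
#'
#' `Delta = (k + 1) / (1 + k rho) - k / (1 + (k - 1) rho)`; `k = 0` means a
#' new donor and yields exactly 1 for every `rho`.
#'
#' @param current_k current number of lines for the donor (0 = new donor).
#' @param rho donor effect in `[0, 1]`.
#' @return marginal ESS gain.
#' @export
ess_increment <- function(current_k, rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]")
  if (any(current_k < 0)) stop("current_k must be >= 0")
  new_part <- (current_k + 1) / (1 + current_k * rho)
  old_part <- ifelse(current_k == 0, 0,
                     current_k / (1 + (current_k - 1) * rho))
  new_part - old_part
}

#' Optimize a study design for effective sample size
#'
#' Exhaustive search over uniform designs (m donors with k lines each, plus
#' leftover budget spent on one extra line for some donors) under a budget
#' or donor-count constraint. Each donor costs `cost_donor` including the
#' first line; every additional line costs `alpha * cost_donor`. Balanced
#' designs dominate at fixed total lines (the ESS is Schur-concave in the
#' replicate counts), so the uniform-plus-remainder family contains an
#' optimum. Ties are broken toward fewer total lines, then more donors
#' (replicate clones never beat independent donors on a tie).
#'
#' @param budget total budget (same units as `cost_donor`).
#' @param cost_donor cost of a donor with one line.
#' @param alpha relative cost of an additional line, in (0, 1].
#' @param rho donor effect in `[0, 1]`.
#' @param constraint "budget", or "n_donors" to fix the number of donors at
#'   `n_donors` and spend the budget on lines.
#' @param n_donors required when `constraint = "n_donors"`.
#' @param max_k maximum lines per donor considered.
#' @return list: `k_list`, `n_donors`, `cost`, `ess` (`ESSReport`).
#' @export
optimize_design <- function(budget, cost_donor, alpha, rho,
                            constraint = c("budget", "n_donors"),
                            n_donors = NULL, max_k = 10) {
  constraint <- match.arg(constraint)
  if (budget < cost_donor) stop("budget below the cost of a single donor")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  line_cost <- alpha * cost_donor
  m_max <- floor(budget / cost_donor)
  m_range <- if (constraint == "n_donors") {
    if (is.null(n_donors)) stop("n_donors required for this constraint")
    if (n_donors > m_max) stop("budget cannot afford n_donors donors")
    n_donors
  } else {
    seq_len(m_max)
  }
  best <- NULL
  for (m in m_range) {
    for (k in seq_len(max_k)) {
      base_cost <- m * (cost_donor + (k - 1) * line_cost)
      if (base_cost > budget) break
      # remainder: give one extra line each to as many donors as affordable
      extra <- if (k < max_k) {
        min(floor((budget - base_cost) / line_cost), m)
      } else 0
      k_list <- rep(k, m)
      if (extra > 0) k_list[seq_len(extra)] <- k + 1
      cost <- base_cost + extra * line_cost
      rep_ <- ess(k_list, rho)
      cand <- list(k_list = k_list, n_donors = m, cost = cost, ess = rep_)
      if (is.null(best) ||
          rep_$ess > best$ess$ess + 1e-9 ||
          (abs(rep_$ess - best$ess$ess) <= 1e-9 &&
           (rep_$n < best$ess$n ||
            (rep_$n == best$ess$n && m > best$n_donors)))) {
        best <- cand
      }
    }
  }
  best
}
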