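# Familial-relative-risk decomposition under a log-additive model, and
# per-variant effective sample sizes for frailty-scale heritability.

#' Per-variant contribution to the familial relative risk
#'
#' Under a log-additive risk model, variant j with allele frequency `p`,
#' log odds ratio `beta` and standard error `tau` contributes
#' `c_j = p (1 - p) (beta^2 - tau^2)` to the log familial relative risk.
#' Subtracting `tau^2` makes the contribution unbiased for
#' `p(1-p) beta_true^2` when `beta ~ N(beta_true, tau^2)`; contributions
#' can therefore be negative when `tau > |beta|` and are reported as such
#' (flooring at zero would bias sums upward).
#'
#' @param p effect-allele frequency in (0, 1); the expression is symmetric
#'   in `p` and `1 - p`, so minor- vs effect-allele coding is immaterial
#' @param beta log odds ratio
#' @param tau standard error of `beta`
#' @return numeric contribution(s), same length as the inputs
#' @export
frr_contribution <- function(p, beta, tau) {
  stopifnot(all(p > 0 & p < 1), all(tau > 0))
  p * (1 - p) * (beta^2 - tau^2)
}

#' Proportion of the familial relative risk explained by a variant set
#'
#' Sums per-variant contributions and divides by `ln(lambda)`, where
#' `lambda` is the overall familial relative risk of the disease (2 for
#' endometrial cancer). Additive over disjoint variant sets.
#'
#' @param p,beta,tau vectors as in [frr_contribution()]; `tau` may instead
#'   be derived from P-values via `p_values`
#' @param p_values optional two-sided P-values from which `tau` is derived
#'   via [se_from_p()]
#' @param lambda_frr familial relative risk (default 2), must exceed 1
#' @param variant_id optional labels for the per-variant table
#' @return object of class `frr`: list with `proportion`, `lambda_frr` and
#'   a per-variant `table`
#' @export
frr_proportion <- function(p, beta, tau = NULL, p_values = NULL,
                           lambda_frr = 2, variant_id = NULL) {
  if (lambda_frr <= 1) stop("lambda_frr must exceed 1")
  if (length(p) == 0) {
    return(structure(list(proportion = 0, lambda_frr = lambda_frr,
                          table = data.frame()), class = "frr"))
  }
  if (is.null(tau)) {
    if (is.null(p_values)) stop("supply tau or p_values")
    tau <- se_from_p(beta, p_values)
  }
  contrib <- frr_contribution(p, beta, tau)
  if (any(contrib < 0))
    warning(sum(contrib < 0),
            " variant(s) with tau > |beta| contribute negatively")
  tab <- data.frame(
    variant_id = if (is.null(variant_id)) seq_along(p) else variant_id,
    eaf = p, beta = beta, tau = tau, contribution = contrib,
    proportion = contrib / log(lambda_frr))
  structure(list(proportion = sum(contrib) / log(lambda_frr),
                 lambda_frr = lambda_frr, table = tab),
            class = "frr")
}

#' @export
print.frr <- function(x, ...) {
  cat(sprintf(
    "Proportion of familial relative risk explained (lambda = %g): %.2f%%\n",
    x$lambda_frr, 100 * x$proportion))
  cat("  variants:", nrow(x$table), "\n")
  invisible(x)
}

#' Effective sample size for frailty-scale heritability
#'
#' `N_j = 1 / (2 p_j (1 - p_j) tau_j^2)` weights each variant by its
#' frequency and the variance of its effect estimate; replacing the study
#' N with `N_j` in LD-score regression yields heritability on the frailty
#' scale.
#'
#' @param p effect-allele frequency in (0, 1)
#' @param tau standard error of the log odds ratio
#' @return effective sample size(s)
#' @export
effective_n <- function(p, tau) {
  stopifnot(all(p > 0 & p < 1), all(tau > 0))
  1 / (2 * p * (1 - p) * tau^2)
}

#' Convert frailty-scale heritability to the proportion of FRR explained
#'
#' `proportion = h2f / (2 ln(lambda))`.
#'
#' @param h2f frailty-scale heritability (non-negative)
#' @param lambda_frr familial relative risk (default 2)
#' @return proportion of the familial relative risk explained
#' @export
h2f_to_frr_proportion <- function(h2f, lambda_frr = 2) {
  stopifnot(all(h2f >= 0), lambda_frr > 1)
  h2f / (2 * log(lambda_frr))
}
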