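# Case-only heterogeneity of variant effects between disease subtypes,
# and the approximate summary-level subgroup contrast.

#' Case-only test of effect heterogeneity between subtypes
#'
#' Among cases only, regresses the subtype indicator on allele dosage by
#' logistic regression; the per-allele coefficient estimates the
#' difference between the subtype-specific case-control log odds ratios,
#' and its Wald test is the case-only heterogeneity test. A hard-call
#' 2x2 allele-count table with its conditional (exact) odds ratio is
#' attached as a diagnostic cross-check. If the subtypes are perfectly
#' separated by dosage the Wald test is invalid; the exact test on the
#' collapsed table is then used as fallback, with a warning.
#'
#' @param dosage per-case allele dosages in \[0, 2\] (or a data.frame with
#'   columns `dosage` and `subtype`)
#' @param subtype per-case subtype labels with exactly two levels; the
#'   second sorted level is coded 1
#' @return object of class `c("case_only_test", "htest")` with `estimate`
#'   (log OR per allele), `stderr`, `p.value`, the collapsed
#'   `allele_table`, and `exact_or`/`exact_p` from the conditional test
#' @export
case_only_test <- function(dosage, subtype = NULL) {
  if (is.data.frame(dosage)) {
    subtype <- dosage$subtype
    dosage <- dosage$dosage
  }
  stopifnot(length(dosage) == length(subtype),
            all(dosage >= 0 & dosage <= 2))
  lev <- sort(unique(as.character(subtype)))
  if (length(lev) != 2) stop("exactly two subtypes required")
  y <- as.integer(as.character(subtype) == lev[2])
  n_by <- table(factor(subtype, levels = lev))
  if (any(n_by < 10))
    warning("fewer than 10 cases in a subtype; test will be unstable")

  # hard-call allele-count 2x2 diagnostic (rows: subtype, cols: allele)
  alleles <- round(dosage)
  tab <- rbind(c(sum(alleles[y == 0]), 2 * sum(y == 0) - sum(alleles[y == 0])),
               c(sum(alleles[y == 1]), 2 * sum(y == 1) - sum(alleles[y == 1])))
  dimnames(tab) <- list(subtype = lev, allele = c("effect", "other"))
  # reversed rows so the exact OR is oriented as subtype-2 vs subtype-1,
  # matching the sign convention of the logistic coefficient
  exact <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    stats::fisher.test(tab[2:1, ]) else NULL

  fit <- suppressWarnings(
    stats::glm(y ~ dosage, family = stats::binomial()))
  co <- summary(fit)$coefficients
  separated <- !fit$converged || abs(co["dosage", "Estimate"]) > 15 ||
    co["dosage", "Std. Error"] > 1e3
  if (separated) {
    if (is.null(exact)) stop("separation with a degenerate allele table")
    warning("dosage separates the subtypes; falling back to the exact test")
    est <- log(unname(exact$estimate))
    se <- NA_real_
    pv <- exact$p.value
  } else {
    est <- co["dosage", "Estimate"]
    se <- co["dosage", "Std. Error"]
    pv <- 2 * stats::pnorm(-abs(est / se))
  }
  structure(list(
    statistic = c(z = est / se),
    estimate = c("log OR per allele" = est),
    stderr = se,
    p.value = pv,
    allele_table = tab,
    exact_or = if (!is.null(exact)) unname(exact$estimate) else NA_real_,
    exact_p = if (!is.null(exact)) exact$p.value else NA_real_,
    method = paste("Case-only logistic regression of subtype on dosage",
                   sprintf("(%s vs %s)", lev[2], lev[1])),
    data.name = deparse(substitute(dosage))),
    class = c("case_only_test", "htest"))
}

#' Approximate subgroup contrast from summary-level estimates
#'
#' Compares two subgroup log odds ratios via
#' `z = (beta1 - beta2) / sqrt(se1^2 + se2^2)`. Valid only when the
#' subgroup estimates are independent — subgroups analysed against a
#' shared control set violate this, so the result is labelled approximate
#' and should not replace the case-only test when individual-level data
#' exist.
#'
#' @param beta1,se1 log OR and standard error in subgroup 1
#' @param beta2,se2 log OR and standard error in subgroup 2
#' @return object of class `htest` with the difference, its SE and a
#'   two-sided P
#' @export
subgroup_contrast <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 > 0, se2 > 0)
  d <- beta1 - beta2
  se <- sqrt(se1^2 + se2^2)
  z <- d / se
  structure(list(
    statistic = c(z = z),
    estimate = c("difference in log OR" = d),
    stderr = se,
    p.value = 2 * stats::pnorm(-abs(z)),
    method = "Subgroup contrast (approximate: assumes independent subgroups)",
    data.name = "summary-level subgroup estimates"),
    class = "htest")
}
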