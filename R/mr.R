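# Two-sample inverse-variance-weighted Mendelian randomization and the
# multivariable extension for mediator adjustment.

.mr_table_check <- function(table, mediator = FALSE) {
  need <- c("bx", "by", "by_se")
  if (mediator) need <- c(need, "bx2")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("instrument table missing column(s): ", paste(miss, collapse = ", "))
  if (any(table$by_se <= 0)) stop("all outcome SEs must be positive")
  table
}

#' Two-sample inverse-variance-weighted Mendelian randomization
#'
#' Combines per-instrument Wald ratios `by/bx` with weights proportional
#' to `bx^2 / by_se^2` (fixed-effect weighting), equivalent to a
#' weighted regression of the outcome associations on the exposure
#' associations through the origin with weights `1/by_se^2`:
#' `theta = sum(bx by / by_se^2) / sum(bx^2 / by_se^2)`,
#' `se = 1 / sqrt(sum(bx^2 / by_se^2))`. Exposure-side standard errors do
#' not enter the weights (the standard two-sample IVW convention; no
#' measurement-error correction). Cochran's Q over instrument-level
#' ratios is reported; `random = TRUE` inflates the standard error by
#' `sqrt(Q/df)` when Q exceeds its degrees of freedom.
#'
#' @param table data.frame with columns `bx` (SNP-exposure effects), `by`,
#'   `by_se` (SNP-outcome effects and SEs, log-odds scale), optionally
#'   `snp`
#' @param random apply multiplicative random-effect SE inflation
#' @param unit_scale report the OR per this many exposure units
#' @return object of class `mr_estimate` with `theta`, `se`, `p`, `or`,
#'   `ci`, `q_stat`, `df`, `n_snps`, `model`
#' @export
mr_ivw <- function(table, random = FALSE, unit_scale = 1) {
  table <- .mr_table_check(table)
  n <- nrow(table)
  if (n < 1 || all(table$bx == 0)) stop("causal effect unidentified")
  if (n == 1) warning("single-instrument Wald ratio; no heterogeneity check")
  w <- 1 / table$by_se^2
  sxx <- sum(w * table$bx^2)
  theta <- sum(w * table$bx * table$by) / sxx
  se <- 1 / sqrt(sxx)
  q <- sum(w * (table$by - theta * table$bx)^2)
  df <- n - 1
  if (random && df > 0 && q > df) se <- se * sqrt(q / df)
  .mr_result(theta, se, q, df, n, unit_scale,
             model = if (random) "ivw_random" else "ivw_univariable")
}

#' Multivariable Mendelian randomization for two exposures
#'
#' Weighted least squares of the SNP-outcome associations on the two
#' SNP-exposure association columns without intercept, weights
#' `1/by_se^2`; the coefficient on the primary exposure is its direct
#' effect, net of the pathway through the second exposure (mediator).
#' Standard errors are fixed-effect, i.e. from `(X' W X)^{-1}` without
#' residual-variance scaling, matching [mr_ivw()] in the univariable
#' limit.
#'
#' @param table data.frame with `bx`, `bx2` (effects on exposure and
#'   mediator), `by`, `by_se`
#' @param unit_scale per-unit scale for the reported ORs
#' @return list with one `mr_estimate` per exposure (`exposure`,
#'   `mediator`) plus `rank` and `condition_number` diagnostics
#' @export
mr_mvivw <- function(table, unit_scale = 1) {
  table <- .mr_table_check(table, mediator = TRUE)
  n <- nrow(table)
  if (n < 3) stop("multivariable MR needs at least 3 instruments")
  if (all(table$bx2 == 0)) {
    # degenerate mediator: the model collapses to univariable IVW
    warning("all mediator effects are zero; reducing to univariable IVW")
    out <- list(exposure = mr_ivw(table, unit_scale = unit_scale),
                mediator = NULL, rank = 1L, condition_number = Inf)
    class(out) <- "mr_mv_estimate"
    return(out)
  }
  X <- cbind(bx = table$bx, bx2 = table$bx2)
  w <- 1 / table$by_se^2
  xtx <- crossprod(X * sqrt(w))
  qr_x <- qr(xtx)
  if (qr_x$rank < 2)
    stop("exposure-effect matrix is rank deficient; effects unidentifiable")
  kappa_x <- kappa(xtx, exact = TRUE)
  theta <- solve(xtx, crossprod(X, w * table$by))
  vc <- solve(xtx)
  fit <- drop(X %*% theta)
  q <- sum(w * (table$by - fit)^2)
  df <- n - 2
  out <- list(
    exposure = .mr_result(theta[1], sqrt(vc[1, 1]), q, df, n, unit_scale,
                          model = "multivariable"),
    mediator = .mr_result(theta[2], sqrt(vc[2, 2]), q, df, n, unit_scale,
                          model = "multivariable"),
    rank = qr_x$rank, condition_number = kappa_x)
  class(out) <- "mr_mv_estimate"
  out
}

.mr_result <- function(theta, se, q, df, n, unit_scale, model) {
  z <- theta / se
  structure(list(theta = theta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 or = exp(theta * unit_scale),
                 ci = exp((theta + c(-1, 1) * Z_975 * se) * unit_scale),
                 q_stat = q, df = df, n_snps = n,
                 unit_scale = unit_scale, model = model),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR (%s), %d instruments\n", x$model, x$n_snps))
  cat(sprintf("  theta = %.4f (se %.4f), OR per %g unit(s) = %.2f (%.2f, %.2f), P = %.3g\n",
              x$theta, x$se, x$unit_scale, x$or, x$ci[1], x$ci[2], x$p))
  if (x$df > 0)
    cat(sprintf("  instrument heterogeneity Q = %.2f on %d df\n",
                x$q_stat, x$df))
  invisible(x)
}

#' @export
print.mr_mv_estimate <- function(x, ...) {
  cat("Multivariable MR (direct effects)\n")
  cat("-- primary exposure --\n"); print(x$exposure)
  if (!is.null(x$mediator)) {
    cat("-- mediator --\n"); print(x$mediator)
  }
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) c(theta = object$theta)

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- object$theta + c(-1, 1) * zq * object$se
  matrix(ci, nrow = 1,
         dimnames = list("theta", sprintf("%g %%", c((1 - level) / 2,
                                                     1 - (1 - level) / 2) * 100)))
}

#' @export
summary.mr_estimate <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Rescale a causal log odds ratio to a per-unit odds ratio
#'
#' @param theta causal log OR per exposure unit
#' @param se its standard error
#' @param unit_scale number of exposure units (positive)
#' @return list with `or` and `ci` (95\%) on the `unit_scale` scale
#' @export
per_unit_or <- function(theta, se, unit_scale = 1) {
  stopifnot(unit_scale > 0, se >= 0)
  list(or = exp(theta * unit_scale),
       ci = exp((theta + c(-1, 1) * Z_975 * se) * unit_scale))
}
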