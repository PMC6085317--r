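# Stratified inverse-variance meta-analysis: per-stratum QC filters,
# fixed- and random-effects pooling, heterogeneity, genomic inflation.

#' Quality-control policy for stratum-level association results
#'
#' Defaults reproduce the exclusions applied in large case-control
#' consortium meta-analyses: a stratum result is dropped when its
#' imputation info score is below 0.4, its minor allele frequency (the
#' folded frequency `min(eaf, 1 - eaf)`) is below 0.005, or its odds ratio
#' falls outside (1/3, 3). After pooling, variants seen in fewer than two
#' strata or with between-strata heterogeneity P below 5e-8 are removed.
#' All bounds are strict inequalities; boundary values are retained.
#'
#' @param min_info minimum imputation info score
#' @param min_maf minimum folded (minor) allele frequency
#' @param max_or upper odds-ratio bound; the lower bound is `1/max_or`
#' @param min_strata minimum number of contributing strata after filtering
#' @param het_p_exclude post-meta heterogeneity P exclusion threshold
#' @return object of class `filter_policy`
#' @export
filter_policy <- function(min_info = 0.4, min_maf = 0.005, max_or = 3,
                          min_strata = 2, het_p_exclude = 5e-8) {
  stopifnot(min_info >= 0, min_maf > 0, max_or > 1,
            min_strata >= 1, het_p_exclude > 0)
  structure(list(min_info = min_info, min_maf = min_maf, max_or = max_or,
                 min_strata = min_strata, het_p_exclude = het_p_exclude),
            class = "filter_policy")
}

#' Apply per-stratum exclusion rules
#'
#' @param records stratum record data.frame
#' @param policy a [filter_policy()]
#' @return data.frame with logical `keep` and a comma-separated `reasons`
#'   column listing every triggered rule (`low_info`, `low_maf`,
#'   `extreme_or`)
#' @export
apply_stratum_filters <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  maf <- pmin(records$eaf, 1 - records$eaf)
  low_info <- records$info < policy$min_info
  low_maf <- maf < policy$min_maf
  # strict OR bounds, compared on the log scale so that beta = log(max_or)
  # sits exactly on the boundary and is retained
  extreme <- records$beta > log(policy$max_or) |
    records$beta < -log(policy$max_or)
  reasons <- mapply(function(a, b, c)
    paste(c("low_info", "low_maf", "extreme_or")[c(a, b, c)], collapse = ","),
    low_info, low_maf, extreme)
  data.frame(variant_id = records$variant_id,
             stratum_id = records$stratum_id,
             keep = !(low_info | low_maf | extreme),
             reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Fixed-effects inverse-variance-weighted pooling
#'
#' Weights are the reciprocal squared standard errors:
#' `w_k = 1/se_k^2`, `beta = sum(w*b)/sum(w)`, `se = 1/sqrt(sum(w))`,
#' with a two-sided normal P for the Wald statistic.
#'
#' @param betas per-stratum log odds ratios
#' @param ses per-stratum standard errors (all positive)
#' @return list with `beta`, `se`, `z`, `p`
#' @export
meta_ivw <- function(betas, ses) {
  if (length(betas) == 0) stop("no strata to pool")
  stopifnot(length(betas) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cochran's Q and the I-squared heterogeneity statistic
#'
#' `Q = sum(w_k (b_k - b_pooled)^2)` against chi-squared on K-1 degrees of
#' freedom; `I2 = max(0, (Q - df)/Q) * 100` (a percentage).
#'
#' @inheritParams meta_ivw
#' @return list with `q_stat`, `df`, `het_p`, `i2`
#' @export
meta_heterogeneity <- function(betas, ses) {
  k <- length(betas)
  if (k < 2) stop("heterogeneity is undefined for fewer than 2 strata")
  stopifnot(all(ses > 0))
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - pooled)^2)
  df <- k - 1
  list(q_stat = q, df = df,
       het_p = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0)
}

#' DerSimonian-Laird random-effects pooling
#'
#' The between-stratum variance is the moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effects weights `w`; pooling then uses `1/(se^2 + tau2)`.
#'
#' @inheritParams meta_ivw
#' @return list with `beta`, `se`, `tau2`, `z`, `p`
#' @export
meta_random <- function(betas, ses) {
  k <- length(betas)
  if (k < 2) stop("random-effects pooling needs at least 2 strata")
  het <- meta_heterogeneity(betas, ses)
  w <- 1 / ses^2
  tau2 <- max(0, (het$q_stat - het$df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  beta <- sum(wr * betas) / sum(wr)
  se <- 1 / sqrt(sum(wr))
  z <- beta / se
  list(beta = beta, se = se, tau2 = tau2, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Stratified GWAS meta-analysis
#'
#' Runs the full pooling pipeline over a set of harmonized strata: apply
#' the per-stratum filters of `policy`, pool surviving results per variant
#' by fixed-effects inverse-variance weighting (random-effects results are
#' computed alongside when `model = "random"`), then drop variants with
#' results in fewer than `policy$min_strata` strata or with between-strata
#' heterogeneity P below `policy$het_p_exclude`. Every exclusion is logged.
#'
#' @param strata list of stratum record data.frames (see
#'   [read_stratum_file()]), or a character vector of file paths
#' @param policy a [filter_policy()]
#' @param model `"fixed"` (default) or `"random"`; the heterogeneity
#'   columns are reported either way
#' @return object of class `meta_gwas`: a list with `results` (one row per
#'   retained variant: the canonical meta columns), `audit` (one row per
#'   dropped (variant, stratum) or variant with a reason code), `policy`,
#'   `model` and `n_strata`
#' @export
meta_gwas <- function(strata, policy = filter_policy(), model = "fixed") {
  model <- match.arg(model, c("fixed", "random"))
  if (is.character(strata)) strata <- lapply(strata, read_stratum_file)
  stopifnot(length(strata) >= 1, all(vapply(strata, is.data.frame, TRUE)))
  all_rec <- do.call(rbind, strata)
  # sort for order-invariance of the floating-point sums
  all_rec <- all_rec[order(all_rec$variant_id, all_rec$stratum_id), ]

  flt <- apply_stratum_filters(all_rec, policy)
  audit <- flt[!flt$keep, c("variant_id", "stratum_id", "reasons")]
  names(audit)[3] <- "reason"
  kept <- all_rec[flt$keep, , drop = FALSE]

  res <- list(); drop_log <- list()
  groups <- split(kept, kept$variant_id)
  for (vid in names(groups)) {
    g <- groups[[vid]]
    k <- nrow(g)
    if (k < policy$min_strata) {
      drop_log[[vid]] <- data.frame(variant_id = vid, stratum_id = NA,
                                    reason = "min_strata")
      next
    }
    het <- meta_heterogeneity(g$beta, g$se)
    if (het$het_p < policy$het_p_exclude) {
      drop_log[[vid]] <- data.frame(variant_id = vid, stratum_id = NA,
                                    reason = "heterogeneity")
      next
    }
    fit <- if (model == "fixed") meta_ivw(g$beta, g$se)
           else meta_random(g$beta, g$se)
    n_tot <- g$n_cases + g$n_controls
    eaf <- if (all(is.finite(n_tot))) sum(g$eaf * n_tot) / sum(n_tot)
           else mean(g$eaf)
    res[[vid]] <- data.frame(
      variant_id = vid, chrom = g$chrom[1], pos = g$pos[1],
      effect_allele = g$effect_allele[1], other_allele = g$other_allele[1],
      eaf = eaf, beta = fit$beta, se = fit$se, z = fit$z, p = fit$p,
      q_stat = het$q_stat, i2 = het$i2, het_p = het$het_p,
      n_strata_used = k, model = model, stringsAsFactors = FALSE)
  }
  results <- if (length(res)) do.call(rbind, res) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(.meta_cols))),
                    .meta_cols)
  if (!nrow(results)) warning("no variant had results in >= 2 strata")
  rownames(results) <- NULL
  audit <- rbind(audit, if (length(drop_log)) do.call(rbind, drop_log))
  rownames(audit) <- NULL
  structure(list(results = results, audit = audit, policy = policy,
                 model = model, n_strata = length(strata)),
            class = "meta_gwas")
}

#' @export
print.meta_gwas <- function(x, ...) {
  cat("Stratified GWAS meta-analysis (", x$model, "-effects)\n", sep = "")
  cat("  strata:", x$n_strata, "  variants retained:", nrow(x$results),
      "  exclusions logged:", nrow(x$audit), "\n")
  invisible(x)
}

#' @export
summary.meta_gwas <- function(object, p_threshold = 5e-8, ...) {
  r <- object$results
  sig <- r[r$p < p_threshold, , drop = FALSE]
  cat("Variants:", nrow(r), " genome-wide significant (P <",
      format(p_threshold), "):", nrow(sig), "\n")
  if (nrow(sig)) {
    sig <- sig[order(sig$p), ]
    print(utils::head(sig[, c("variant_id", "chrom", "pos", "beta", "se",
                              "p", "i2", "n_strata_used")], 10))
  }
  invisible(sig)
}

#' @export
coef.meta_gwas <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$variant_id)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)`, the ratio of the observed
#' median association chi-squared to its null expectation (0.4549364).
#'
#' @param z Wald z-statistics (used as `z^2` if `chi2` missing)
#' @param chi2 1-df chi-squared statistics
#' @return `lambda_raw`, a positive scalar
#' @export
lambda_gc <- function(z = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(z)) stop("supply z or chi2")
    chi2 <- z^2
  }
  if (!length(chi2)) stop("empty input")
  if (length(chi2) < 100)
    warning("fewer than 100 statistics; lambda estimate will be unstable")
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Rescale an inflation factor to 1000 cases and 1000 controls
#'
#' Inflation from residual stratification grows with effective sample
#' size, so studies are compared on the scale of a notional study of 1000
#' cases and 1000 controls:
#' `lambda_1000 = 1 + (lambda - 1) * (1/n_cases + 1/n_controls) / (2/1000)`.
#'
#' @param lambda_raw observed inflation factor
#' @param n_cases,n_controls sample sizes behind `lambda_raw`
#' @return the rescaled inflation factor
#' @export
lambda_1000 <- function(lambda_raw, n_cases, n_controls) {
  stopifnot(lambda_raw > 0, n_cases >= 1, n_controls >= 1)
  1 + (lambda_raw - 1) * (1 / n_cases + 1 / n_controls) / (1 / 1000 + 1 / 1000)
}
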