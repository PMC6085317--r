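# Risk-locus definition, approximate conditional/joint analysis against an
# LD reference, likelihood-ratio credible sets, and Wakefield ABF / BFDP.

.pick_lead <- function(members) {
  # deterministic: min P, ties -> min se, then lexicographic variant id
  ord <- order(members$p, members$se, members$variant_id)
  members[ord[1], , drop = FALSE]
}

#' Define risk loci from meta-analysis results
#'
#' Genome-wide-significant variants (P below `p_threshold`) seed windows of
#' `window` bp either side; overlapping windows on one chromosome are
#' merged into a single locus. Significant variants lying within `window`
#' bp of any previously reported lead in `exclude_regions` are removed
#' before clumping, so known loci are not rediscovered. Each locus reports
#' the lead variant (minimum P; ties broken by smaller se, then variant
#' id) and all meta records inside the merged window.
#'
#' @param meta a `meta_gwas` object or its `results` data.frame
#' @param p_threshold genome-wide significance threshold (default 5e-8)
#' @param window flank size in basepairs (default 500 kb)
#' @param exclude_regions optional data.frame with columns `chrom`, `pos`
#'   of known leads whose +/- `window` flanks are masked
#' @return list of loci of class `gwas_loci`; each locus is a list with
#'   `chrom`, `start`, `end`, `lead` (one-row data.frame), `members`
#'   (data.frame) and `secondary_signals` (NULL until
#'   [select_secondary_signals()] is run)
#' @export
define_loci <- function(meta, p_threshold = 5e-8, window = 5e5,
                        exclude_regions = NULL) {
  records <- if (inherits(meta, "meta_gwas")) meta$results else meta
  stopifnot(is.data.frame(records))
  sig <- records[records$p < p_threshold, , drop = FALSE]
  if (!is.null(exclude_regions) && nrow(sig)) {
    masked <- rep(FALSE, nrow(sig))
    for (i in seq_len(nrow(exclude_regions))) {
      masked <- masked |
        (sig$chrom == as.character(exclude_regions$chrom[i]) &
         abs(sig$pos - exclude_regions$pos[i]) <= window)
    }
    sig <- sig[!masked, , drop = FALSE]
  }
  if (!nrow(sig)) return(structure(list(), class = "gwas_loci"))

  loci <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    lo <- s$pos - window; hi <- s$pos + window
    grp <- cumsum(c(1, as.integer(lo[-1] > cummax(hi)[-length(hi)])))
    for (g in unique(grp)) {
      span <- c(min(lo[grp == g]), max(hi[grp == g]))
      members <- records[records$chrom == ch &
                         records$pos >= span[1] & records$pos <= span[2], ,
                         drop = FALSE]
      lead <- .pick_lead(members[members$p < p_threshold, , drop = FALSE])
      loci[[length(loci) + 1L]] <- list(
        chrom = ch, start = span[1], end = span[2],
        lead = lead, members = members, secondary_signals = NULL)
    }
  }
  ord <- order(vapply(loci, function(l) l$lead$p, numeric(1)))
  structure(loci[ord], class = "gwas_loci")
}

#' @export
print.gwas_loci <- function(x, ...) {
  cat("Risk loci:", length(x), "\n")
  for (l in x)
    cat(sprintf("  %s:%d-%d lead %s P=%.3g members=%d secondary=%d\n",
                l$chrom, l$start, l$end, l$lead$variant_id, l$lead$p,
                nrow(l$members),
                if (is.null(l$secondary_signals)) 0L
                else nrow(l$secondary_signals)))
  invisible(x)
}

.std_scale <- function(eaf) sqrt(2 * eaf * (1 - eaf))

.check_collinearity <- function(R, ids, cap_r2) {
  r2 <- R^2; diag(r2) <- 0
  if (any(r2 > cap_r2)) {
    ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    stop("collinear variants in conditional model (r2 = ",
         signif(max(r2), 3), " > ", cap_r2, "): ",
         ids[ij[1]], ", ", ids[ij[2]])
  }
}

#' Approximate conditional analysis from summary statistics
#'
#' Re-estimates each target variant's effect conditional on a set of index
#' variants, using only marginal summary statistics plus a reference LD
#' correlation matrix — the summary-data analogue of jointly fitting the
#' variants in an individual-level regression. Effects are standardized to
#' the unit-variance genotype scale via `sqrt(2p(1-p))`, the joint
#' coefficients solve the correlation-weighted normal equations on
#' \{condition set + target\}, and the target's coefficient and standard
#' error are transformed back to the per-allele scale. This linearizes the
#' logistic model, the standard approximation for summary-data joint
#' analysis; its error is quantified against an individual-level oracle in
#' the package tests.
#'
#' @param stats data.frame with columns `variant_id`, `beta`, `se`, `eaf`
#'   (marginal, harmonized to the LD reference's alleles)
#' @param ld an [ld_reference()] covering all variants used
#' @param condition_on character vector of variant ids to condition on
#'   (may be empty, in which case marginal results are returned)
#' @param targets variants to re-estimate (default: all not conditioned on)
#' @param collinearity_r2 refuse to solve systems containing a pair with
#'   squared correlation above this cap (default 0.9)
#' @return data.frame with `variant_id`, `beta_cond`, `se_cond`, `p_cond`
#'   and a logical `degenerate` column (TRUE when a target is itself in the
#'   condition set, for which the conditional effect is 0 by construction)
#' @export
conditional_joint <- function(stats, ld, condition_on = character(),
                              targets = NULL, collinearity_r2 = 0.9) {
  stopifnot(inherits(ld, "ld_reference"))
  if (is.null(targets))
    targets <- setdiff(stats$variant_id, condition_on)
  need <- unique(c(condition_on, targets))
  if (!all(need %in% ld$variant_ids))
    stop("variant(s) missing from LD reference: ",
         paste(utils::head(setdiff(need, ld$variant_ids), 5), collapse = ", "))
  if (!all(need %in% stats$variant_id))
    stop("variant(s) missing from summary stats")
  rownames(stats) <- stats$variant_id

  out <- lapply(targets, function(t) {
    if (t %in% condition_on)
      return(data.frame(variant_id = t, beta_cond = 0, se_cond = NA_real_,
                        p_cond = NA_real_, degenerate = TRUE))
    m <- c(condition_on, t)
    st <- stats[m, , drop = FALSE]
    s <- .std_scale(st$eaf)
    b <- st$beta * s            # standardized marginal effects
    v <- st$se * s              # their standard errors
    if (length(m) == 1) {
      a <- b; se_a <- v
    } else {
      R <- ld$correlation[m, m]
      .check_collinearity(R, m, collinearity_r2)
      Ri <- solve(R)
      a <- drop(Ri %*% b)
      # Cov(marginal b-hat) ~ D R D with D = diag(v); joint covariance
      # R^-1 D R D R^-1, reducing to diag(v^2) when R = I
      cv <- Ri %*% (v * t(v * R)) %*% Ri
      se_a <- sqrt(diag(cv))
    }
    i <- length(m)
    beta_c <- a[i] / s[i]; se_c <- se_a[i] / s[i]
    data.frame(variant_id = t, beta_cond = beta_c, se_cond = se_c,
               p_cond = 2 * stats::pnorm(-abs(beta_c / se_c)),
               degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Stepwise selection of secondary signals at a locus
#'
#' Starting from the lead variant, repeatedly conditions on the current
#' signal set and admits the best remaining variant when its conditional P
#' is below `p_threshold` and its squared LD correlation with every
#' selected signal is below `r2_max`; stops when no candidate qualifies.
#'
#' @param locus one locus from [define_loci()]
#' @param ld an [ld_reference()] covering the locus members to consider
#' @param p_threshold conditional significance threshold (default 5e-8)
#' @param r2_max maximum squared correlation allowed between reported
#'   signals (default 0.05)
#' @param collinearity_r2 passed to [conditional_joint()]
#' @return the locus with `secondary_signals` filled in (a data.frame of
#'   conditional estimates; zero rows when the locus has a single signal)
#' @export
select_secondary_signals <- function(locus, ld, p_threshold = 5e-8,
                                     r2_max = 0.05, collinearity_r2 = 0.9) {
  members <- locus$members[locus$members$variant_id %in% ld$variant_ids, ,
                           drop = FALSE]
  selected <- locus$lead$variant_id
  secondary <- data.frame(variant_id = character(), beta_cond = numeric(),
                          se_cond = numeric(), p_cond = numeric(),
                          stringsAsFactors = FALSE)
  repeat {
    cand <- setdiff(members$variant_id, selected)
    if (length(cand)) {
      r2 <- ld$correlation[cand, selected, drop = FALSE]^2
      cand <- cand[apply(r2 < r2_max, 1, all)]
    }
    if (!length(cand)) break
    cond <- conditional_joint(members, ld, condition_on = selected,
                              targets = cand,
                              collinearity_r2 = collinearity_r2)
    best <- cond[order(cond$p_cond), ][1, ]
    if (!is.finite(best$p_cond) || best$p_cond >= p_threshold) break
    selected <- c(selected, best$variant_id)
    secondary <- rbind(secondary,
                       best[, c("variant_id", "beta_cond", "se_cond",
                                "p_cond")])
  }
  rownames(secondary) <- NULL
  locus$secondary_signals <- secondary
  locus
}

#' Likelihood-ratio credible set for a locus
#'
#' The relative likelihood of each variant against the lead is the Wald
#' approximation `Lambda_j = exp((z_j^2 - z_lead^2)/2)`; variants within
#' `window` bp of the lead whose likelihood is no less than `lambda_min`
#' times the lead's (default odds 1:100) are flagged as credible causal
#' risk variants (ccrSNPs). The lead always has `Lambda = 1`.
#'
#' @param locus one locus from [define_loci()]
#' @param lambda_min inclusion threshold on the relative likelihood
#'   (default 0.01)
#' @param window maximum distance from the lead in bp (default 500 kb)
#' @return object of class `credible_set`: data.frame with `variant_id`,
#'   `z`, `lambda`, `ccr`, ordered by decreasing `lambda`, with the lead id
#'   as attribute `lead`
#' @export
credible_set <- function(locus, lambda_min = 0.01, window = 5e5) {
  m <- locus$members
  m <- m[abs(m$pos - locus$lead$pos) <= window, , drop = FALSE]
  z <- if ("z" %in% names(m)) m$z else m$beta / m$se
  z_lead <- z[m$variant_id == locus$lead$variant_id]
  lam <- exp((z^2 - z_lead^2) / 2)
  # guard against one-ulp misses at the published 1:100 boundary
  ccr <- lam >= lambda_min * (1 - 1e-9)
  out <- data.frame(variant_id = m$variant_id, z = z, lambda = lam,
                    ccr = ccr, stringsAsFactors = FALSE)
  out <- out[order(-out$lambda, out$variant_id), ]
  rownames(out) <- NULL
  structure(out, lead = locus$lead$variant_id,
            class = c("credible_set", "data.frame"))
}

#' Wakefield approximate Bayes factor and Bayesian false-discovery
#' probability
#'
#' For an estimated log odds ratio with variance `V`, the approximate
#' Bayes factor comparing the null to a `N(0, W)` alternative is
#' `ABF = sqrt((V + W)/V) * exp(-z^2 W / (2 (V + W)))`, and
#' `BFDP = ABF * PO / (ABF * PO + 1)` with prior odds of no association
#' `PO = (1 - pi)/pi`. The prior variance `W` is set so the maximum
#' plausible odds ratio is the prior's 97.5th percentile:
#' `W = (ln(max_plausible_or)/1.959964)^2`.
#'
#' Supply either `se` or `p`; with `p`, the standard error is derived via
#' [se_from_p()] (the convention used for printed-table reproduction).
#'
#' @param beta log odds ratio (or use `or`)
#' @param se standard error of `beta`
#' @param p two-sided P-value, used instead of `se` when given
#' @param or odds ratio, used instead of `beta` when given
#' @param pi prior probability of association (default 1e-4)
#' @param max_plausible_or 97.5th percentile of the prior OR (default 1.5)
#' @return object of class `bfdp` (a data.frame with `beta`, `V`, `W`,
#'   `z`, `abf`, `bfdp`), one row per variant
#' @export
bfdp <- function(beta = NULL, se = NULL, p = NULL, or = NULL,
                 pi = 1e-4, max_plausible_or = 1.5) {
  if (!is.null(or)) beta <- log(or)
  if (is.null(beta)) stop("supply beta or or")
  if (is.null(se)) {
    if (is.null(p)) stop("supply se or p")
    se <- se_from_p(beta, p)
  }
  stopifnot(all(is.finite(beta)), all(se > 0), pi > 0, pi < 1,
            max_plausible_or > 1)
  V <- se^2
  W <- (log(max_plausible_or) / Z_975)^2
  z <- beta / se
  abf <- sqrt((V + W) / V) * exp(-z^2 * W / (2 * (V + W)))
  po <- (1 - pi) / pi
  res <- data.frame(beta = beta, V = V, W = W, z = z, abf = abf,
                    bfdp = abf * po / (abf * po + 1))
  class(res) <- c("bfdp", "data.frame")
  res
}

#' @export
print.bfdp <- function(x, ...) {
  y <- as.data.frame(x)
  y$bfdp_pct <- sprintf("%.1f%%", 100 * y$bfdp)
  print(y[, c("beta", "z", "abf", "bfdp_pct")], ...)
  invisible(x)
}
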