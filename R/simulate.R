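# Simulators for every input the pipeline consumes: stratified summary
# statistics with known truth, LD blocks with individual-level data, MR
# instrument tables, case-only genotype sets, and feature BEDs.

#' Configuration for the stratified summary-statistic simulator
#'
#' Defaults emulate a 17-stratum endometrial-cancer-scale case-control
#' meta-analysis: 12,906 cases and 108,979 controls split into one large
#' array-consortium stratum, a biobank stratum with a very large control
#' excess, two medium consortium strata, a small matched study, and twelve
#' further strata sharing the remainder evenly.
#'
#' @param seed integer seed; a fixed seed gives identical output
#' @param n_strata number of strata
#' @param n_cases,n_controls per-stratum counts (recycled to `n_strata`)
#' @param n_variants number of variants
#' @param fraction_causal fraction of variants with nonzero true effect
#' @param true_beta_mean,true_beta_sd normal law of causal log ORs
#' @param eaf_bounds uniform bounds for allele frequencies, inside (0, 1)
#' @param info_bounds uniform bounds for imputation info, inside (0, 1\]
#' @param missing_rate per-(variant, stratum) Bernoulli missingness
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_strata = 17L,
                       n_cases = c(4710L, 636L, 2271L, 424L, 288L,
                                   rep(381L, 11), 386L),
                       n_controls = c(19438L, 62853L, 2219L, 558L, 1440L,
                                      rep(1872L, 11), 1879L),
                       n_variants = 1000L,
                       fraction_causal = 0.01,
                       true_beta_mean = 0,
                       true_beta_sd = 0.1,
                       eaf_bounds = c(0.05, 0.95),
                       info_bounds = c(0.7, 1),
                       missing_rate = 0.02) {
  n_cases <- rep_len(n_cases, n_strata)
  n_controls <- rep_len(n_controls, n_strata)
  stopifnot(n_strata >= 1, n_variants >= 1,
            all(n_cases >= 1), all(n_controls >= 1),
            fraction_causal >= 0, fraction_causal <= 1,
            missing_rate >= 0, missing_rate < 1,
            info_bounds[1] > 0, info_bounds[2] <= 1)
  if (eaf_bounds[1] <= 0 || eaf_bounds[2] >= 1)
    stop("eaf bounds must lie strictly inside (0, 1)")
  structure(list(seed = as.integer(seed), n_strata = as.integer(n_strata),
                 n_cases = n_cases, n_controls = n_controls,
                 n_variants = as.integer(n_variants),
                 fraction_causal = fraction_causal,
                 true_beta_mean = true_beta_mean,
                 true_beta_sd = true_beta_sd,
                 eaf_bounds = eaf_bounds, info_bounds = info_bounds,
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Simulate stratified case-control summary statistics with known truth
#'
#' For variant j in stratum k, the sampling variance follows the
#' case-control effective-sample-size relation
#' `tau2_jk = 1 / (2 p_j (1 - p_j) info_jk * n_eff_k)` with
#' `n_eff_k = n_cases_k n_controls_k / (n_cases_k + n_controls_k)`, and
#' the estimate is drawn `beta_hat ~ N(true_beta_j, tau2_jk)`. A
#' `missing_rate` fraction of (variant, stratum) pairs is dropped so the
#' minimum-strata filter is exercised.
#'
#' @param config a [sim_config()]
#' @return list with `strata` (per-stratum record data.frames as produced
#'   by [read_stratum_file()]) and `truth` (data.frame `variant_id`,
#'   `eaf`, `causal`, `true_beta`)
#' @export
simulate_stratum_sumstats <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nv <- config$n_variants
  ids <- sprintf("v%05d", seq_len(nv))
  eaf <- stats::runif(nv, config$eaf_bounds[1], config$eaf_bounds[2])
  causal <- stats::runif(nv) < config$fraction_causal
  true_beta <- ifelse(causal,
                      stats::rnorm(nv, config$true_beta_mean,
                                   config$true_beta_sd), 0)
  truth <- data.frame(variant_id = ids, eaf = eaf, causal = causal,
                      true_beta = true_beta, stringsAsFactors = FALSE)
  strata <- vector("list", config$n_strata)
  for (k in seq_len(config$n_strata)) {
    nca <- config$n_cases[k]; nco <- config$n_controls[k]
    neff <- nca * nco / (nca + nco)
    info <- stats::runif(nv, config$info_bounds[1], config$info_bounds[2])
    tau2 <- 1 / (2 * eaf * (1 - eaf) * info * neff)
    beta_hat <- stats::rnorm(nv, true_beta, sqrt(tau2))
    keep <- stats::runif(nv) >= config$missing_rate
    se <- sqrt(tau2)
    strata[[k]] <- data.frame(
      variant_id = ids, chrom = "1", pos = seq_len(nv) * 1000L,
      effect_allele = "A", other_allele = "G",
      eaf = eaf, beta = beta_hat, se = se,
      p = 2 * stats::pnorm(-abs(beta_hat / se)),
      info = info, n_cases = nca, n_controls = nco,
      stratum_id = sprintf("stratum%02d", k),
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(strata[[k]]) <- NULL
  }
  list(strata = strata, truth = truth)
}

#' Simulate an LD block with individual-level genotypes
#'
#' Haplotypes are latent AR(1) Gaussians with autocorrelation
#' `rho^|i-j|`, thresholded at the allele-frequency quantile; dosages sum
#' two haplotypes per individual. A quantitative phenotype
#' `y = X b + N(0, 1)` is generated, marginal per-variant regressions
#' supply the summary statistics, and the empirical dosage correlation
#' matrix becomes the LD reference — the individual-level data serve as
#' the oracle for summary-level conditional analysis.
#'
#' @param m number of variants (>= 2)
#' @param rho latent autocorrelation, |rho| < 1
#' @param n_individuals sample size; must be at least `m + 2` so the
#'   joint fit is identifiable
#' @param true_betas per-allele effects (length `m`)
#' @param eaf effect-allele frequencies (recycled to `m`)
#' @param seed integer seed
#' @return list with `genotypes` (n x m dosage matrix), `phenotype`,
#'   `sumstats` (marginal `variant_id`, `eaf`, `beta`, `se`, `p`), and
#'   `ld` (an [ld_reference()])
#' @export
simulate_ld_block <- function(m, rho, n_individuals, true_betas,
                              eaf = 0.3, seed = 1L) {
  stopifnot(m >= 2, abs(rho) < 1, length(true_betas) == m)
  if (n_individuals < m + 2)
    stop("n_individuals must be at least m + 2 for an identifiable joint fit")
  eaf <- rep_len(eaf, m)
  stopifnot(all(eaf > 0 & eaf < 1))
  set.seed(seed)
  nh <- 2L * n_individuals
  z <- matrix(0, nh, m)
  z[, 1] <- stats::rnorm(nh)
  if (m > 1) for (j in 2:m)
    z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(nh)
  h <- sweep(z, 2, stats::qnorm(eaf), "<") + 0
  X <- h[seq_len(n_individuals), ] + h[n_individuals + seq_len(n_individuals), ]
  y <- drop(X %*% true_betas) + stats::rnorm(n_individuals)

  n <- n_individuals
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  if (any(sxx == 0)) stop("monomorphic variant simulated; adjust eaf or n")
  sxy <- drop(crossprod(xc, yc))
  b <- sxy / sxx
  sigma2 <- (sum(yc^2) - b * sxy) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  ids <- sprintf("snp%02d", seq_len(m))
  sumstats <- data.frame(
    variant_id = ids, eaf = colMeans(X) / 2, beta = b, se = se,
    p = 2 * stats::pt(-abs(b / se), df = n - 2), stringsAsFactors = FALSE)
  colnames(X) <- ids
  list(genotypes = X, phenotype = y, sumstats = sumstats,
       ld = ld_reference(ids, stats::cor(X), n))
}

#' Simulate a two-sample MR instrument table with known causal structure
#'
#' Instrument effects on the exposure are drawn, effects on a mediator
#' follow a linear path from the exposure effects plus an independent
#' component, and outcome effects are
#' `by = theta * bx + mediator_slope * bx2 + pleiotropy`, observed with
#' sampling noise at the stated standard errors. The defaults mirror a
#' menarche-BMI-like mediation design: 368 instruments, a protective
#' direct effect, and a strong mediator effect, so the total (univariable)
#' slope is `theta + mediator_slope * exposure_mediator_effect`.
#'
#' @param n_snps number of instruments (>= 2)
#' @param theta direct causal slope of the exposure on the outcome (log
#'   OR per exposure unit)
#' @param mediator_slope causal slope of the mediator on the outcome
#' @param exposure_mediator_effect linear path from instrument-exposure
#'   effects to instrument-mediator effects
#' @param mediator_indep_sd sd of the mediator-effect component
#'   independent of the exposure (keeps multivariable MR identifiable)
#' @param pleiotropy_sd sd of direct instrument-outcome pleiotropy
#' @param se_bx,se_by sampling standard errors of the observed exposure
#'   and outcome associations
#' @param seed integer seed
#' @return list with `table` (columns `snp`, `bx`, `bx_se`, `by`,
#'   `by_se`, `bx2`, `bx2_se`) and `truth` (`theta_direct`,
#'   `mediator_slope`, `theta_total`)
#' @export
simulate_mr_instruments <- function(n_snps = 368L,
                                    theta = log(0.88),
                                    mediator_slope = log(1.92),
                                    exposure_mediator_effect = -0.108,
                                    mediator_indep_sd = 0.02,
                                    pleiotropy_sd = 0,
                                    se_bx = 0.004, se_by = 0.02,
                                    seed = 1L) {
  stopifnot(n_snps >= 2, se_bx > 0, se_by > 0)
  set.seed(seed)
  bx_true <- stats::runif(n_snps, 0.02, 0.1) *
    sample(c(-1, 1), n_snps, replace = TRUE)
  bx2_true <- exposure_mediator_effect * bx_true +
    stats::rnorm(n_snps, 0, mediator_indep_sd)
  by_true <- theta * bx_true + mediator_slope * bx2_true +
    stats::rnorm(n_snps, 0, pleiotropy_sd)
  table <- data.frame(
    snp = sprintf("iv%04d", seq_len(n_snps)),
    bx = bx_true + stats::rnorm(n_snps, 0, se_bx),
    bx_se = se_bx,
    by = by_true + stats::rnorm(n_snps, 0, se_by),
    by_se = se_by,
    bx2 = bx2_true + stats::rnorm(n_snps, 0, se_bx),
    bx2_se = se_bx,
    stringsAsFactors = FALSE)
  list(table = table,
       truth = list(theta_direct = theta,
                    mediator_slope = mediator_slope,
                    theta_total = theta +
                      mediator_slope * exposure_mediator_effect))
}

#' Simulate a case-only genotype set with subtype-specific effects
#'
#' Subtype A dosages are binomial(2, `eaf`); subtype B dosages use the
#' allele frequency shifted by `subtype_log_or` on the logit of the
#' per-allele probability, so `subtype_log_or` is the estimand of the
#' case-only test.
#'
#' @param n_cases_a,n_cases_b cases per subtype (>= 10)
#' @param eaf effect-allele frequency in subtype A
#' @param subtype_log_or per-allele log odds ratio between subtypes
#' @param seed integer seed
#' @return data.frame with `case_id`, `dosage`, `subtype`; the truth is
#'   attached as attribute `truth`
#' @export
simulate_case_only <- function(n_cases_a, n_cases_b, eaf, subtype_log_or,
                               seed = 1L) {
  stopifnot(n_cases_a >= 10, n_cases_b >= 10, eaf > 0, eaf < 1)
  set.seed(seed)
  p_b <- stats::plogis(stats::qlogis(eaf) + subtype_log_or)
  out <- data.frame(
    case_id = sprintf("case%05d", seq_len(n_cases_a + n_cases_b)),
    dosage = c(stats::rbinom(n_cases_a, 2, eaf),
               stats::rbinom(n_cases_b, 2, p_b)),
    subtype = rep(c("A", "B"), c(n_cases_a, n_cases_b)),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(subtype_log_or = subtype_log_or,
                             eaf_a = eaf, eaf_b = p_b)
  out
}

#' Simulate a BED file of feature intervals
#'
#' Interval widths are geometric around `mean_width` (minimum 1 bp),
#' starts are uniform; output is sorted, 0-based half-open and clipped to
#' `[0, genome_length)`.
#'
#' @param n_intervals number of intervals (0 gives an empty set)
#' @param genome_length chromosome length in bp
#' @param mean_width mean interval width in bp
#' @param seed integer seed
#' @param chrom chromosome name
#' @param path optional path; when given the intervals are written as a
#'   3-column BED file
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open)
#' @export
simulate_feature_bed <- function(n_intervals, genome_length, mean_width,
                                 seed = 1L, chrom = "chr1", path = NULL) {
  stopifnot(n_intervals >= 0, genome_length > 0, mean_width > 0)
  set.seed(seed)
  if (n_intervals == 0) {
    bed <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  } else {
    width <- 1L + stats::rgeom(n_intervals, 1 / mean_width)
    start <- floor(stats::runif(n_intervals, 0, genome_length - width))
    end <- pmin(start + width, genome_length)
    bed <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), stringsAsFactors = FALSE)
    bed <- bed[order(bed$start, bed$end), , drop = FALSE]
    rownames(bed) <- NULL
  }
  if (!is.null(path))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  bed
}
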