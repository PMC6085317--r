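# helpers to build small meta-result tables for clumping tests
meta_row <- function(id, chrom, pos, p, beta = 0.2, se = NULL) {
  if (is.null(se)) se <- abs(beta) / qnorm(1 - p / 2)
  data.frame(variant_id = id, chrom = chrom, pos = pos,
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = beta, se = se, z = beta / se, p = p,
             q_stat = 0, i2 = 0, het_p = 1, n_strata_used = 5L,
             model = "fixed", stringsAsFactors = FALSE)
}

test_that("locus definition merges windows, excludes known flanks, picks leads", {
  m <- rbind(
    meta_row("a", "1", 1e6, 1e-9),
    meta_row("b", "1", 1.4e6, 1e-10),   # 400 kb from a: same locus
    meta_row("c", "1", 5e6, 1e-12),     # far away: own locus
    meta_row("d", "2", 1e6, 1e-3))      # not significant
  loci <- define_loci(m)
  expect_length(loci, 2)
  # loci are ordered by lead P; the chr1:5Mb signal is strongest
  expect_equal(loci[[1]]$lead$variant_id, "c")
  expect_equal(loci[[2]]$lead$variant_id, "b")
  expect_setequal(loci[[2]]$members$variant_id, c("a", "b"))

  # a significant variant 100 kb from a known lead yields no locus
  known <- data.frame(chrom = "1", pos = 1.1e6)
  loci2 <- define_loci(m[1:2, ], exclude_regions = known)
  expect_length(loci2, 0)

  # lead tie-breaking: equal P, smaller se wins; then lexicographic id
  tie <- rbind(meta_row("x2", "3", 1e6, 1e-9, se = 0.02),
               meta_row("x1", "3", 1.1e6, 1e-9, se = 0.01),
               meta_row("x0", "3", 1.2e6, 1e-9, se = 0.01))
  expect_equal(define_loci(tie)[[1]]$lead$variant_id, "x0")
})

test_that("a synthetic genome with 9 planted signals yields exactly 9 loci", {
  set.seed(101)
  planted <- lapply(1:9, function(i)
    meta_row(sprintf("hit%d", i), as.character(i), 10e6 + i * 3e6, 1e-10))
  noise <- lapply(1:200, function(i)
    meta_row(sprintf("bg%03d", i), as.character(sample(1:9, 1)),
             runif(1, 1, 9e6), runif(1, 1e-6, 1)))
  m <- do.call(rbind, c(planted, noise))
  loci <- define_loci(m)
  expect_length(loci, 9)
  expect_setequal(vapply(loci, function(l) l$lead$variant_id, ""),
                  sprintf("hit%d", 1:9))
})

test_that("conditional analysis reduces to marginal under orthogonal LD", {
  stats <- data.frame(variant_id = c("s1", "s2", "s3"),
                      beta = c(0.2, 0.1, -0.05), se = c(0.02, 0.03, 0.04),
                      eaf = c(0.3, 0.5, 0.2), stringsAsFactors = FALSE)
  ld <- ld_reference(stats$variant_id, diag(3))
  cond <- conditional_joint(stats, ld, condition_on = "s1")
  expect_equal(cond$beta_cond, stats$beta[2:3], tolerance = 1e-10)
  expect_equal(cond$se_cond, stats$se[2:3], tolerance = 1e-10)

  # conditioning a variant on itself is degenerate with a zero effect
  self <- conditional_joint(stats, ld, condition_on = "s1", targets = "s1")
  expect_true(self$degenerate)
  expect_equal(self$beta_cond, 0)

  # collinearity guard names the offending pair
  R <- matrix(c(1, 0.99, 0.99, 1), 2)
  ld2 <- ld_reference(c("a", "b"), R)
  st2 <- data.frame(variant_id = c("a", "b"), beta = c(0.1, 0.1),
                    se = 0.02, eaf = 0.4)
  expect_error(conditional_joint(st2, ld2, condition_on = "a"),
               "collinear")
})

test_that("summary-level conditional estimates match the individual-level joint fit", {
  hits <- 0; total <- 0
  for (rep in 1:25) {
    blk <- simulate_ld_block(5, 0.5, 5000,
                             c(0.15, 0, 0.1, 0, 0), eaf = 0.3,
                             seed = 1000 + rep)
    cond <- conditional_joint(blk$sumstats, blk$ld, condition_on = "snp01")
    for (t in cond$variant_id) {
      X <- cbind(1, blk$genotypes[, c("snp01", t)])
      fit <- lm.fit(X, blk$phenotype)
      res <- blk$phenotype - X %*% fit$coefficients
      s2 <- sum(res^2) / (nrow(X) - 3)
      vc <- s2 * chol2inv(chol(crossprod(X)))
      joint_b <- fit$coefficients[3]; joint_se <- sqrt(vc[3, 3])
      total <- total + 1
      hits <- hits + (abs(cond$beta_cond[cond$variant_id == t] - joint_b)
                      <= 3 * joint_se)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("stepwise secondary-signal selection follows the r2 and P rules", {
  # one causal signal: nothing secondary is admitted
  blk1 <- simulate_ld_block(4, 0.3, 8000, c(0.2, 0, 0, 0), eaf = 0.3,
                            seed = 41)
  locus1 <- list(lead = blk1$sumstats[which.min(blk1$sumstats$p), ],
                 members = blk1$sumstats)
  out1 <- select_secondary_signals(locus1, blk1$ld)
  expect_equal(nrow(out1$secondary_signals), 0)

  # two nearly uncorrelated planted signals: both reported
  blk2 <- simulate_ld_block(4, 0.1, 8000, c(0.2, 0, 0, 0.2), eaf = 0.3,
                            seed = 42)
  expect_lt(max(blk2$ld$correlation[1, 4]^2), 0.05)
  locus2 <- list(lead = blk2$sumstats[which.min(blk2$sumstats$p), ],
                 members = blk2$sumstats)
  out2 <- select_secondary_signals(locus2, blk2$ld)
  expect_equal(nrow(out2$secondary_signals), 1)
  got <- c(out2$lead$variant_id, out2$secondary_signals$variant_id)
  expect_setequal(got, c("snp01", "snp04"))

  # correlated pair (r2 > 0.05): only the stronger survives
  blk3 <- simulate_ld_block(2, 0.55, 8000, c(0.2, 0.2), eaf = 0.3,
                            seed = 43)
  expect_gt(blk3$ld$correlation[1, 2]^2, 0.05)
  locus3 <- list(lead = blk3$sumstats[which.min(blk3$sumstats$p), ],
                 members = blk3$sumstats)
  out3 <- select_secondary_signals(locus3, blk3$ld)
  expect_equal(nrow(out3$secondary_signals), 0)
})

test_that("credible sets implement the 1:100 likelihood-ratio rule", {
  z_lead <- 6
  z_edge <- sqrt(z_lead^2 - 2 * log(100))   # relative likelihood exactly 0.01
  members <- rbind(
    meta_row("lead", "1", 1e6, 2 * pnorm(-6), beta = 0.3, se = 0.05),
    meta_row("edge", "1", 1.1e6, 0.5, beta = z_edge * 0.05, se = 0.05),
    meta_row("null", "1", 1.2e6, 0.5, beta = 0, se = 0.05),
    meta_row("far", "1", 1.7e6, 0.5, beta = 0.29, se = 0.05))
  members$z <- members$beta / members$se
  locus <- list(lead = members[1, ], members = members)
  cs <- credible_set(locus)
  expect_equal(cs$lambda[cs$variant_id == "lead"], 1)
  expect_true(cs$ccr[cs$variant_id == "lead"])
  # boundary: "no less than one hundredth" includes lambda = 0.01
  expect_equal(cs$lambda[cs$variant_id == "edge"], 0.01, tolerance = 1e-9)
  expect_true(cs$ccr[cs$variant_id == "edge"])
  expect_false(cs$ccr[cs$variant_id == "null"])
  # variants beyond 500 kb of the lead are not considered
  expect_false("far" %in% cs$variant_id)

  # set size is non-increasing in the threshold and matches brute force
  for (thr in c(0.001, 0.01, 0.1, 0.5)) {
    cs_t <- credible_set(locus, lambda_min = thr)
    in_win <- members[abs(members$pos - members$pos[1]) <= 5e5, ]
    brute <- exp((in_win$z^2 - 36) / 2) >= thr * (1 - 1e-9)
    expect_equal(sum(cs_t$ccr), sum(brute))
  }
  sizes <- vapply(c(0.001, 0.01, 0.1, 0.5),
                  function(t) sum(credible_set(locus, lambda_min = t)$ccr), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("BFDP reproduces published worked examples and its limits", {
  # non-replicating variant: OR 1.07, P 6.3e-5 printed as BFDP 98%
  expect_lt(abs(bfdp(or = 1.07, p = 6.3e-5)$bfdp - 0.98), 0.01)
  # novel locus with printed BFDP 2%: OR 1.23, P 3.6e-8
  expect_lt(abs(bfdp(or = 1.23, p = 3.6e-8)$bfdp - 0.02), 0.005)

  # monotone decreasing in |z| at fixed V and W
  V <- 0.02^2
  zs <- seq(0, 8, by = 0.5)
  vals <- bfdp(beta = zs * 0.02, se = rep(0.02, length(zs)))$bfdp
  expect_true(all(diff(vals) < 0))
  # at z = 0 the posterior is dominated by the tiny prior
  expect_gt(vals[1], 1 - 1e-4)
  # huge |z| kills the null
  expect_lt(bfdp(beta = 0.4, se = 0.02)$bfdp, 1e-10)
})
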