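test_that("OR/CI and P conversions to the log-odds scale are correct", {
  # printed-table style input: OR 1.15 (1.12, 1.19)
  conv <- or_ci_to_beta(1.15, 1.12, 1.19)
  expect_equal(conv$beta, 0.1398, tolerance = 1e-3)
  expect_equal(conv$se, (log(1.19) - log(1.12)) / 3.919928, tolerance = 1e-6)
  expect_equal(conv$se, 0.0155, tolerance = 1e-2)

  # OR of 1 with a symmetric CI is the null
  expect_equal(or_ci_to_beta(1, 1 / 1.1, 1.1)$beta, 0)

  # P-derived se against an independently computed inverse-normal value
  # (frozen from scipy.stats.norm.isf(5.5e-11))
  expect_equal(se_from_p(log(1.10), 1.1e-10), 0.014770984168983082,
               tolerance = 1e-12)
})

test_that("CI-derived and P-derived standard errors agree on consistent records", {
  set.seed(42)
  for (i in 1:50) {
    beta <- runif(1, 0.02, 0.5) * sample(c(-1, 1), 1)
    se <- runif(1, 0.01, 0.1)
    ci <- exp(beta + c(-1, 1) * 1.959964 * se)
    p <- 2 * pnorm(-abs(beta / se))
    se_ci <- or_ci_to_beta(exp(beta), ci[1], ci[2])$se
    se_p <- se_from_p(beta, p)
    expect_lt(abs(se_ci - se) / se, 0.02)
    expect_lt(abs(se_p - se) / se, 0.02)
  }
})

test_that("read_stratum_file converts dialects, validates and reports bad rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    snp = c("rs1", "rs2", "rs3"), chr = c("1", "1", "2"),
    bp = c(100L, 200L, 300L), ea = c("A", "C", "T"), oa = c("G", "T", "A"),
    eaf = c(0.3, 1.2, 0.5),              # rs2 has an impossible frequency
    or = c(1.15, 1.10, 0.9), oci_l = c(1.12, 1.05, 0.85),
    oci_u = c(1.19, 1.15, 0.95),
    info = c(0.9, 1, 1), ncases = 1000L, ncontrols = 2000L)
  write_stratum_fixture(df, tmp)
  expect_warning(rec <- read_stratum_file(tmp, stratum_id = "s1"),
                 "failed validation")
  expect_equal(nrow(rec), 2)
  rej <- attr(rec, "rejected")
  expect_equal(rej$variant_id, "rs2")
  expect_match(rej$reason, "eaf_out_of_range")
  expect_equal(rec$beta[rec$variant_id == "rs1"], log(1.15))
  expect_equal(rec$se[rec$variant_id == "rs1"],
               (log(1.19) - log(1.12)) / (2 * 1.959964))
  expect_equal(rec$stratum_id, rep("s1", 2))

  # OR + P dialect: se re-derived from the P-value
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  df2 <- data.frame(snp = "rs9", chr = "3", bp = 1L, ea = "A", oa = "G",
                    eaf = 0.2, or = 1.10, p = 1.1e-10, info = 1,
                    ncases = 500L, ncontrols = 500L)
  write_stratum_fixture(df2, tmp2)
  rec2 <- read_stratum_file(tmp2)
  expect_equal(rec2$se, se_from_p(log(1.10), 1.1e-10))

  # missing mandatory column is a hard format error
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write_stratum_fixture(df2[, setdiff(names(df2), "eaf")], tmp3)
  expect_error(read_stratum_file(tmp3), "eaf")

  # absent info column defaults to genotyped with a warning
  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  write_stratum_fixture(df2[, setdiff(names(df2), "info")], tmp4)
  expect_warning(rec4 <- read_stratum_file(tmp4), "info")
  expect_equal(rec4$info, 1)
})

test_that("allele harmonization flips, complements and flags ambiguity", {
  ref <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                    effect_allele = c("G", "A", "T", "C"),
                    other_allele = c("A", "G", "A", "G"))
  rec <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = 1:4,
    effect_allele = c("A", "A", "T", "G"),   # rs1 swapped, rs4 on - strand
    other_allele = c("G", "G", "A", "C"),
    eaf = c(0.3, 0.25, 0.5, 0.2), beta = c(0.1, 0.2, 0.05, 0.3),
    se = 0.05, p = 0.5, info = 1, n_cases = 10L, n_controls = 10L,
    stratum_id = "s", stringsAsFactors = FALSE)
  h <- harmonize_alleles(rec, ref)
  expect_equal(h$beta, c(-0.1, 0.2, 0.05, -0.3))
  expect_equal(h$eaf, c(0.7, 0.25, 0.5, 0.8))
  expect_equal(h$effect_allele, ref$effect_allele)
  # rs3 is an A/T pair with eaf 0.5: strand-ambiguous
  expect_equal(h$ambiguous, c(FALSE, FALSE, TRUE, FALSE))

  bad <- rec[1, ]; bad$effect_allele <- "A"; bad$other_allele <- "C"
  expect_error(harmonize_alleles(bad, ref), "incompatible")
})

test_that("meta files round-trip exactly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), effect_allele = character(),
                      other_allele = character(), eaf = numeric(),
                      beta = numeric(), se = numeric(), z = numeric(),
                      p = numeric(), q_stat = numeric(), i2 = numeric(),
                      het_p = numeric(), n_strata_used = integer(),
                      model = character(), stringsAsFactors = FALSE)
  write_meta_file(empty, tmp)
  expect_equal(nrow(read_meta_file(tmp)), 0)

  set.seed(7)
  n <- 1000
  rec <- data.frame(
    variant_id = sprintf("rs%04d", 1:n), chrom = as.character(1:22)[1 + (1:n) %% 22],
    pos = sample.int(1e8, n), effect_allele = "A", other_allele = "G",
    eaf = runif(n, 0.01, 0.99), beta = rnorm(n, 0, 0.2),
    se = runif(n, 0.01, 0.3), z = rnorm(n), p = runif(n),
    q_stat = rchisq(n, 16), i2 = runif(n, 0, 100), het_p = runif(n),
    n_strata_used = sample(2:17, n, TRUE), model = "fixed",
    stringsAsFactors = FALSE)
  write_meta_file(rec, tmp)
  back <- read_meta_file(tmp)
  expect_equal(back, rec)
})
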