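# Independent oracles used across the suite. These deliberately use naive
# algorithms (direct matrix solves, O(n*m) scans, full enumeration) so the
# package's optimized paths are checked against something they do not share
# code with.

# generalized-least-squares pooling of independent estimates (design = 1)
gls_pool_oracle <- function(betas, ses) {
  V <- diag(ses^2, nrow = length(ses))
  one <- rep(1, length(betas))
  vi <- solve(V)
  var_hat <- 1 / drop(t(one) %*% vi %*% one)
  list(beta = var_hat * drop(t(one) %*% vi %*% betas),
       se = sqrt(var_hat))
}

# O(n*m) per-pair containment: SNP at 1-based q overlaps [s, e) iff
# s <= q - 1 < e
brute_overlap_oracle <- function(snps, bed) {
  vapply(seq_len(nrow(snps)), function(i) {
    q0 <- snps$pos[i] - 1L
    any(bed$chrom == snps$chrom[i] & bed$start <= q0 & q0 < bed$end)
  }, logical(1))
}

# two-sided Fisher P by full enumeration of the hypergeometric support,
# probability-mass rule
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# allele-level dosage correlation implied by thresholding AR(1) latent
# Gaussians at the frequency quantile, by numeric integration of the
# bivariate normal orthant probability
dosage_cor_oracle <- function(rho, p) {
  t <- stats::qnorm(p)
  p11 <- stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((t - rho * z) / sqrt(1 - rho^2)),
    -Inf, t, rel.tol = 1e-10)$value
  (p11 - p^2) / (p * (1 - p))
}

# weighted least squares through the origin (QR path, no shared code with
# the closed-form IVW sums)
wls_origin_oracle <- function(bx, by, w) {
  fit <- stats::lm.wfit(x = matrix(bx, ncol = 1), y = by, w = w)
  unname(fit$coefficients)
}

# convenience: a small synthetic stratum file on disk
write_stratum_fixture <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
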