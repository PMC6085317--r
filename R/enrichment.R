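# Overlap of credible-set variants with epigenomic feature intervals and
# Fisher enrichment between SNP sets or feature conditions.
#
# Coordinate conventions: SNP positions are 1-based; BED intervals are
# 0-based half-open. A SNP at 1-based position q overlaps [s, e) iff
# s <= q - 1 < e.

#' Read a BED file of feature intervals
#'
#' @param path BED file (3+ columns, 0-based half-open)
#' @return a `GRanges` (1-based internally, as usual for Bioconductor)
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

.snps_to_granges <- function(snps) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = snps$pos, width = 1))
}

.as_granges_features <- function(x) {
  if (is.data.frame(x)) {
    # 0-based half-open data.frame(chrom, start, end) -> 1-based GRanges
    stopifnot(all(x$start < x$end))
    return(GenomicRanges::GRanges(
      seqnames = as.character(x$chrom),
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)))
  }
  x
}

#' Overlap a SNP set with epigenomic feature sets
#'
#' @param snps data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based)
#' @param features a named list of feature sets, each a `GRanges` (from
#'   [read_bed()]) or a 0-based half-open data.frame with `chrom`,
#'   `start`, `end`
#' @param name label for the SNP set
#' @return object of class `overlap_summary`: list with `name`, `n_snps`,
#'   `n_overlapping` (SNPs hitting at least one feature set),
#'   `fraction`, `per_feature` counts, and a logical `flags` matrix
#'   (SNP x feature set) in input SNP order
#' @export
overlap_snps <- function(snps, features, name = "snps") {
  if (!is.list(features) || inherits(features, "GRanges"))
    features <- list(feature = features)
  if (is.null(names(features)))
    names(features) <- paste0("feature", seq_along(features))
  gr <- .snps_to_granges(snps)
  flags <- vapply(features, function(f) {
    GenomicRanges::countOverlaps(gr, .as_granges_features(f),
                                 ignore.strand = TRUE) > 0
  }, logical(length(gr)))
  flags <- matrix(flags, nrow = length(gr),
                  dimnames = list(snps$variant_id, names(features)))
  any_hit <- apply(flags, 1, any)
  structure(list(name = name,
                 n_snps = nrow(snps),
                 n_overlapping = sum(any_hit),
                 fraction = mean(any_hit),
                 per_feature = colSums(flags),
                 flags = flags),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Overlap summary '%s': %d / %d SNPs (%.0f%%) hit >=1 feature set\n",
              x$name, x$n_overlapping, x$n_snps, 100 * x$fraction))
  invisible(x)
}

#' Fisher enrichment of overlap fractions between two SNP sets
#'
#' Builds the 2x2 table of overlapping / non-overlapping counts for the
#' two sets and tests it with Fisher's exact test (two-sided by the
#' probability-mass rule: the P-value sums all tables no more probable
#' than the observed one under the hypergeometric null). The reported
#' odds ratio is the sample cross-product ratio.
#'
#' @param a,b `overlap_summary` objects (see [overlap_snps()])
#' @return list with `odds_ratio`, `p.value`, `table`
#' @export
enrichment_fisher <- function(a, b) {
  stopifnot(inherits(a, "overlap_summary"), inherits(b, "overlap_summary"))
  if (a$n_snps == 0 || b$n_snps == 0) stop("empty SNP set")
  tab <- rbind(c(a$n_overlapping, a$n_snps - a$n_overlapping),
               c(b$n_overlapping, b$n_snps - b$n_overlapping))
  dimnames(tab) <- list(set = c(a$name, b$name),
                        overlap = c("yes", "no"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; enrichment undefined, P = 1")
    return(list(odds_ratio = NA_real_, p.value = 1, table = tab))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p.value = p, table = tab)
}

#' Contrast feature conditions for one SNP set
#'
#' Same machinery as [enrichment_fisher()], labelled as a condition
#' contrast (e.g. overlap with estrogen-stimulated versus unstimulated
#' features for the same credible-set SNPs).
#'
#' @param features_a,features_b `overlap_summary` objects for the two
#'   conditions
#' @return as [enrichment_fisher()], plus `contrast = TRUE`
#' @export
condition_contrast <- function(features_a, features_b) {
  out <- enrichment_fisher(features_a, features_b)
  out$contrast <- TRUE
  out
}
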