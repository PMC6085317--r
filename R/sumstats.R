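# Reading, validation and harmonization of per-stratum and meta-level
# GWAS summary statistics, plus the locus LD-reference container.

# 97.5% normal quantile used throughout for CI <-> se conversions and the
# Wakefield prior; fixed to 6 decimals so printed-table reproductions are
# stable across platforms.
Z_975 <- 1.959964

.canonical_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "p", "info",
                     "n_cases", "n_controls")

.default_aliases <- c(
  variant_id = "variant_id", snp = "variant_id", rsid = "variant_id",
  chrom = "chrom", chr = "chrom",
  pos = "pos", bp = "pos", position = "pos",
  ea = "effect_allele", effect_allele = "effect_allele", a1 = "effect_allele",
  oa = "other_allele", other_allele = "other_allele", a2 = "other_allele",
  eaf = "eaf", freq = "eaf",
  beta = "beta", b = "beta",
  se = "se", stderr = "se",
  p = "p", pval = "p", pvalue = "p",
  info = "info", rsq = "info",
  n_cases = "n_cases", ncases = "n_cases",
  n_controls = "n_controls", ncontrols = "n_controls",
  "or" = "or", oci_l = "oci_l", oci_u = "oci_u"
)

#' Convert an odds ratio and 95\% confidence interval to log-odds scale
#'
#' `beta = ln(OR)`; `se = (ln(UCI) - ln(LCI)) / (2 * 1.959964)`.
#'
#' @param or odds ratio(s)
#' @param ci_lower,ci_upper bounds of the 95\% confidence interval
#' @return list with components `beta` and `se`
#' @export
or_ci_to_beta <- function(or, ci_lower, ci_upper) {
  stopifnot(all(or > 0), all(ci_lower > 0), all(ci_upper > ci_lower))
  list(beta = log(or), se = (log(ci_upper) - log(ci_lower)) / (2 * Z_975))
}

#' Derive the standard error of a log odds ratio from its P-value
#'
#' Inverts the two-sided Wald test: `se = |beta| / qnorm(1 - P/2)`.
#' This is the convention used for all printed-table reproductions
#' (credible sets, BFDP, familial-relative-risk decomposition), where the
#' P-value is printed to more useful precision than the CI bounds.
#'
#' @param beta log odds ratio
#' @param p two-sided P-value in (0, 1)
#' @return standard error (same length as `beta`)
#' @export
se_from_p <- function(beta, p) {
  stopifnot(all(p > 0), all(p < 1))
  # upper-tail form keeps precision for genome-wide P-values (1 - p/2
  # rounds to 1 in double precision once p < ~1e-16)
  abs(beta) / stats::qnorm(p / 2, lower.tail = FALSE)
}

.validate_stratum <- function(df) {
  reasons <- rep("", nrow(df))
  add <- function(bad, code) {
    bad[is.na(bad)] <- TRUE
    ifelse(bad, paste0(reasons, ifelse(nchar(reasons), ",", ""), code), reasons)
  }
  reasons <- add(!(df$eaf > 0 & df$eaf < 1), "eaf_out_of_range")
  reasons <- add(!(df$se > 0), "nonpositive_se")
  reasons <- add(!(df$info >= 0 & df$info <= 1), "info_out_of_range")
  reasons <- add(!(df$n_cases >= 1 & df$n_controls >= 1), "bad_sample_size")
  reasons <- add(df$effect_allele == df$other_allele, "identical_alleles")
  reasons <- add(!is.finite(df$beta), "nonfinite_beta")
  reasons
}

#' Read one stratum's association summary statistics
#'
#' Reads a delimited summary-statistics file, maps column aliases onto the
#' canonical schema, converts odds-ratio-scale input to the log-odds scale,
#' and validates every row. Effect sizes may be supplied as `beta`+`se`, as
#' `or` with 95\% CI bounds (`oci_l`, `oci_u`), or as `or` with a P-value.
#' When both a CI and a P-value are present the standard error is taken
#' from the P-value (see [se_from_p()]).
#'
#' Rows failing validation are never silently dropped: they are removed
#' from the returned table, attached as `attr(, "rejected")` with reason
#' codes, and reported via a warning.
#'
#' @param path path to a tab-separated file with a header row
#' @param aliases optional named character vector mapping file column names
#'   to canonical names, merged over the built-in alias map
#' @param stratum_id label for this stratum; defaults to the file name
#' @param sep field separator (default tab)
#' @return data.frame of validated stratum records with columns
#'   `variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#'   p, info, n_cases, n_controls, stratum_id`
#' @export
read_stratum_file <- function(path, aliases = NULL, stratum_id = NULL,
                              sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  amap <- .default_aliases
  if (!is.null(aliases)) amap[names(aliases)] <- aliases
  hit <- tolower(names(raw)) %in% names(amap)
  names(raw)[hit] <- amap[tolower(names(raw))[hit]]

  mandatory <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "eaf")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))

  has <- function(...) all(c(...) %in% names(raw))
  if (has("beta", "se")) {
    # native scale, nothing to convert
  } else if (has("or", "oci_l", "oci_u")) {
    conv <- or_ci_to_beta(raw$or, raw$oci_l, raw$oci_u)
    raw$beta <- conv$beta
    raw$se <- conv$se
  } else if (has("or", "p")) {
    raw$beta <- log(raw$or)
    raw$se <- se_from_p(raw$beta, raw$p)
  } else {
    stop("need beta+se, or+oci_l+oci_u, or or+p columns")
  }
  if (!"p" %in% names(raw))
    raw$p <- 2 * stats::pnorm(-abs(raw$beta / raw$se))
  if (!"info" %in% names(raw)) {
    warning("no imputation info column; assuming genotyped (info = 1)")
    raw$info <- 1
  }
  if (!"n_cases" %in% names(raw)) raw$n_cases <- NA_integer_
  if (!"n_controls" %in% names(raw)) raw$n_controls <- NA_integer_
  raw$stratum_id <- if (is.null(stratum_id)) basename(path) else stratum_id
  out <- raw[, c(.canonical_cols, "stratum_id")]
  out$chrom <- as.character(out$chrom)

  reasons <- .validate_stratum(out)
  bad <- nchar(reasons) > 0
  if (any(bad)) {
    rej <- out[bad, , drop = FALSE]
    rej$reason <- reasons[bad]
    warning(sum(bad), " row(s) failed validation (",
            paste(utils::head(unique(reasons[bad]), 5), collapse = "; "),
            "); see attr(, 'rejected')")
    out <- out[!bad, , drop = FALSE]
    attr(out, "rejected") <- rej
  }
  rownames(out) <- NULL
  out
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.comp_allele <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(ch) {
    if (all(ch %in% names(.complement)))
      paste(rev(.complement[ch]), collapse = "")
    else NA_character_
  }, character(1))
}

#' Align stratum records to a common effect/other allele reference
#'
#' Records whose alleles are swapped relative to the reference have their
#' effect reversed (`beta` negated, `eaf` replaced by `1 - eaf`); records
#' on the opposite strand are complemented first. Strand-ambiguous A/T and
#' C/G variants with `eaf` in \[0.4, 0.6\] are flagged in the `ambiguous`
#' column because their orientation cannot be resolved from frequency.
#'
#' @param records a stratum data.frame (as from [read_stratum_file()]) or a
#'   list of them
#' @param reference data.frame with columns `variant_id, effect_allele,
#'   other_allele` defining the target orientation
#' @return input with `beta`/`eaf` aligned and logical columns `flipped`
#'   and `ambiguous` added; a list in, a list out
#' @export
harmonize_alleles <- function(records, reference) {
  if (is.data.frame(records)) return(.harmonize_one(records, reference))
  lapply(records, .harmonize_one, reference = reference)
}

.harmonize_one <- function(df, reference) {
  idx <- match(df$variant_id, reference$variant_id)
  if (anyNA(idx))
    stop("variant(s) absent from reference: ",
         paste(utils::head(df$variant_id[is.na(idx)], 5), collapse = ", "))
  ref_ea <- reference$effect_allele[idx]
  ref_oa <- reference$other_allele[idx]
  ea <- df$effect_allele; oa <- df$other_allele
  cea <- .comp_allele(ea); coa <- .comp_allele(oa)

  same    <- ea == ref_ea & oa == ref_oa
  swapped <- ea == ref_oa & oa == ref_ea
  csame   <- !same & !swapped & !is.na(cea) & cea == ref_ea & coa == ref_oa
  cswap   <- !same & !swapped & !is.na(cea) & cea == ref_oa & coa == ref_ea
  bad <- !(same | swapped | csame | cswap)
  if (any(bad))
    stop("allele pair incompatible with reference for: ",
         paste(utils::head(df$variant_id[bad], 5), collapse = ", "))

  flip <- swapped | cswap
  df$beta[flip] <- -df$beta[flip]
  df$eaf[flip] <- 1 - df$eaf[flip]
  df$effect_allele <- ref_ea
  df$other_allele <- ref_oa
  df$flipped <- flip
  palindromic <- !is.na(cea) & ea == coa   # A/T or C/G pair
  df$ambiguous <- palindromic & df$eaf >= 0.4 & df$eaf <= 0.6
  df
}

.meta_cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "z", "p", "q_stat", "i2", "het_p",
                "n_strata_used", "model")

#' Write pooled meta-analysis records to a tab-separated file
#'
#' Columns are written in a fixed order with 17-significant-digit floats so
#' that [read_meta_file()] round-trips to identical records.
#'
#' @param records data.frame of meta records (see [meta_gwas()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_meta_file <- function(records, path) {
  stopifnot(all(.meta_cols %in% names(records)))
  out <- records[, .meta_cols, drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a meta-analysis file written by [write_meta_file()]
#' @param path input path
#' @return data.frame of meta records
#' @export
read_meta_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df
}

#' LD reference for a locus
#'
#' Bundles an ordered variant list with the square matrix of pairwise
#' genotype correlations r (so r-squared is its elementwise square) from a
#' reference panel.
#'
#' @param variant_ids character vector of variant identifiers
#' @param correlation square symmetric correlation matrix matching
#'   `variant_ids`
#' @param sample_size number of reference individuals
#' @return object of class `ld_reference`
#' @export
ld_reference <- function(variant_ids, correlation, sample_size = NA_integer_) {
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != length(variant_ids) ||
      ncol(correlation) != length(variant_ids))
    stop("correlation dimensions do not match variant list")
  if (max(abs(correlation - t(correlation))) > 1e-8)
    stop("correlation matrix is not symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-8)
    stop("correlation matrix diagonal must be 1")
  if (max(abs(correlation)) > 1 + 1e-8)
    stop("correlations must satisfy |r| <= 1")
  dimnames(correlation) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids),
                 correlation = correlation,
                 sample_size = sample_size),
            class = "ld_reference")
}

#' Read an LD reference from a variant list and a matrix file
#'
#' @param matrix_path whitespace-delimited square matrix of correlations
#' @param variants_path one variant id per line, in matrix order
#' @param sample_size reference panel size (optional)
#' @return an [ld_reference()] object
#' @export
read_ld_reference <- function(matrix_path, variants_path,
                              sample_size = NA_integer_) {
  ids <- readLines(variants_path)
  ids <- ids[nzchar(ids)]
  m <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  ld_reference(ids, unname(m), sample_size)
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("LD reference:", length(x$variant_ids), "variants",
      if (!is.na(x$sample_size)) paste0("(panel n = ", x$sample_size, ")"),
      "\n")
  invisible(x)
}
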