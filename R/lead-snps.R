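# Published lead-SNP summary results for endometrial cancer risk loci,
# as printed in the source meta-analysis of 12,906 cases and 108,979
# controls (all-histology fixed-effects results). Positions are 1-based,
# genome build 38. `info` is 1 for directly genotyped variants.

#' Published endometrial cancer lead-SNP table
#'
#' Printed all-histology meta-analysis results for the lead variants of
#' the endometrial cancer risk loci: the previously reported loci
#' (`novel = FALSE`; the 14q32.33 variant did not replicate and carries
#' `replicated = FALSE`) and the nine newly reported loci
#' (`novel = TRUE`). These printed values — effect-allele frequency, odds
#' ratio with 95\% CI, and meta-analysis P — are the inputs for
#' reproducing the published BFDP and familial-relative-risk
#' calculations; standard errors are re-derived from the printed P-values
#' via [se_from_p()].
#'
#' @return data.frame with columns `region`, `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `info`, `or`,
#'   `ci_lower`, `ci_upper`, `p`, `novel`, `replicated`
#' @export
ec_lead_snps <- function() {
  prev <- data.frame(
    region = c("6p22.3", "6q22.31", "8q24.21", "8q24.21", "8q24.21",
               "13q22.1", "14q32.33", "15q15.1", "15q21.2", "17q12"),
    variant_id = c("rs1740828", "rs2747716", "rs35286446", "rs4733613",
                   "rs139584729", "rs7981863", "rs2498796", "rs937213",
                   "rs17601876", "rs11263761"),
    chrom = c("6", "6", "8", "8", "8", "13", "14", "15", "15", "17"),
    pos = c(21648854L, 125687226L, 128433617L, 128587032L, 128611656L,
            73238004L, 104776883L, 40029923L, 51261712L, 37737784L),
    effect_allele = c("G", "A", "GAT", "C", "C", "C", "A", "C", "G", "A"),
    other_allele = c("A", "G", "G", "G", "G", "T", "G", "T", "A", "G"),
    eaf = c(0.52, 0.57, 0.58, 0.12, 0.98, 0.72, 0.30, 0.42, 0.48, 0.52),
    info = c(1, 1, 0.99, 1, 0.97, 1, 0.98, 1, 1, 0.98),
    or = c(1.15, 1.10, 1.10, 1.18, 1.40, 1.16, 1.07, 1.09, 1.12, 1.15),
    ci_lower = c(1.11, 1.07, 1.06, 1.13, 1.25, 1.12, 1.03, 1.06, 1.09, 1.12),
    ci_upper = c(1.19, 1.14, 1.13, 1.24, 1.58, 1.20, 1.11, 1.13, 1.16, 1.19),
    p = c(4.2e-16, 2.9e-10, 3.1e-09, 7.5e-14, 2.4e-08, 2.7e-17, 6.3e-05,
          5.1e-09, 3.3e-14, 3.2e-20),
    novel = FALSE,
    replicated = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                   TRUE),
    stringsAsFactors = FALSE)
  new <- data.frame(
    region = c("1p34.3", "2p16.1", "9p21.3", "11p13", "12p12.1",
               "12q24.11", "12q24.21", "17q11.2", "17q21.32"),
    variant_id = c("rs113998067", "rs148261157", "rs1679014", "rs10835920",
                   "rs9668337", "rs3184504", "rs10850382", "rs11295063",
                   "rs882380"),
    chrom = c("1", "2", "9", "11", "12", "12", "12", "17", "17"),
    pos = c(37607755L, 60670444L, 22207038L, 32468118L, 26273405L,
            111446804L, 114776743L, 31319014L, 48216874L),
    effect_allele = c("C", "A", "T", "T", "A", "C", "T", "G", "A"),
    other_allele = c("T", "G", "C", "C", "G", "T", "C", "A", "C"),
    eaf = c(0.04, 0.03, 0.07, 0.38, 0.74, 0.52, 0.31, 0.38, 0.61),
    info = c(0.90, 0.88, 1, 0.99, 0.99, 1, 1, 1, 0.99),
    or = c(1.23, 1.26, 1.18, 1.09, 1.11, 1.10, 1.10, 1.10, 1.10),
    ci_lower = c(1.14, 1.16, 1.12, 1.06, 1.08, 1.07, 1.07, 1.06, 1.06),
    ci_upper = c(1.32, 1.36, 1.25, 1.13, 1.15, 1.14, 1.14, 1.13, 1.13),
    p = c(3.6e-08, 3.4e-08, 6.4e-09, 1.3e-08, 1.1e-09, 1.1e-10, 3.5e-09,
          4.3e-08, 4.7e-09),
    novel = TRUE,
    replicated = TRUE,
    stringsAsFactors = FALSE)
  rbind(prev, new)
}
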