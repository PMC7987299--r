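#' Case-only TWAS test for subtype heterogeneity
#'
#' Applies the TWAS statistic to z-scores from a case-only GWAS comparing
#' ER+ with ER- patients. Under a multinomial model with expression log odds
#' ratios \eqn{\beta_1} (ER+) and \eqn{\beta_2} (ER-), this tests
#' \eqn{H_0: \beta_2 - \beta_1 = 0}; with the package's z orientation (the
#' effect allele increases the odds of ER- versus ER+ disease) a positive
#' statistic indicates a stronger ER- expression effect.
#'
#' @param weights A \code{weight_model}.
#' @param gwas_caseonly Harmonized \code{gwas_summary} with scan label
#'   \code{"case_only"}.
#' @param ld A (regularized) \code{ld_matrix}.
#' @return As \code{\link{twas_z}}.
#' @export
case_only_test <- function(weights, gwas_caseonly, ld) {
  if (!identical(scan_label(gwas_caseonly), "case_only"))
    stop("expected a case-only scan")
  twas_z(weights, gwas_caseonly, ld)
}

SUBTYPE_LABELS <- c("er_pos_specific", "er_neg_specific", "shared",
                    "heterogeneous_only", "not_significant")

#' Classify a gene's subtype-specificity from its four scan p-values
#'
#' Deterministic rules at the given threshold(s): a gene is
#' \code{er_pos_specific} when the case-only and ER+ tests are significant
#' but the ER- test is not (\code{er_neg_specific} symmetrically);
#' \code{shared} when both subtype tests are significant without case-only
#' heterogeneity; \code{heterogeneous_only} when only the case-only test is
#' significant; otherwise \code{not_significant}.
#'
#' @param p_overall,p_pos,p_neg,p_caseonly The four scan p-values.
#' @param threshold Single shared threshold, or a named vector with entries
#'   \code{er_pos}, \code{er_neg}, \code{case_only} for scan-specific
#'   Bonferroni thresholds.
#' @param gene_id Identifier carried into the result.
#' @return Object of class \code{subtype_call}: gene_id, the four p-values
#'   and the label.
#' @export
classify_subtype <- function(p_overall, p_pos, p_neg, p_caseonly,
                             threshold, gene_id = "gene") {
  ps <- c(p_overall, p_pos, p_neg, p_caseonly)
  if (!is.numeric(ps) || any(is.na(ps)) || length(ps) != 4)
    stop("all four p-values required as numbers")
  thr <- function(scan) {
    if (length(threshold) == 1 && is.null(names(threshold))) threshold
    else unname(threshold[[scan]])
  }
  sig_pos <- p_pos < thr("er_pos")
  sig_neg <- p_neg < thr("er_neg")
  sig_co <- p_caseonly < thr("case_only")
  label <- if (sig_co && sig_pos && !sig_neg) "er_pos_specific"
  else if (sig_co && sig_neg && !sig_pos) "er_neg_specific"
  else if (sig_pos && sig_neg && !sig_co) "shared"
  else if (sig_co && !sig_pos && !sig_neg) "heterogeneous_only"
  else "not_significant"
  structure(list(gene_id = gene_id, p_overall = p_overall, p_pos = p_pos,
                 p_neg = p_neg, p_caseonly = p_caseonly, label = label),
            class = "subtype_call")
}
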