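#' SNP correlation (LD) matrix from a reference panel
#'
#' Pearson correlations of dosages for the requested SNPs, with exact
#' symmetry enforced.
#'
#' @param panel A \code{genotype_panel}.
#' @param snp_ids SNP ids to include, in the requested order (default: all).
#' @return Object of class \code{ld_matrix}: list with \code{snp_ids},
#'   \code{sigma} and the ridge \code{lambda} applied (0 here).
#' @export
ld_matrix <- function(panel, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- panel$snps$id
  idx <- match(snp_ids, panel$snps$id)
  if (anyNA(idx)) stop("SNPs absent from panel: ",
                       paste(snp_ids[is.na(idx)], collapse = ", "))
  D <- panel$dosage[, idx, drop = FALSE]
  if (any(apply(D, 2, stats::var) == 0)) stop("zero-variance SNP in LD request")
  S <- stats::cor(D)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(list(snp_ids = snp_ids, sigma = S, lambda = 0),
            class = "ld_matrix")
}

#' Ridge-regularize an LD matrix
#'
#' \eqn{\Sigma_{adj} = (\Sigma + \lambda I) / (1 + \lambda)}: off-diagonals
#' are shrunk by \eqn{1/(1+\lambda)} while the diagonal stays exactly 1, so
#' the single-SNP TWAS statistic remains the GWAS z-score and the matrix is
#' strictly positive definite for \eqn{\lambda > 0} (smallest eigenvalue at
#' least \eqn{\lambda/(1+\lambda)}).
#'
#' @param ld An \code{ld_matrix}.
#' @param lam Ridge parameter (default 0.1).
#' @return Regularized \code{ld_matrix} with \code{lambda} recorded.
#' @export
regularize_ld <- function(ld, lam = 0.1) {
  stopifnot(inherits(ld, "ld_matrix"))
  if (lam < 0) stop("lambda must be nonnegative")
  if (lam == 0) return(ld)
  S <- (ld$sigma + lam * diag(nrow(ld$sigma))) / (1 + lam)
  structure(list(snp_ids = ld$snp_ids, sigma = S,
                 lambda = ld$lambda + lam),
            class = "ld_matrix")
}

#' Summary-statistics TWAS association statistic for one gene
#'
#' Computes \eqn{z_{TWAS} = w'z / \sqrt{w' \Sigma w}} where \eqn{w} are the
#' expression-prediction weights, \eqn{z} the harmonized GWAS z-scores and
#' \eqn{\Sigma} the (regularized) reference LD over the SNPs used. Weights
#' are restricted to SNPs present in both sources; the count of weight SNPs
#' missing from the GWAS is reported. The two-sided p-value comes from
#' \code{pnorm}, whose complementary-error-function tail is accurate to
#' far below 1e-30.
#'
#' @param weights A \code{weight_model} (or a named numeric weight vector).
#' @param gwas A harmonized \code{gwas_summary}.
#' @param ld An \code{ld_matrix} covering at least the weight SNPs.
#' @return Object of class \code{twas_result}: gene_id, scan_label, z_twas,
#'   p, n_snps_used, n_snps_missing, significant (NA until thresholded), or
#'   class \code{twas_skip} with a diagnostic when the gene cannot be
#'   tested.
#' @export
twas_z <- function(weights, gwas, ld) {
  if (inherits(weights, "weight_model")) {
    w_all <- weights$weights
    gene_id <- weights$gene_id
  } else {
    w_all <- weights
    gene_id <- attr(weights, "gene_id")
    if (is.null(gene_id)) gene_id <- "gene"
  }
  w_all <- w_all[w_all != 0]
  g <- as.data.frame(gwas)
  used <- intersect(names(w_all), intersect(g$SNP, ld$snp_ids))
  n_missing <- length(w_all) - length(used)
  if (!length(used))
    return(structure(list(gene_id = gene_id, reason = "empty_intersection"),
                     class = "twas_skip"))
  w <- w_all[used]
  z <- g$Z[match(used, g$SNP)]
  S <- ld$sigma[match(used, ld$snp_ids), match(used, ld$snp_ids),
                drop = FALSE]
  denom2 <- drop(crossprod(w, S %*% w))
  if (denom2 <= 0)
    return(structure(list(gene_id = gene_id,
                          reason = "nonpositive_variance"),
                     class = "twas_skip"))
  zt <- sum(w * z) / sqrt(denom2)
  structure(list(gene_id = gene_id, scan_label = scan_label(gwas),
                 z_twas = zt, p = 2 * stats::pnorm(-abs(zt)),
                 n_snps_used = length(used), n_snps_missing = n_missing,
                 significant = NA),
            class = "twas_result")
}

#' Bonferroni familywise significance threshold
#'
#' @param alpha Familywise error rate (default 0.05).
#' @param n_genes Number of genes tested.
#' @return \code{alpha / n_genes}.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_genes) {
  if (n_genes < 1) stop("n_genes must be at least 1")
  alpha / n_genes
}

#' Count significant genes in a results table
#'
#' Strict comparison: rows with p-value strictly below the threshold.
#'
#' @param results data.frame of per-gene results.
#' @param threshold Significance threshold.
#' @param p_col Name of the p-value column to use (e.g. one per scan).
#' @return Integer count.
#' @export
count_significant <- function(results, threshold, p_col = "p") {
  if (!nrow(results)) return(0L)
  if (!p_col %in% names(results)) stop("no column '", p_col, "' in results")
  sum(results[[p_col]] < threshold, na.rm = TRUE)
}
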