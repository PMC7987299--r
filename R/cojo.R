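#' Group genes into regions by transitive-closure distance merging
#'
#' Genes chained by pairwise coordinate distance at most \code{window} share
#' a region (merging is done with \code{GenomicRanges::reduce}); regions are
#' split by chromosome and sorted by position.
#'
#' @param genes data.frame with gene_id, chrom, start, end (1-based,
#'   inclusive).
#' @param window Grouping window in base pairs (default 500000).
#' @return data.frame: region_id, chrom, start, end, gene_ids
#'   (comma-separated), n_genes.
#' @export
group_regions <- function(genes, window = 5e5) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  # reduce merges ranges whose gap is < min.gapwidth; a coordinate distance
  # of exactly `window` between gene boundaries is a gap of window - 1
  red <- GenomicRanges::reduce(gr, min.gapwidth = window)
  hit <- GenomicRanges::findOverlaps(gr, red)
  memb <- S4Vectors::subjectHits(hit)[match(seq_len(nrow(genes)),
                                            S4Vectors::queryHits(hit))]
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  rank <- match(seq_along(red), ord)
  out <- do.call(rbind, lapply(seq_along(red), function(k) {
    ids <- genes$gene_id[memb == k]
    data.frame(region_id = sprintf("region%03d", rank[k]),
               chrom = as.character(GenomicRanges::seqnames(red))[k],
               start = GenomicRanges::start(red)[k],
               end = GenomicRanges::end(red)[k],
               gene_ids = paste(ids, collapse = ","),
               n_genes = length(ids), stringsAsFactors = FALSE)
  }))
  out[order(out$region_id), , drop = FALSE]
}

# embed a named weight vector into the union SNP order, zeros elsewhere
embed_weights <- function(w, snp_ids) {
  out <- numeric(length(snp_ids))
  names(out) <- snp_ids
  w <- w[w != 0]
  out[intersect(names(w), snp_ids)] <- w[intersect(names(w), snp_ids)]
  out
}

#' Correlation between two genes' predicted-expression features
#'
#' With weight vectors embedded over the union SNP set and reference LD
#' \eqn{\Sigma}, the feature correlation is
#' \eqn{r_{jk} = w_j' \Sigma w_k / \sqrt{(w_j' \Sigma w_j)(w_k' \Sigma w_k)}},
#' the correlation of the two linear combinations of standardized dosages.
#'
#' @param w_j,w_k Named weight vectors.
#' @param ld A (regularized) \code{ld_matrix} over the union SNPs.
#' @return Scalar in [-1, 1].
#' @export
feature_correlation <- function(w_j, w_k, ld) {
  S <- ld$sigma
  a <- embed_weights(w_j, ld$snp_ids)
  b <- embed_weights(w_k, ld$snp_ids)
  va <- drop(crossprod(a, S %*% a))
  vb <- drop(crossprod(b, S %*% b))
  if (va <= 0 || vb <= 0) stop("zero-variance predicted-expression feature")
  drop(crossprod(a, S %*% b)) / sqrt(va * vb)
}

#' Joint analysis of several TWAS genes in one region
#'
#' Features with pairwise |r| above \code{prune_r} are collapsed (keeping
#' the smallest marginal p), joint effects are the generalized-least-squares
#' solution \eqn{b = R^{-1} z}, and each retained gene's joint z is
#' \eqn{b_i / \sqrt{(R^{-1})_{ii}}} with a two-sided normal p. A gene is
#' flagged as retained when its joint p is below \code{p_retain}.
#'
#' @param z Named vector of marginal TWAS z-scores (one per gene).
#' @param R Feature correlation matrix (symmetric, unit diagonal) in the
#'   same order.
#' @param prune_r Collinearity pruning threshold (default 0.95).
#' @param p_retain Retention threshold on the joint p (default 0.05).
#' @return data.frame: gene_id, z_marginal, p_marginal, z_joint, p_joint,
#'   retained, pruned (TRUE for genes collapsed into a proxy; their joint
#'   columns are NA).
#' @export
joint_gene_analysis <- function(z, R, prune_r = 0.95, p_retain = 0.05) {
  k <- length(z)
  stopifnot(nrow(R) == k, ncol(R) == k)
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop("R must be symmetric with unit diagonal")
  ids <- names(z)
  if (is.null(ids)) ids <- sprintf("gene%02d", seq_len(k))
  p_marg <- 2 * stats::pnorm(-abs(z))
  # prune collinear features, keeping the smallest marginal p of each clique
  keep <- logical(k)
  for (i in order(p_marg)) {
    if (!any(keep & abs(R[i, ]) > prune_r)) keep[i] <- TRUE
  }
  Rk <- R[keep, keep, drop = FALSE]
  zk <- z[keep]
  Rinv <- tryCatch(solve(Rk), error = function(e) NULL)
  if (is.null(Rinv)) {
    warning("feature correlation matrix singular after pruning; ",
            "ridge-stabilizing with epsilon 1e-6")
    eps <- 1e-6
    Rinv <- solve((Rk + eps * diag(nrow(Rk))) / (1 + eps))
  }
  b <- drop(Rinv %*% zk)
  zj <- b / sqrt(diag(Rinv))
  pj <- 2 * stats::pnorm(-abs(zj))
  out <- data.frame(gene_id = ids, z_marginal = unname(z),
                    p_marginal = unname(p_marg), z_joint = NA_real_,
                    p_joint = NA_real_, retained = FALSE, pruned = !keep,
                    stringsAsFactors = FALSE)
  out$z_joint[keep] <- zj
  out$p_joint[keep] <- pj
  out$retained[keep] <- pj < p_retain
  out
}

# per-SNP correlations with a gene's predicted-expression feature:
# rho_s = (Sigma w)_s / sqrt(w' Sigma w)
snp_feature_correlations <- function(w, ld) {
  a <- embed_weights(w, ld$snp_ids)
  q <- drop(crossprod(a, ld$sigma %*% a))
  if (q <= 0) stop("zero-variance predicted-expression feature")
  drop(ld$sigma %*% a) / sqrt(q)
}

#' SNP z-score conditional on predicted gene expression
#'
#' Standard summary-statistics conditioning:
#' \eqn{z_{cond} = (z_s - \rho' R^{-1} z_g) / \sqrt{1 - \rho' R^{-1} \rho}}
#' where \eqn{\rho} holds the SNP's correlations with each gene feature,
#' \eqn{R} the feature correlation matrix and \eqn{z_g} the gene TWAS
#' z-scores. When the features explain the SNP completely
#' (\eqn{1 - \rho' R^{-1} \rho \le 0}) the SNP is reported as fully
#' explained: conditional z NA, conditional p 1.
#'
#' @param z_snp Marginal SNP z-score.
#' @param rho Vector of SNP-feature correlations.
#' @param R Feature correlation matrix.
#' @param z_genes Gene TWAS z-scores.
#' @return List: z_cond, p_cond, fully_explained flag.
#' @export
conditional_snp_z <- function(z_snp, rho, R, z_genes) {
  if (any(abs(rho) > 1 + 1e-8)) stop("|rho| must be at most 1")
  Rinv <- solve(R)
  denom2 <- 1 - drop(crossprod(rho, Rinv %*% rho))
  if (denom2 <= 1e-10)
    return(list(z_cond = NA_real_, p_cond = 1, fully_explained = TRUE))
  zc <- (z_snp - drop(crossprod(rho, Rinv %*% z_genes))) / sqrt(denom2)
  list(z_cond = zc, p_cond = 2 * stats::pnorm(-abs(zc)),
       fully_explained = FALSE)
}

#' Ratio and magnitude summaries of a conditional analysis
#'
#' \code{ratio} is the proportion of marginally genome-wide-significant SNPs
#' that lose significance after conditioning,
#' \code{(n_before - n_after) / n_before}; \code{magnitude} is the change in
#' the minimum p-value, \code{index_p / min_conditional_p}. When nothing was
#' significant before conditioning the ratio is reported as 1 by convention
#' (nothing remained to explain) and flagged.
#'
#' @param n_sig_before,n_sig_after Counts of genome-wide-significant SNPs
#'   before and after conditioning.
#' @param index_p Marginal p of the index SNP (the regional minimum).
#' @param min_conditional_p Minimum conditional p over the region's SNPs.
#' @return List: ratio, magnitude, nothing_to_explain flag.
#' @export
cojo_change_summary <- function(n_sig_before, n_sig_after, index_p,
                                min_conditional_p) {
  nothing <- n_sig_before == 0
  ratio <- if (nothing) 1 else (n_sig_before - n_sig_after) / n_sig_before
  list(ratio = ratio, magnitude = index_p / min_conditional_p,
       nothing_to_explain = nothing)
}

#' Region-level conditional analysis of GWAS SNPs on a gene's expression
#'
#' Conditions every region SNP's z-score on the predicted expression of the
#' given gene(s) and summarizes how much of the genome-wide-significant
#' signal the gene explains.
#'
#' @param gwas Harmonized \code{gwas_summary} restricted (or restrictable)
#'   to the region.
#' @param models List of \code{weight_model}s for the region's gene(s);
#'   conditioning uses all of them jointly.
#' @param ld A regularized \code{ld_matrix} over the region SNPs.
#' @param snp_ids Region SNPs to condition (default: all LD SNPs present in
#'   the scan).
#' @param gw_threshold Genome-wide significance threshold (default 5e-8).
#' @return Object of class \code{conditional_summary}: gene_id, n_snps,
#'   n_sig_before, index_snp, index_p, n_sig_after, min_conditional_p,
#'   ratio, magnitude, nothing_to_explain, and the per-SNP track (data.frame
#'   snp, bp, z_marginal, p_marginal, z_conditional, p_conditional) in
#'   \code{$track}.
#' @export
conditional_region_summary <- function(gwas, models, ld, snp_ids = NULL,
                                       gw_threshold = 5e-8) {
  if (inherits(models, "weight_model")) models <- list(models)
  g <- as.data.frame(gwas)
  if (is.null(snp_ids)) snp_ids <- intersect(ld$snp_ids, g$SNP)
  snp_ids <- intersect(snp_ids, intersect(ld$snp_ids, g$SNP))
  z <- g$Z[match(snp_ids, g$SNP)]
  bp <- g$BP[match(snp_ids, g$SNP)]
  p_marg <- 2 * stats::pnorm(-abs(z))

  k <- length(models)
  rho_mat <- vapply(models, function(mo)
    snp_feature_correlations(mo$weights, ld)[match(snp_ids, ld$snp_ids)],
    numeric(length(snp_ids)))
  rho_mat <- matrix(rho_mat, ncol = k)
  R <- diag(k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      R[i, j] <- R[j, i] <- feature_correlation(models[[i]]$weights,
                                                models[[j]]$weights, ld)
    }
  }
  z_genes <- vapply(models, function(mo) {
    res <- twas_z(mo, gwas, ld)
    if (inherits(res, "twas_skip")) stop("gene cannot be tested in region")
    res$z_twas
  }, numeric(1))

  cond <- lapply(seq_along(snp_ids), function(i)
    conditional_snp_z(z[i], rho_mat[i, ], R, z_genes))
  z_cond <- vapply(cond, function(x) x$z_cond, numeric(1))
  p_cond <- vapply(cond, function(x) x$p_cond, numeric(1))

  n_before <- sum(p_marg < gw_threshold)
  n_after <- sum(p_cond < gw_threshold)
  idx <- which.min(p_marg)
  chg <- cojo_change_summary(n_before, n_after, p_marg[idx], min(p_cond))
  structure(list(
    gene_id = paste(vapply(models, `[[`, character(1), "gene_id"),
                    collapse = ","),
    n_snps = length(snp_ids),
    n_sig_before = n_before,
    index_snp = snp_ids[idx],
    index_p = p_marg[idx],
    n_sig_after = n_after,
    min_conditional_p = min(p_cond),
    ratio = chg$ratio,
    magnitude = chg$magnitude,
    nothing_to_explain = chg$nothing_to_explain,
    track = data.frame(snp = snp_ids, bp = bp, z_marginal = z,
                       p_marginal = p_marg, z_conditional = z_cond,
                       p_conditional = p_cond, stringsAsFactors = FALSE)
  ), class = "conditional_summary")
}
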