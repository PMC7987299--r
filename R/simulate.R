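#' Simulation configuration for a single cis locus
#'
#' Bundles every knob of the synthetic-data generator: the reference-panel
#' dimensions, the GWAS sample sizes for the estrogen-receptor (ER) subtype
#' scans, the LD structure of the locus, the genetic architecture of the gene
#' and its expression effects on disease.
#'
#' @param n_ref_individuals Number of reference-panel individuals with both
#'   genotypes and expression (default 67, a small eQTL panel).
#' @param n_gwas_cases_pos,n_gwas_cases_neg Numbers of ER+ and ER- cases in
#'   the GWAS the summary statistics emulate.
#' @param n_gwas_controls Number of shared GWAS controls.
#' @param n_snps Number of cis SNPs at the locus.
#' @param maf_range Interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param ld_rho First-order autoregressive correlation of the latent
#'   haplotype field; controls how fast LD decays with SNP index.
#' @param n_causal_eqtl Number of SNPs with nonzero effect on expression.
#' @param h2_cis Proportion of expression variance explained by the causal
#'   cis SNPs.
#' @param alpha_pos,alpha_neg Expression effects (log odds per SD of genetic
#'   expression) on ER+ and ER- disease.
#' @param architecture One of \code{"mediated"} (all SNP-disease signal flows
#'   through expression), \code{"pleiotropic"} (mediation plus a direct
#'   effect at a SNP with zero expression weight), \code{"colocalized"}
#'   (disease signal comes only from a non-eQTL SNP in LD with the causal
#'   eQTL) or \code{"null"} (no disease signal; requires zero alphas).
#' @param seed Master seed; per-stage sub-streams are derived from it.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_ref_individuals = 67,
                       n_gwas_cases_pos = 69501,
                       n_gwas_cases_neg = 21468,
                       n_gwas_controls = 105974,
                       n_snps = 100,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.7,
                       n_causal_eqtl = 3,
                       h2_cis = 0.2,
                       alpha_pos = 0,
                       alpha_neg = 0,
                       architecture = c("mediated", "pleiotropic",
                                        "colocalized", "null"),
                       seed = 1L) {
  architecture <- match.arg(architecture)
  counts <- c(n_ref_individuals, n_gwas_cases_pos, n_gwas_cases_neg,
              n_gwas_controls, n_snps)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2])
    stop("maf_range bounds inverted or malformed")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (h2_cis < 0 || h2_cis > 1) stop("h2_cis must be in [0, 1]")
  if (n_causal_eqtl > n_snps) stop("n_causal_eqtl cannot exceed n_snps")
  if (architecture == "null" && (alpha_pos != 0 || alpha_neg != 0))
    stop("architecture 'null' requires alpha_pos = alpha_neg = 0")
  structure(list(
    n_ref_individuals = as.integer(n_ref_individuals),
    n_gwas_cases_pos = as.integer(n_gwas_cases_pos),
    n_gwas_cases_neg = as.integer(n_gwas_cases_neg),
    n_gwas_controls = as.integer(n_gwas_controls),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    ld_rho = ld_rho,
    n_causal_eqtl = as.integer(n_causal_eqtl),
    h2_cis = h2_cis,
    alpha_pos = alpha_pos,
    alpha_neg = alpha_neg,
    architecture = architecture,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# one master seed, deterministic sub-streams per pipeline stage
stage_seed <- function(seed, stage) {
  offset <- c(panel = 11L, expression = 29L, gwas = 47L)[[stage]]
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Simulate an LD-structured diploid genotype panel
#'
#' Haplotypes are generated from a latent first-order autoregressive Gaussian
#' field along the SNP index and thresholded at the per-SNP allele-frequency
#' quantile, which yields tunable LD decay without a coalescent simulator.
#' Dosages count copies of the A1 (minor) allele. Positions are strictly
#' increasing on a single chromosome.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{genotype_panel}: list with \code{ids} (individuals),
#'   \code{snps} (data.frame: id, chrom, pos, a1, a2, maf) and \code{dosage}
#'   (individuals x SNPs matrix of 0/1/2).
#' @export
simulate_genotype_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_ref_individuals
  m <- config$n_snps
  rho <- config$ld_rho
  set.seed(stage_seed(config$seed, "panel"))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pos <- 1e6 + cumsum(sample(500:5000, m, replace = TRUE))

  # 2n haplotypes; AR(1) latent field column-recursive along SNPs
  lat <- matrix(stats::rnorm(2 * n * m), nrow = 2 * n, ncol = m)
  if (rho > 0 && m > 1) {
    sc <- sqrt(1 - rho^2)
    for (j in 2:m) lat[, j] <- rho * lat[, j - 1] + sc * lat[, j]
  }
  thr <- stats::qnorm(maf)
  hap <- sweep(lat, 2, thr, `<`) + 0
  dos <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]

  # guarantee polymorphism: give the first individual one minor-allele copy
  # at any column the thresholding left constant
  mono <- which(apply(dos, 2, function(x) length(unique(x)) == 1L))
  if (length(mono)) dos[1, mono] <- ifelse(dos[1, mono] == 0, 1, dos[1, mono] - 1)

  alle <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                   character(2)))
  freq <- colMeans(dos) / 2
  snps <- data.frame(
    id = sprintf("rs%05d", seq_len(m)),
    chrom = "1",
    pos = as.integer(pos),
    a1 = alle[, 1],
    a2 = alle[, 2],
    maf = pmin(freq, 1 - freq),
    stringsAsFactors = FALSE
  )
  dimnames(dos) <- list(sprintf("ind%04d", seq_len(n)), snps$id)
  structure(list(ids = rownames(dos), snps = snps, dosage = dos),
            class = "genotype_panel")
}

#' Simulate cis-heritable gene expression with known truth
#'
#' Expression is a linear predictor over column-standardized dosages at
#' \code{n_causal_eqtl} randomly placed causal SNPs plus Gaussian noise, with
#' effect sizes rescaled so the genetic and residual variance fractions equal
#' \code{h2_cis} and \code{1 - h2_cis} in expectation (exactly in-sample for
#' the genetic part).
#'
#' @param panel A \code{genotype_panel}.
#' @param config The \code{\link{sim_config}} used to build the panel.
#' @return List with \code{expression} (length-n vector) and \code{truth}, a
#'   \code{sim_truth} holding \code{causal_snp_indices}, per-SNP
#'   \code{true_weights} on the standardized-dosage scale (zero off the
#'   causal set), and \code{realized_h2}.
#' @export
simulate_expression <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (config$h2_cis > 1) stop("h2_cis cannot exceed 1")
  n <- nrow(panel$dosage)
  m <- ncol(panel$dosage)
  set.seed(stage_seed(config$seed, "expression"))

  causal <- sort(sample.int(m, config$n_causal_eqtl))
  w <- numeric(m)
  h2 <- config$h2_cis
  Z <- scale(panel$dosage)
  if (h2 > 0) {
    b <- stats::rnorm(length(causal))
    g_raw <- drop(Z[, causal, drop = FALSE] %*% b)
    vr <- stats::var(g_raw)
    if (vr <= 0) stop("degenerate genetic predictor; increase panel size")
    b <- b * sqrt(h2 / vr)
    w[causal] <- b
    g <- drop(Z[, causal, drop = FALSE] %*% b)
  } else {
    g <- numeric(n)
  }
  e <- if (h2 < 1) stats::rnorm(n, sd = sqrt(1 - h2)) else numeric(n)
  y <- g + e
  truth <- structure(list(
    causal_snp_indices = causal,
    true_weights = w,
    realized_h2 = if (stats::var(y) > 0) stats::var(g) / stats::var(y) else 0
  ), class = "sim_truth")
  list(expression = y, truth = truth)
}

# effective sample size of a balanced-variance case-control z-score
n_eff <- function(n_case, n_control) 4 / (1 / n_case + 1 / n_control)

#' Simulate subtype-stratified GWAS summary statistics at the z-score level
#'
#' Draws the four scans (overall, ER+, ER-, case-only) directly as
#' multivariate-normal z-scores with unit marginal variance and covariance
#' equal to the panel LD. Per-SNP means follow the configured architecture:
#' under mediation the marginal SNP effect on a subtype is
#' \code{alpha * cor(SNP, expression)}, scaled by the square root of the
#' scan's effective sample size. The case-only scan is oriented so that its
#' mean is proportional to \code{alpha_neg - alpha_pos} (effect allele
#' increases odds of ER- versus ER+ disease).
#'
#' @param panel A \code{genotype_panel}.
#' @param truth The \code{sim_truth} from \code{\link{simulate_expression}}.
#' @param config The shared \code{\link{sim_config}}.
#' @param ld Optional precomputed \code{ld_matrix} of the panel (reused
#'   across replicates for speed).
#' @return Named list of four \code{GwasSummary} data.frames
#'   (\code{overall}, \code{er_pos}, \code{er_neg}, \code{case_only}); each
#'   carries its vector of expected z-scores in attribute
#'   \code{"expected_z"}.
#' @export
simulate_subtype_gwas <- function(panel, truth, config, ld = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  arch <- config$architecture
  if (!arch %in% c("mediated", "pleiotropic", "colocalized", "null"))
    stop("unknown architecture label")
  m <- ncol(panel$dosage)
  if (length(truth$true_weights) != m)
    stop("truth inconsistent with panel")
  if (is.null(ld)) ld <- ld_matrix(panel)
  S <- ld$sigma
  set.seed(stage_seed(config$seed, "gwas"))

  # rescale true weights so w' S w = h2: then (S w)_s = cor(SNP_s, expression)
  w <- truth$true_weights
  lam <- numeric(m)
  if (any(w != 0)) {
    q <- drop(crossprod(w, S %*% w))
    if (q > 0) w <- w * sqrt(config$h2_cis / q)
    lam <- drop(S %*% w)
  }

  np <- config$n_gwas_cases_pos
  nn <- config$n_gwas_cases_neg
  nc <- config$n_gwas_controls
  alpha_ov <- (np * config$alpha_pos + nn * config$alpha_neg) / (np + nn)

  mediate <- function(alpha, neff) sqrt(neff) * alpha * lam
  mu <- list(
    overall = mediate(alpha_ov, n_eff(np + nn, nc)),
    er_pos = mediate(config$alpha_pos, n_eff(np, nc)),
    er_neg = mediate(config$alpha_neg, n_eff(nn, nc)),
    case_only = sqrt(n_eff(np, nn)) * (config$alpha_neg - config$alpha_pos) * lam
  )
  if (arch %in% c("pleiotropic", "colocalized")) {
    # direct disease effect at a SNP with zero expression weight, adjacent to
    # (hence in LD with) the first causal eQTL
    cz <- truth$causal_snp_indices[1]
    cand <- setdiff(c(cz + 1L, cz - 1L, which(truth$true_weights == 0)),
                    truth$causal_snp_indices)
    d <- cand[cand >= 1 & cand <= m][1]
    direct <- function(alpha, neff) sqrt(neff) * alpha * S[, d]
    add <- list(
      overall = direct(alpha_ov, n_eff(np + nn, nc)),
      er_pos = direct(config$alpha_pos, n_eff(np, nc)),
      er_neg = direct(config$alpha_neg, n_eff(nn, nc)),
      case_only = sqrt(n_eff(np, nn)) *
        (config$alpha_neg - config$alpha_pos) * S[, d]
    )
    if (arch == "colocalized") mu <- add
    else mu <- Map(`+`, mu, add)
  }
  if (arch == "null") mu <- lapply(mu, function(x) x * 0)

  # square root of the (PSD) LD matrix for correlated draws
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
  n_scan <- c(overall = np + nn + nc, er_pos = np + nc, er_neg = nn + nc,
              case_only = np + nn)
  out <- lapply(names(mu), function(scan) {
    z <- drop(mu[[scan]] + L %*% stats::rnorm(m))
    g <- gwas_summary(data.frame(
      SNP = panel$snps$id, CHR = panel$snps$chrom, BP = panel$snps$pos,
      A1 = panel$snps$a1, A2 = panel$snps$a2, Z = z,
      N = as.integer(n_scan[[scan]]), stringsAsFactors = FALSE
    ), scan_label = scan)
    attr(g, "expected_z") <- mu[[scan]]
    g
  })
  names(out) <- names(mu)
  out
}
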