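#' Genetic relationship matrix from dosages
#'
#' GCTA-style GRM: dosage columns are standardized to mean 0, variance 1 and
#' the matrix is ZZ'/m over the m SNPs, so the diagonal averages about 1 and
#' the matrix is symmetric positive semi-definite by construction.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @return n x n relationship matrix.
#' @export
grm <- function(genotypes) {
  if (nrow(genotypes) < 2) stop("need at least 2 individuals")
  v <- apply(genotypes, 2, stats::var)
  poly <- v > 0
  if (!any(poly)) stop("all SNPs monomorphic; GRM undefined")
  Z <- scale(genotypes[, poly, drop = FALSE])
  A <- tcrossprod(Z) / sum(poly)
  (A + t(A)) / 2
}

#' Precompute the eigendecomposition of a GRM
#'
#' REML with a single relationship matrix reduces, after rotation by the
#' GRM's eigenvectors, to diagonal weighted least squares, so the
#' decomposition can be shared across many phenotypes measured on the same
#' individuals (e.g. many genes or simulation replicates).
#'
#' @param A GRM, or an object already of class \code{grm_eigen} (returned
#'   unchanged).
#' @param tol Symmetry/PSD tolerance: eigenvalues below \code{-tol} are an
#'   error, small negatives are clamped to zero.
#' @return Object of class \code{grm_eigen} with \code{values} and
#'   \code{vectors}.
#' @export
grm_eigen <- function(A, tol = 1e-6) {
  if (inherits(A, "grm_eigen")) return(A)
  if (max(abs(A - t(A))) > tol) stop("GRM not symmetric within tolerance")
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("GRM not positive semi-definite within tolerance")
  e$values <- pmax(e$values, 0)
  class(e) <- "grm_eigen"
  e
}

# restricted log-likelihood and derived quantities in the eigenrotated basis,
# where V = diag(sg2 * d + se2); returns pieces reused by the REML updates
reml_pieces <- function(yt, Xt, d, sg2, se2) {
  v <- sg2 * d + se2
  if (any(v <= 0)) return(NULL)
  W <- 1 / v
  XtW <- Xt * W
  XtWX <- crossprod(Xt, XtW)
  XtWy <- crossprod(XtW, yt)
  cXtWX <- chol(XtWX)
  beta <- backsolve(cXtWX, backsolve(cXtWX, XtWy, transpose = TRUE))
  r <- yt - Xt %*% beta
  Py <- W * r                       # P y = V^{-1}(y - X beta_GLS)
  n <- length(yt); p <- ncol(Xt)
  yPy <- sum(yt * Py)
  ll <- -0.5 * ((n - p) * log(2 * pi) + sum(log(v)) +
                  2 * sum(log(diag(cXtWX))) + yPy)
  list(v = v, W = W, Py = drop(Py), ll = ll, XtWX_chol = cXtWX, Xt = Xt,
       d = d, yPy = yPy)
}

# apply the projection P to a vector t: P t = V^{-1} t - V^{-1} X (X'V^{-1}X)^{-1} X'V^{-1} t
P_apply <- function(pc, t) {
  Wt <- pc$W * t
  b <- backsolve(pc$XtWX_chol,
                 backsolve(pc$XtWX_chol, crossprod(pc$Xt, Wt),
                           transpose = TRUE))
  drop(Wt - pc$W * (pc$Xt %*% b))
}

# tr(P M) for M diagonal with entries mdiag in the rotated basis
P_trace <- function(pc, mdiag) {
  XtWMWX <- crossprod(pc$Xt * (pc$W * mdiag), pc$Xt * pc$W)
  inv <- chol2inv(pc$XtWX_chol)
  sum(pc$W * mdiag) - sum(inv * XtWMWX)
}

#' Estimate cis SNP-heritability of expression by REML
#'
#' Fits the single-variance-component model
#' \eqn{y = Xb + g + e}, \eqn{g \sim N(0, \sigma^2_g A)},
#' \eqn{e \sim N(0, \sigma^2_e I)} by average-information REML with
#' expectation-maximization fallback steps whenever an AI update leaves the
#' admissible region, and screens \eqn{\sigma^2_g = 0} with a likelihood
#' ratio test referred to the boundary-corrected 50:50 mixture of a point
#' mass at zero and a chi-square with one degree of freedom.
#'
#' @param expression Phenotype vector (one gene's expression).
#' @param grm Relationship matrix from \code{\link{grm}}, or a precomputed
#'   \code{\link{grm_eigen}}.
#' @param covariates Fixed-effect design matrix (an intercept is always
#'   added); e.g. genotype principal components.
#' @param tol Relative restricted log-likelihood convergence tolerance.
#' @param max_iter Maximum REML iterations; non-convergence is flagged in
#'   the result, not thrown.
#' @return Object of class \code{heritability_result}: list with h2,
#'   sigma2_g, sigma2_e, loglik_alt, loglik_null, lrt_p, converged, n_iter.
#' @export
reml_h2 <- function(expression, grm, covariates = NULL, tol = 1e-6,
                    max_iter = 100L) {
  y <- as.numeric(expression)
  eg <- grm_eigen(grm)
  n <- length(y)
  if (length(eg$values) != n) stop("expression length does not match GRM")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("covariates not of full column rank")
  # rotate to the GRM eigenbasis: V becomes diagonal
  U <- eg$vectors
  d <- eg$values
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  vp <- stats::var(y)
  if (vp == 0) stop("constant expression vector")
  floor_v <- 1e-8 * vp  # clamp components away from 0 to keep V invertible
  sg2 <- se2 <- vp / 2
  pc <- reml_pieces(yt, Xt, d, sg2, se2)
  ll_old <- pc$ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # score: dL/ds2_j = -0.5 (tr(P V_j) - y'P V_j P y), V_1 = A, V_2 = I
    PAy <- P_apply(pc, pc$d * pc$Py)
    score <- c(-0.5 * (P_trace(pc, pc$d) - sum(pc$Py * pc$d * pc$Py)),
               -0.5 * (P_trace(pc, rep(1, n)) - sum(pc$Py * pc$Py)))
    # average-information matrix: AI_jk = 0.5 y'P V_j P V_k P y
    PVg <- pc$d * pc$Py
    PVe <- pc$Py
    PPVg <- P_apply(pc, PVg)
    PPVe <- P_apply(pc, PVe)
    AI <- 0.5 * matrix(c(sum(PVg * PPVg), sum(PVg * PPVe),
                         sum(PVe * PPVg), sum(PVe * PPVe)), 2, 2)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    new <- if (!is.null(step)) c(sg2, se2) + step else NULL
    if (is.null(new) || any(!is.finite(new)) || any(new < floor_v) ||
        sum(new) > 100 * vp) {
      # EM fallback: s2_j_new = s2_j + s2_j^2/n (y'P V_j P y - tr(P V_j))
      new <- c(sg2 + sg2^2 / n * (sum(pc$Py * pc$d * pc$Py) -
                                    P_trace(pc, pc$d)),
               se2 + se2^2 / n * (sum(pc$Py^2) - P_trace(pc, rep(1, n))))
      new <- pmax(new, floor_v)
    }
    pc_new <- reml_pieces(yt, Xt, d, new[1], new[2])
    if (is.null(pc_new)) break
    sg2 <- new[1]; se2 <- new[2]
    pc <- pc_new
    if (abs(pc$ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- pc$ll
  }
  # null model: sigma2_g = 0, REML sigma2_e is RSS/(n - p) from OLS
  fit0 <- stats::lm.fit(Xt, yt)
  p <- ncol(Xt)
  se2_0 <- sum(fit0$residuals^2) / (n - p)
  pc0 <- reml_pieces(yt, Xt, d * 0, 0, se2_0)
  ll_null <- pc0$ll

  # boundary safeguard: EM creeps when the optimum is sigma2_g = 0 and can
  # stall below the null likelihood; the boundary solution is then the REML
  # optimum of the alternative as well
  pcb <- reml_pieces(yt, Xt, d, floor_v, se2_0)
  if (!is.null(pcb) && pcb$ll > pc$ll) {
    sg2 <- floor_v
    se2 <- se2_0
    pc <- pcb
    converged <- TRUE
  }
  ll_alt <- pc$ll

  at_floor <- sg2 <= floor_v * (1 + 1e-6)
  lrt <- max(0, 2 * (ll_alt - ll_null))
  lrt_p <- if (lrt <= 0 || at_floor) 1 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(
    h2 = sg2 / (sg2 + se2),
    sigma2_g = if (at_floor) 0 else sg2,
    sigma2_e = se2,
    loglik_alt = ll_alt,
    loglik_null = ll_null,
    lrt_p = lrt_p,
    converged = converged,
    n_iter = it
  ), class = "heritability_result")
}
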