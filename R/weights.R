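WEIGHT_METHODS <- c("blup", "lasso", "enet", "top1", "sparse_bayes")
# fixed tie-break order used by model selection
METHOD_PREFERENCE <- c("enet", "lasso", "blup", "sparse_bayes", "top1")

# residualize a phenotype on fixed covariates (intercept always included)
residualize <- function(y, covariates = NULL) {
  X <- cbind(rep(1, length(y)), covariates)
  stats::lm.fit(X, y)$residuals
}

# 50 log-spaced penalties spanning 3 decades down from the all-zero point
penalty_grid <- function(Z, y, alpha) {
  lmax <- max(abs(crossprod(Z, y))) / (length(y) * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50))
}

#' Fit per-gene SNP-to-expression weights by one of five methods
#'
#' Expression is residualized on the covariates and genotypes are
#' column-standardized before fitting, so all weights are on the
#' standardized-dosage scale. Methods: \code{blup} (ridge solution with
#' shrinkage fixed by the REML genetic/residual variance ratio),
#' \code{lasso} and \code{enet} (mixing parameter 0.5; coordinate descent
#' with the penalty chosen by inner cross-validation over a 50-point grid),
#' \code{top1} (marginal coefficient of the single SNP with the smallest
#' marginal p, all other weights zero) and \code{sparse_bayes}
#' (posterior-mean weights from a spike-and-slab Gibbs sampler).
#'
#' @param genotypes Individuals x SNPs dosage matrix (column names = SNP
#'   ids).
#' @param expression Expression vector.
#' @param covariates Optional fixed-effect covariate matrix.
#' @param method One of \code{"blup"}, \code{"lasso"}, \code{"enet"},
#'   \code{"top1"}, \code{"sparse_bayes"}.
#' @param hyperparams Optional list; recognized entries: \code{enet_alpha}
#'   (default 0.5), \code{lambda} (fixed penalty overriding inner CV),
#'   \code{n_iter}/\code{burn_in} for the Gibbs sampler, \code{h2} (slab
#'   scale; defaults to a REML estimate).
#' @param seed Seed controlling inner-CV folds and the Gibbs sampler.
#' @param gene_id Identifier stored in the result.
#' @return Object of class \code{weight_model}: gene_id, method, named
#'   weight vector (length = n SNPs), \code{empty} flag, and slots cv_r2,
#'   h2, h2_lrt_p to be filled by the caller.
#' @export
fit_weights <- function(genotypes, expression, covariates = NULL,
                        method = c("blup", "lasso", "enet", "top1",
                                   "sparse_bayes"),
                        hyperparams = list(), seed = 1L, gene_id = "gene") {
  method <- match.arg(method)
  y <- residualize(as.numeric(expression), covariates)
  Z <- scale(genotypes)
  m <- ncol(Z)
  n <- nrow(Z)
  w <- numeric(m)

  if (method == "top1") {
    # marginal simple-regression coefficient and t-test p per SNP
    bj <- drop(crossprod(Z, y)) / pmax(colSums(Z^2), .Machine$double.eps)
    rj <- suppressWarnings(as.numeric(stats::cor(Z, y)))
    rj[!is.finite(rj)] <- 0
    tj <- rj * sqrt(pmax(n - 2, 1)) / sqrt(pmax(1 - rj^2, 1e-12))
    pj <- 2 * stats::pt(-abs(tj), df = max(n - 2, 1))
    best <- which.min(pj)
    w[best] <- bj[best]
  } else if (method %in% c("lasso", "enet")) {
    alpha <- if (method == "lasso") 1 else
      if (!is.null(hyperparams$enet_alpha)) hyperparams$enet_alpha else 0.5
    grid <- penalty_grid(Z, y, alpha)
    if (!is.null(hyperparams$lambda)) {
      # include the requested penalty in the fitted path so the coefficient
      # lookup is exact without a refit
      path <- sort(unique(c(grid, hyperparams$lambda)), decreasing = TRUE)
      fit <- glmnet::glmnet(Z, y, alpha = alpha, lambda = path,
                            standardize = FALSE, intercept = TRUE,
                            thresh = 1e-12)
      w <- as.numeric(stats::coef(fit, s = hyperparams$lambda))[-1]
    } else {
      set.seed(seed)
      foldid <- sample(rep_len(1:5, n))
      cv <- glmnet::cv.glmnet(Z, y, alpha = alpha, lambda = grid,
                              foldid = foldid, standardize = FALSE,
                              intercept = TRUE)
      w <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    }
  } else if (method == "blup") {
    h <- reml_h2(y, grm(genotypes))
    ratio <- if (h$sigma2_g > 0) h$sigma2_e / h$sigma2_g else 1e8
    w <- drop(solve(crossprod(Z) + m * ratio * diag(m), crossprod(Z, y)))
  } else { # sparse_bayes
    n_iter <- if (!is.null(hyperparams$n_iter)) hyperparams$n_iter else 600L
    burn <- if (!is.null(hyperparams$burn_in)) hyperparams$burn_in else 200L
    h2 <- hyperparams$h2
    if (is.null(h2)) h2 <- max(reml_h2(y, grm(genotypes))$h2, 0.01)
    w <- spike_slab_gibbs(Z, y, h2 = h2, n_iter = n_iter, burn_in = burn,
                          seed = seed,
                          pi_fixed = hyperparams$pi_fixed)
  }

  names(w) <- colnames(genotypes)
  structure(list(gene_id = gene_id, method = method, weights = w,
                 empty = all(w == 0), cv_r2 = NA_real_, h2 = NA_real_,
                 h2_lrt_p = NA_real_),
            class = "weight_model")
}

# spike-and-slab Gibbs sampler: b_j = delta_j * N(0, s2b), delta_j ~ Bern(pi),
# pi ~ Beta(1, 1), slab variance initialized at h2/(expected causal count),
# s2b and s2e resampled from inverse-gamma conditionals
spike_slab_gibbs <- function(Z, y, h2, n_iter = 600L, burn_in = 200L,
                             seed = 1L, pi_fixed = NULL) {
  set.seed(seed)
  n <- nrow(Z); m <- ncol(Z)
  ZtZ_diag <- colSums(Z^2)
  b <- numeric(m)
  delta <- rep(FALSE, m)
  pi_inc <- if (is.null(pi_fixed)) 0.1 else pi_fixed
  vy <- stats::var(y)
  s2b <- max(h2 * vy / max(1, round(pi_inc * m)), 1e-6)
  s2e <- max((1 - h2) * vy, 1e-6)
  r <- y  # residual y - Z b
  acc <- numeric(m)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(m)) {
      r_j <- r + Z[, j] * b[j]          # residual excluding SNP j
      zr <- sum(Z[, j] * r_j)
      v_post <- 1 / (ZtZ_diag[j] / s2e + 1 / s2b)
      mu_post <- v_post * zr / s2e
      # log Bayes factor for inclusion
      lbf <- 0.5 * (log(v_post) - log(s2b)) + 0.5 * mu_post^2 / v_post
      p1 <- 1 / (1 + exp(-(lbf + log(pi_inc / (1 - pi_inc)))))
      delta[j] <- stats::runif(1) < p1
      b[j] <- if (delta[j]) stats::rnorm(1, mu_post, sqrt(v_post)) else 0
      r <- r_j - Z[, j] * b[j]
    }
    k <- sum(delta)
    if (is.null(pi_fixed))
      pi_inc <- stats::rbeta(1, 1 + k, 1 + m - k)
    pi_inc <- min(max(pi_inc, 1e-4), 1 - 1e-4)
    if (k > 0)
      s2b <- 1 / stats::rgamma(1, 1 + k / 2, 1 + sum(b[delta]^2) / 2)
    s2e <- 1 / stats::rgamma(1, 1 + n / 2, 1 + sum(r^2) / 2)
    if (it > burn_in) {
      acc <- acc + b
      kept <- kept + 1L
    }
  }
  acc / max(kept, 1L)
}

#' Fivefold cross-validated prediction accuracy of a weight method
#'
#' Individuals are partitioned into k disjoint folds; each fold's expression
#' is predicted from a model trained on the remaining folds, out-of-fold
#' predictions are concatenated, and the accuracy is the squared Pearson
#' correlation between predicted and observed expression (0 when the
#' prediction is constant).
#'
#' @inheritParams fit_weights
#' @param k Number of folds (default 5).
#' @return Scalar cv_r2 in [0, 1]; fold assignment is in attribute
#'   \code{"folds"}.
#' @export
cross_validate <- function(genotypes, expression, covariates = NULL,
                           method = "lasso", hyperparams = list(), k = 5L,
                           seed = 1L) {
  n <- nrow(genotypes)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("need at least k individuals")
  y <- residualize(as.numeric(expression), covariates)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    mod <- fit_weights(genotypes[!test, , drop = FALSE], y[!test],
                       method = method, hyperparams = hyperparams,
                       seed = seed + f)
    mu <- colMeans(genotypes[!test, , drop = FALSE])
    sd_ <- apply(genotypes[!test, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    Zt <- sweep(sweep(genotypes[test, , drop = FALSE], 2, mu), 2, sd_, `/`)
    pred[test] <- drop(Zt %*% mod$weights)
  }
  r2 <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) 0 else
    stats::cor(pred, y)^2
  structure(r2, folds = folds)
}

#' Select the best model for a gene and apply the inclusion filters
#'
#' A gene is excluded when its heritability likelihood-ratio p exceeds
#' \code{h2_p_max} or when no method reaches \code{cv_r2_min}; otherwise the
#' model with the largest cv_r2 is returned, ties broken by the fixed
#' preference order enet, lasso, blup, sparse_bayes, top1. Models flagged as
#' empty (all-zero weights) never qualify.
#'
#' @param models List of \code{weight_model}s for one gene, cv_r2 and h2
#'   fields filled.
#' @param h2_p_max Heritability screen (default 0.01).
#' @param cv_r2_min Prediction-accuracy screen (default 0.01); any one
#'   method reaching it qualifies the gene, the best model supplies the
#'   weights.
#' @return The selected \code{weight_model}, or a list of class
#'   \code{gene_exclusion} with the gene id and the reason
#'   (\code{"empty_model_set"}, \code{"h2_not_significant"},
#'   \code{"cv_r2_below_threshold"}).
#' @export
select_and_filter <- function(models, h2_p_max = 0.01, cv_r2_min = 0.01) {
  models <- Filter(function(mo) !isTRUE(mo$empty), models)
  excl <- function(id, why) structure(list(gene_id = id, reason = why),
                                      class = "gene_exclusion")
  if (!length(models)) return(excl(NA_character_, "empty_model_set"))
  id <- models[[1]]$gene_id
  h2p <- models[[1]]$h2_lrt_p
  if (is.na(h2p) || h2p > h2_p_max) return(excl(id, "h2_not_significant"))
  r2 <- vapply(models, function(mo) mo$cv_r2, numeric(1))
  if (max(r2, na.rm = TRUE) < cv_r2_min)
    return(excl(id, "cv_r2_below_threshold"))
  meth <- vapply(models, function(mo) mo$method, character(1))
  ord <- order(-r2, match(meth, METHOD_PREFERENCE))
  models[[ord[1]]]
}

#' Train, cross-validate and select expression weights for one gene
#'
#' Convenience wrapper running the full per-gene pipeline: REML heritability
#' screen, all five fitting methods with fivefold cross-validation, and
#' filtered model selection.
#'
#' @inheritParams fit_weights
#' @param methods Methods to fit (default all five).
#' @param h2_p_max,cv_r2_min Passed to \code{\link{select_and_filter}}.
#' @return As \code{\link{select_and_filter}}; selected models carry cv_r2,
#'   h2 and h2_lrt_p. The per-method cv_r2 table is in attribute
#'   \code{"method_table"}.
#' @export
train_gene_weights <- function(genotypes, expression, covariates = NULL,
                               methods = WEIGHT_METHODS, seed = 1L,
                               gene_id = "gene", h2_p_max = 0.01,
                               cv_r2_min = 0.01) {
  h <- reml_h2(residualize(expression, covariates), grm(genotypes))
  models <- lapply(methods, function(me) {
    mod <- fit_weights(genotypes, expression, covariates, method = me,
                       hyperparams = list(h2 = max(h$h2, 0.01)), seed = seed,
                       gene_id = gene_id)
    mod$cv_r2 <- as.numeric(cross_validate(genotypes, expression, covariates,
                                           method = me,
                                           hyperparams = list(h2 = max(h$h2, 0.01)),
                                           seed = seed))
    mod$h2 <- h$h2
    mod$h2_lrt_p <- h$lrt_p
    mod
  })
  sel <- select_and_filter(models, h2_p_max = h2_p_max,
                           cv_r2_min = cv_r2_min)
  attr(sel, "method_table") <- data.frame(
    method = vapply(models, `[[`, character(1), "method"),
    cv_r2 = vapply(models, `[[`, numeric(1), "cv_r2"))
  sel
}
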