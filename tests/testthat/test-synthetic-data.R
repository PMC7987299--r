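test_that("configuration rejects malformed inputs", {
  expect_error(make_config(maf_range = c(0.4, 0.1)), "inverted")
  expect_error(make_config(maf_range = c(0, 0.5)), "within")
  expect_error(make_config(n_snps = 0), "positive")
  expect_error(make_config(h2_cis = 1.5), "h2_cis")
  expect_error(make_config(ld_rho = 1), "ld_rho")
  expect_error(make_config(n_causal_eqtl = 50, n_snps = 10), "exceed")
  expect_error(make_config(architecture = "null", alpha_pos = 0.1),
               "alpha")
  expect_error(make_config(architecture = "backdoor"))
})

test_that("genotype panels are valid and reproducible", {
  cfg <- make_config(n_ref_individuals = 150, n_snps = 60, seed = 3)
  p1 <- simulate_genotype_panel(cfg)
  p2 <- simulate_genotype_panel(cfg)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
  expect_true(all(p1$dosage %in% 0:2))
  expect_true(all(diff(p1$snps$pos) > 0))
  expect_true(all(p1$snps$maf > 0 & p1$snps$maf <= 0.5))
  expect_true(all(p1$snps$a1 != p1$snps$a2))
  # empirical MAF close to the sampled range, allowing sampling error
  expect_true(all(p1$snps$maf > cfg$maf_range[1] - 3 * sqrt(0.25 / 300)))
})

test_that("ld_rho = 0 yields near-independent SNPs", {
  p <- make_panel(n_ref_individuals = 250, n_snps = 400, ld_rho = 0,
                  seed = 11)
  S <- stats::cor(p$dosage)
  off <- abs(S[upper.tri(S)])
  expect_lt(mean(off), 3 / sqrt(250))
})

test_that("adjacent-SNP correlation decays with lag under AR(1) LD", {
  adj <- lag10 <- numeric(50)
  for (s in 1:50) {
    p <- make_panel(n_ref_individuals = 120, n_snps = 40, ld_rho = 0.9,
                    seed = 100 + s)
    S <- stats::cor(p$dosage)
    m <- nrow(S)
    adj[s] <- mean(S[cbind(1:(m - 1), 2:m)])
    lag10[s] <- mean(S[cbind(1:(m - 10), 11:m)])
  }
  expect_gt(mean(adj), mean(lag10) + 0.2)
})

test_that("expression respects the heritability contract at the boundaries", {
  cfg0 <- make_config(h2_cis = 0, seed = 5, n_ref_individuals = 400)
  p <- simulate_genotype_panel(cfg0)
  ex0 <- simulate_expression(p, cfg0)
  expect_identical(ex0$truth$true_weights, numeric(ncol(p$dosage)))
  r2 <- as.numeric(stats::cor(p$dosage, ex0$expression))^2
  expect_lt(mean(r2), 3 / 400)  # E[r^2] is about 1/n under independence

  cfg1 <- make_config(h2_cis = 1, seed = 5)
  p1 <- simulate_genotype_panel(cfg1)
  ex1 <- simulate_expression(p1, cfg1)
  Zc <- scale(p1$dosage[, ex1$truth$causal_snp_indices])
  res <- stats::lm.fit(cbind(1, Zc), ex1$expression)$residuals
  expect_lt(max(abs(res)), 1e-10)
  expect_equal(ex1$truth$realized_h2, 1, tolerance = 1e-10)
  # non-causal SNPs carry exactly zero weight
  expect_true(all(ex1$truth$true_weights[-ex1$truth$causal_snp_indices] == 0))
})

test_that("realized heritability is unbiased at h2 = 0.5", {
  base <- make_config(h2_cis = 0.5, n_ref_individuals = 1000, n_snps = 50,
                      n_causal_eqtl = 3, seed = 1)
  p <- simulate_genotype_panel(base)
  h2 <- vapply(1:500, function(r) {
    cfg <- make_config(h2_cis = 0.5, n_ref_individuals = 1000, n_snps = 50,
                       n_causal_eqtl = 3, seed = 1000 + r)
    simulate_expression(p, cfg)$truth$realized_h2
  }, numeric(1))
  expect_gt(mean(h2), 0.47)
  expect_lt(mean(h2), 0.53)
})

test_that("null-architecture z-scores are calibrated", {
  cfg <- make_config(architecture = "null", alpha_pos = 0, alpha_neg = 0,
                     n_ref_individuals = 150, n_snps = 50, seed = 2)
  p <- simulate_genotype_panel(cfg)
  ld <- ld_matrix(p)
  ex <- simulate_expression(p, cfg)
  hits <- vapply(1:200, function(r) {
    cfg_r <- make_config(architecture = "null", alpha_pos = 0,
                         alpha_neg = 0, n_ref_individuals = 150,
                         n_snps = 50, seed = 5000 + r)
    sc <- simulate_subtype_gwas(p, ex$truth, cfg_r, ld = ld)
    mean(abs(sc$overall$Z) > 1.96)
  }, numeric(1))
  expect_lt(abs(mean(hits) - 0.05), 0.01)
})

test_that("case-only scan is null when both subtype effects are equal", {
  cfg <- make_config(alpha_pos = 0.15, alpha_neg = 0.15,
                     architecture = "mediated", seed = 8,
                     n_ref_individuals = 200, n_snps = 30)
  p <- simulate_genotype_panel(cfg)
  ex <- simulate_expression(p, cfg)
  ld <- ld_matrix(p)
  sc <- simulate_subtype_gwas(p, ex$truth, cfg, ld = ld)
  expect_equal(unname(attr(sc$case_only, "expected_z")), rep(0, 30))
  zs <- unlist(lapply(1:150, function(r) {
    cfg_r <- make_config(alpha_pos = 0.15, alpha_neg = 0.15,
                         architecture = "mediated", seed = 7000 + r,
                         n_ref_individuals = 200, n_snps = 30)
    simulate_subtype_gwas(p, ex$truth, cfg_r, ld = ld)$case_only$Z
  }))
  expect_lt(abs(mean(zs)), 3 * stats::sd(zs) / sqrt(150))
})

test_that("mediated causal-SNP mean matches the closed form", {
  mk <- function(s) make_config(architecture = "mediated", alpha_pos = 0.02,
                                alpha_neg = 0, h2_cis = 0.6,
                                n_causal_eqtl = 1, n_snps = 20,
                                n_ref_individuals = 300, seed = s)
  cfg <- mk(4)
  p <- simulate_genotype_panel(cfg)
  ex <- simulate_expression(p, cfg)
  ld <- ld_matrix(p)
  cz <- ex$truth$causal_snp_indices
  neff <- 4 / (1 / 60000 + 1 / 100000)
  # the generator draws the causal weight's sign at random
  closed <- sign(ex$truth$true_weights[cz]) * sqrt(neff) * 0.02 * sqrt(0.6)
  # deterministic check of the generator's expected z at the causal SNP
  sc <- simulate_subtype_gwas(p, ex$truth, cfg, ld = ld)
  expect_equal(unname(attr(sc$er_pos, "expected_z")[cz]), closed,
               tolerance = 1e-8)
  # empirical mean over replicates within Monte-Carlo error
  zc <- vapply(1:300, function(r)
    simulate_subtype_gwas(p, ex$truth, mk(9000 + r), ld = ld)$er_pos$Z[cz],
    numeric(1))
  expect_equal(mean(zc), closed, tolerance = 4 / sqrt(300))
})

test_that("null replicate z-score correlation converges to panel LD", {
  cfg <- make_config(architecture = "null", alpha_pos = 0, alpha_neg = 0,
                     n_ref_individuals = 200, n_snps = 12, ld_rho = 0.8,
                     seed = 6)
  p <- simulate_genotype_panel(cfg)
  ld <- ld_matrix(p)
  ex <- simulate_expression(p, cfg)
  Zs <- vapply(1:2000, function(r) {
    cfg_r <- make_config(architecture = "null", alpha_pos = 0,
                         alpha_neg = 0, n_ref_individuals = 200,
                         n_snps = 12, ld_rho = 0.8, seed = 20000 + r)
    simulate_subtype_gwas(p, ex$truth, cfg_r, ld = ld)$er_neg$Z
  }, numeric(12))
  pairs <- list(c(1, 2), c(5, 6), c(3, 12))
  for (pr in pairs) {
    expect_lt(abs(stats::cor(Zs[pr[1], ], Zs[pr[2], ]) -
                    ld$sigma[pr[1], pr[2]]), 0.05)
  }
})

test_that("overall-scan signal is monotone in both subtype effects", {
  cfg <- make_config(architecture = "mediated", alpha_pos = 0.05,
                     alpha_neg = 0.05, n_causal_eqtl = 1, seed = 12)
  p <- simulate_genotype_panel(cfg)
  ex <- simulate_expression(p, cfg)
  ld <- ld_matrix(p)
  cz <- ex$truth$causal_snp_indices
  sgn <- sign(ex$truth$true_weights[cz])  # causal weight sign is random
  mu_at <- function(ap, an) {
    cfg_a <- make_config(architecture = "mediated", alpha_pos = ap,
                         alpha_neg = an, n_causal_eqtl = 1, seed = 12)
    sgn * attr(simulate_subtype_gwas(p, ex$truth, cfg_a, ld = ld)$overall,
               "expected_z")[[cz]]
  }
  grid <- c(0.02, 0.05, 0.1, 0.2)
  expect_true(all(diff(vapply(grid, mu_at, numeric(1), an = 0.05)) > 0))
  expect_true(all(diff(vapply(grid, mu_at, numeric(1), ap = 0.05,
                              USE.NAMES = FALSE)) > 0))
})
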