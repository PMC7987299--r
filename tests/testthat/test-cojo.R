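test_that("region grouping merges by transitive closure within the window", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "1",
                      start = c(1.0e6, 1.4e6), end = c(1.0e6, 1.4e6))
  r <- group_regions(genes)
  expect_equal(nrow(r), 1L)
  expect_identical(r$gene_ids, "a,b")

  # chaining: a-b and b-c within the window, a-c not
  genes3 <- data.frame(gene_id = c("a", "b", "c"), chrom = "1",
                       start = c(1.0e6, 1.4e6, 1.9e6),
                       end = c(1.0e6, 1.4e6, 1.9e6))
  # independent transitive-closure oracle on pairwise gap distances
  d <- as.matrix(dist(genes3$start))
  adj <- d <= 5e5
  reach <- adj
  for (k in 1:3) reach <- reach | (reach %*% adj > 0)
  expect_true(all(reach))  # the three genes form one chained component
  r3 <- group_regions(genes3)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$n_genes, 3L)

  # same positions on different chromosomes stay apart
  genes4 <- data.frame(gene_id = c("a", "b"), chrom = c("1", "2"),
                       start = 1e6, end = 1e6)
  expect_equal(nrow(group_regions(genes4)), 2L)

  # far apart on one chromosome: two regions, sorted by position
  genes5 <- data.frame(gene_id = c("z", "a"), chrom = "1",
                       start = c(9e6, 1e6), end = c(9e6, 1e6))
  r5 <- group_regions(genes5)
  expect_equal(r5$gene_ids, c("a", "z"))
})

test_that("feature correlations match individual-level predicted expression", {
  w1 <- stats::setNames(c(1, 0.5, 0, 0, 0), sprintf("rs%d", 1:5))
  expect_equal(feature_correlation(w1, w1, toy_ld(diag(5))), 1)
  w2 <- stats::setNames(c(0, 0, 0, 0.3, -1), sprintf("rs%d", 1:5))
  expect_equal(feature_correlation(w1, w2, toy_ld(diag(5))), 0)
  expect_error(feature_correlation(w1 * 0, w2, toy_ld(diag(5))),
               "zero-variance")

  p <- make_panel(seed = 81, n_ref_individuals = 2000, n_snps = 5,
                  ld_rho = 0.6)
  ld <- ld_matrix(p)
  set.seed(81)
  wa <- stats::setNames(rnorm(5), p$snps$id)
  wb <- stats::setNames(rnorm(5), p$snps$id)
  Z <- scale(p$dosage)
  r_ind <- stats::cor(drop(Z %*% wa), drop(Z %*% wb))
  expect_equal(feature_correlation(wa, wb, ld), r_ind, tolerance = 0.02)
})

test_that("joint analysis solves the normal equations and prunes collinearity", {
  z <- c(g1 = 3, g2 = -2.5)
  out <- joint_gene_analysis(z, diag(2))
  expect_equal(out$z_joint, unname(z))            # identity R: joint = marginal
  expect_equal(out$p_joint, out$p_marginal)

  # perfect collinearity: weaker gene pruned, not inverted
  R1 <- matrix(c(1, 1, 1, 1), 2, 2)
  out1 <- joint_gene_analysis(c(g1 = 6, g2 = 5.9), R1)
  expect_false(out1$pruned[1])
  expect_true(out1$pruned[2])
  expect_true(is.na(out1$z_joint[2]))

  # worked instance from a published two-gene region (marginal z 6.7, -5.22)
  z2 <- c(a = 6.7, b = -5.22)
  r <- -0.5
  R2 <- matrix(c(1, r, r, 1), 2, 2)
  # independently coded normal-equations solve
  b <- solve(R2, z2)
  zj <- b / sqrt(diag(solve(R2)))
  out2 <- joint_gene_analysis(z2, R2)
  expect_equal(out2$z_joint, unname(zj), tolerance = 1e-8)
  expect_true(all(out2$retained == (out2$p_joint < 0.05)))

  # single gene: joint equals marginal exactly
  out3 <- joint_gene_analysis(c(only = 4.2), matrix(1, 1, 1))
  expect_equal(out3$z_joint, 4.2)

  # order invariance up to row order
  out4 <- joint_gene_analysis(z2[2:1], R2[2:1, 2:1])
  expect_equal(out4$z_joint[match(names(z2), out4$gene_id)],
               out2$z_joint, tolerance = 1e-10)
})

test_that("conditional SNP z-scores reduce correctly in edge cases", {
  # uncorrelated feature leaves the SNP untouched
  r0 <- conditional_snp_z(2.3, rho = 0, R = matrix(1, 1, 1), z_genes = 5)
  expect_equal(r0$z_cond, 2.3)
  # a single-SNP gene conditioned on itself is fully explained
  r1 <- conditional_snp_z(2.3, rho = 1, R = matrix(1, 1, 1), z_genes = 2.3)
  expect_true(r1$fully_explained)
  expect_equal(r1$p_cond, 1)
  expect_error(conditional_snp_z(1, rho = 1.5, matrix(1, 1, 1), 1), "rho")
})

test_that("conditional z matches an individual-level two-stage regression", {
  cfg <- make_config(n_ref_individuals = 5000, n_snps = 3, ld_rho = 0.5,
                     h2_cis = 1, n_causal_eqtl = 2, seed = 83)
  p <- simulate_genotype_panel(cfg)
  Z <- scale(p$dosage)
  set.seed(83)
  w <- c(0.8, -0.4, 0)
  f <- drop(Z[, 1:3] %*% w)               # predicted expression feature
  y <- 0.05 * f + rnorm(5000)             # modest trait effect
  n <- 5000
  # marginal GWAS z-scores as regression t-statistics
  z_snp <- vapply(1:3, function(j) {
    fit <- stats::lm(y ~ Z[, j])
    stats::coef(summary(fit))[2, 3]
  }, numeric(1))
  ld <- ld_matrix(p)
  wm <- toy_model(stats::setNames(w, p$snps$id))
  z_gene <- twas_z(wm, toy_gwas(p$snps$id, p$snps$a1, p$snps$a2, z_snp),
                   ld)$z_twas
  rho <- drop(ld$sigma %*% w) / sqrt(drop(t(w) %*% ld$sigma %*% w))
  for (j in 1:3) {
    oracle <- stats::coef(summary(stats::lm(y ~ Z[, j] + f)))[2, 3]
    got <- conditional_snp_z(z_snp[j], rho[j], matrix(1, 1, 1), z_gene)
    if (got$fully_explained) next
    expect_equal(got$z_cond, oracle, tolerance = 0.05)
  }
})

test_that("conditional summaries reproduce the ratio and magnitude algebra", {
  # inputs matching two published conditional-analysis rows
  a <- cojo_change_summary(12, 1, 8.2e-17, 6.4e-9)
  expect_equal(round(a$ratio, 2), 0.92)
  expect_equal(signif(a$magnitude, 3), 1.28e-8)
  b <- cojo_change_summary(12, 6, 8.2e-17, 3.9e-12)
  expect_equal(round(b$ratio, 2), 0.50)
  expect_equal(signif(b$magnitude, 3), 2.10e-5)
  # unchanged minimum p: magnitude exactly 1
  c0 <- cojo_change_summary(36, 36, 2.8e-44, 2.8e-44)
  expect_equal(c0$magnitude, 1)
  expect_equal(c0$ratio, 0)
  # nothing significant before conditioning: ratio 1 by convention, flagged
  d <- cojo_change_summary(0, 0, 0.2, 0.4)
  expect_true(d$nothing_to_explain)
  expect_equal(d$ratio, 1)
})

test_that("conditioning on an uncorrelated gene changes no SNP z", {
  # gene weights on SNPs uncorrelated with the scan SNPs (block identity LD)
  S <- diag(6)
  ld <- toy_ld(S, sprintf("rs%d", 1:6))
  w <- stats::setNames(c(0, 0, 0, 0, 1, 0.5), sprintf("rs%d", 1:6))
  set.seed(84)
  zv <- c(rnorm(4, sd = 3), 0.1, -0.2)
  g <- toy_gwas(sprintf("rs%d", 1:6), rep("A", 6), rep("G", 6), zv)
  cs <- conditional_region_summary(g, toy_model(w), ld,
                                   snp_ids = sprintf("rs%d", 1:4))
  expect_equal(cs$track$z_conditional, cs$track$z_marginal,
               tolerance = 1e-10)
})

test_that("a fully mediated gene explains its locus' genome-wide signal", {
  cfg0 <- make_config(n_ref_individuals = 300, n_snps = 20, h2_cis = 0.5,
                      n_causal_eqtl = 3, alpha_pos = 0.03,
                      architecture = "mediated", seed = 85)
  p <- simulate_genotype_panel(cfg0)
  ex <- simulate_expression(p, cfg0)
  ld0 <- ld_matrix(p)
  ld <- regularize_ld(ld0, 0.1)
  mod <- toy_model(stats::setNames(ex$truth$true_weights, p$snps$id))
  cleared <- vapply(1:50, function(r) {
    cfg_r <- make_config(n_ref_individuals = 300, n_snps = 20,
                         h2_cis = 0.5, n_causal_eqtl = 3, alpha_pos = 0.03,
                         architecture = "mediated", seed = 85000 + r)
    sc <- simulate_subtype_gwas(p, ex$truth, cfg_r, ld = ld0)$er_pos
    cs <- conditional_region_summary(sc, mod, ld)
    cs$n_sig_after == 0
  }, logical(1))
  expect_gte(mean(cleared), 0.95)
})
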