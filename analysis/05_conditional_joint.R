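#!/usr/bin/env Rscript
# Stage 5: conditional and joint analyses. (a) For each tested gene,
# condition the locus' SNP z-scores on the gene's predicted expression and
# summarize how much genome-wide-significant signal survives (ratio and
# magnitude of change in the minimum p). (b) Group genes into regions and,
# where a region holds several genes, jointly model their TWAS z-scores to
# find the independently associated ones.

library(twaskit)
source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "params.R"))

tab <- utils::read.delim("results/twas_results.tsv")
wf <- read_weights("results/weights.tsv")
gw_thr <- 5e-8

load_model <- function(gene) {
  wr <- wf[wf$gene_id == gene, ]
  structure(list(gene_id = gene, method = wr$method[1],
                 weights = stats::setNames(wr$weight, wr$snp_id),
                 empty = FALSE, cv_r2 = wr$cv_r2[1], h2 = wr$h2[1],
                 h2_lrt_p = wr$h2_lrt_p[1]), class = "weight_model")
}

## (a) per-gene conditional summaries on the ER+ scan
cond <- do.call(rbind, lapply(tab$gene_id, function(gene) {
  sim <- build_gene(gene)
  mod <- load_model(gene)
  ld <- regularize_ld(ld_matrix(sim$panel), TWAS_LAMBDA)
  g <- harmonize_alleles(sim$scans$er_pos, sim$panel, drop_ambiguous = FALSE)
  cs <- conditional_region_summary(g, mod, ld, gw_threshold = gw_thr)
  utils::write.table(
    cbind(chrom = "1", cs$track[, c("bp", "snp", "z_marginal",
                                    "z_conditional")]),
    file.path("results", paste0(gene, "_conditional_track.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  data.frame(gene_id = gene, n_snps = cs$n_snps,
             n_sig_before = cs$n_sig_before, index_snp = cs$index_snp,
             index_p = cs$index_p, n_sig_after = cs$n_sig_after,
             min_conditional_p = cs$min_conditional_p,
             ratio = cs$ratio, magnitude = cs$magnitude)
}))
utils::write.table(cond,
                   "results/conditional_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("conditional analysis on the ER+ scan (threshold 5e-8):\n")
print(format(cond, digits = 3), row.names = FALSE)

## (b) joint analysis of multi-gene regions
regions <- group_regions(GENE_TABLE[GENE_TABLE$gene_id %in% tab$gene_id, ])
cat("\nregions:\n"); print(regions, row.names = FALSE)
for (i in seq_len(nrow(regions))) {
  ids <- strsplit(regions$gene_ids[i], ",")[[1]]
  if (length(ids) < 2) next
  # feature correlations need a common SNP frame; the simulated loci share
  # SNP ids, so embed weights over the union and use the first gene's panel
  sim <- build_gene(ids[1])
  ld <- regularize_ld(ld_matrix(sim$panel), TWAS_LAMBDA)
  z <- stats::setNames(tab$z_overall[match(ids, tab$gene_id)], ids)
  mods <- lapply(ids, function(g) load_model(g)$weights)
  R <- diag(length(ids))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a < b)
      R[a, b] <- R[b, a] <- feature_correlation(mods[[a]], mods[[b]], ld)
  }
  jr <- joint_gene_analysis(z, R)
  utils::write.table(format(jr, digits = 3),
                     file.path("results",
                               paste0(regions$region_id[i], "_joint.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\njoint analysis,", regions$region_id[i], ":\n")
  print(format(jr, digits = 3), row.names = FALSE)
}
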