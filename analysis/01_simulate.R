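#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study materials — an LD-structured
# reference panel with cis-heritable expression for several genes, and
# subtype-stratified GWAS summary scans (overall, ER+, ER-, case-only) with
# known truth. Later stages regenerate the same objects from the shared
# parameters below, so each script runs standalone; this one also exports
# the panel and scans as interchange text for inspection.

library(twaskit)

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "params.R"))

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

for (g in seq_along(GENE_CONFIGS)) {
  cfg <- GENE_CONFIGS[[g]]
  panel <- simulate_genotype_panel(cfg)
  expr <- simulate_expression(panel, cfg)
  scans <- simulate_subtype_gwas(panel, expr$truth, cfg)
  gene <- names(GENE_CONFIGS)[g]
  write_panel_tped(panel, file.path("results/sim", gene))
  write_panel_vcf(panel, file.path("results/sim", paste0(gene, ".vcf")))
  utils::write.table(
    data.frame(individual = panel$ids, expression = expr$expression),
    file.path("results/sim", paste0(gene, "_expression.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (scan in names(scans)) {
    write_gwas(scans[[scan]],
               file.path("results/sim", paste0(gene, "_", scan, ".tsv")))
  }
  cat(sprintf(
    "%s [%s]: %d individuals x %d SNPs, realized cis-h2 %.2f, causal SNPs %s\n",
    gene, cfg$architecture, nrow(panel$dosage), ncol(panel$dosage),
    expr$truth$realized_h2,
    paste(expr$truth$causal_snp_indices, collapse = ",")))
}
cat("wrote panels, expression and four GWAS scans per gene under results/sim/\n")
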