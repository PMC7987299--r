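# Shared study parameters for the analysis scripts. One simulated cis locus
# per gene; GWAS sample sizes follow the breast-cancer meta-analysis scale
# (69,501 ER+ cases, 21,468 ER- cases, 105,974 controls) while the reference
# panel is a small eQTL panel (67 individuals in the study emulated here;
# 300 here so the weight models are estimable at desk scale).

MASTER_SEED <- 20240101

gene_cfg <- function(offset, ...) {
  twaskit::sim_config(
    n_ref_individuals = 300, n_snps = 60, maf_range = c(0.05, 0.5),
    ld_rho = 0.7, n_causal_eqtl = 3,
    n_gwas_cases_pos = 69501, n_gwas_cases_neg = 21468,
    n_gwas_controls = 105974,
    seed = MASTER_SEED + offset, ...)
}

GENE_CONFIGS <- list(
  # shared effect on both subtypes, fully mediated through expression
  geneA_shared = gene_cfg(1, h2_cis = 0.4, alpha_pos = 0.04,
                          alpha_neg = 0.04, architecture = "mediated"),
  # ER+-specific effect: the case-only scan should light up
  geneB_erpos = gene_cfg(2, h2_cis = 0.3, alpha_pos = 0.05, alpha_neg = 0,
                         architecture = "mediated"),
  # disease signal from a neighbouring non-eQTL SNP (colocalization)
  geneC_coloc = gene_cfg(3, h2_cis = 0.4, alpha_pos = 0.04,
                         alpha_neg = 0.04, architecture = "colocalized"),
  # heritable expression but no disease effect
  geneD_null = gene_cfg(4, h2_cis = 0.5, architecture = "null"),
  # expression not heritable: should fail the REML screen
  geneE_nonherit = gene_cfg(5, h2_cis = 0, architecture = "null")
)

# gene coordinates used for region grouping (one chromosome, two clusters)
GENE_TABLE <- data.frame(
  gene_id = names(GENE_CONFIGS),
  chrom = "1",
  start = c(1.00e6, 1.35e6, 2.60e6, 4.00e6, 5.00e6),
  end = c(1.05e6, 1.40e6, 2.65e6, 4.05e6, 5.05e6),
  stringsAsFactors = FALSE)
GENE_TABLE$cis_start <- GENE_TABLE$start - 5e5
GENE_TABLE$cis_end <- GENE_TABLE$end + 5e5

TWAS_LAMBDA <- 0.1

# regenerate the full simulated state for one gene
build_gene <- function(gene) {
  cfg <- GENE_CONFIGS[[gene]]
  panel <- twaskit::simulate_genotype_panel(cfg)
  expr <- twaskit::simulate_expression(panel, cfg)
  scans <- twaskit::simulate_subtype_gwas(panel, expr$truth, cfg)
  list(cfg = cfg, panel = panel, expression = expr$expression,
       truth = expr$truth, scans = scans)
}
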