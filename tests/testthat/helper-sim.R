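# shared fixture builders; everything is generated in code at test time

make_config <- function(...) {
  args <- list(...)
  defaults <- list(n_ref_individuals = 200, n_snps = 30, n_causal_eqtl = 2,
                   h2_cis = 0.4, ld_rho = 0.5, maf_range = c(0.1, 0.5),
                   n_gwas_cases_pos = 60000, n_gwas_cases_neg = 20000,
                   n_gwas_controls = 100000, seed = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}

make_panel <- function(...) simulate_genotype_panel(make_config(...))

# hand-built tiny panel with fixed alleles, for harmonization tests
toy_panel <- function(a1 = c("G", "A", "A", "C"),
                      a2 = c("A", "C", "T", "G")) {
  m <- length(a1)
  set.seed(42)
  dos <- matrix(sample(0:2, 12 * m, replace = TRUE), 12, m)
  dos[1, ] <- 1  # guarantee polymorphism
  snps <- data.frame(id = sprintf("rs%d", seq_len(m)), chrom = "1",
                     pos = 1000L * seq_len(m), a1 = a1, a2 = a2,
                     maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
                     stringsAsFactors = FALSE)
  dimnames(dos) <- list(sprintf("i%02d", 1:12), snps$id)
  structure(list(ids = rownames(dos), snps = snps, dosage = dos),
            class = "genotype_panel")
}

toy_gwas <- function(snp, a1, a2, z, scan = "overall", chr = "1",
                     bp = 1000L * seq_along(snp), n = 1000L) {
  gwas_summary(data.frame(SNP = snp, CHR = chr, BP = bp, A1 = a1, A2 = a2,
                          Z = z, N = n, stringsAsFactors = FALSE), scan)
}

# ld_matrix object from an explicit correlation matrix
toy_ld <- function(S, ids = sprintf("rs%d", seq_len(nrow(S)))) {
  structure(list(snp_ids = ids, sigma = S, lambda = 0), class = "ld_matrix")
}

# weight_model from a named numeric vector
toy_model <- function(w, gene_id = "gene", cv_r2 = 0.5, h2 = 0.3,
                      h2_lrt_p = 1e-4, method = "enet") {
  structure(list(gene_id = gene_id, method = method, weights = w,
                 empty = all(w == 0), cv_r2 = cv_r2, h2 = h2,
                 h2_lrt_p = h2_lrt_p), class = "weight_model")
}
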