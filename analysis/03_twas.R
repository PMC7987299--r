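#!/usr/bin/env Rscript
# Stage 3: summary-statistics TWAS of every tested gene against the four
# scans, with allele harmonization, ridge-regularized reference LD and a
# Bonferroni threshold over the tested genes. Mirrors the layout of a
# per-gene association table (h2, cv r2, one p per scan).

library(twaskit)
source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "params.R"))

screen <- utils::read.delim("results/gene_screen.tsv")
tested <- screen$gene_id[screen$status == "tested"]
wf <- read_weights("results/weights.tsv")

rows <- lapply(tested, function(gene) {
  sim <- build_gene(gene)
  wrows <- wf[wf$gene_id == gene, ]
  w <- stats::setNames(wrows$weight, wrows$snp_id)
  mod <- structure(list(gene_id = gene, method = wrows$method[1],
                        weights = w, empty = FALSE, cv_r2 = wrows$cv_r2[1],
                        h2 = wrows$h2[1], h2_lrt_p = wrows$h2_lrt_p[1]),
                   class = "weight_model")
  ld <- regularize_ld(ld_matrix(sim$panel, names(w)), TWAS_LAMBDA)
  st <- vapply(names(sim$scans), function(scan) {
    g <- harmonize_alleles(sim$scans[[scan]], sim$panel, drop_ambiguous = FALSE)
    res <- if (scan == "case_only") case_only_test(mod, g, ld)
           else twas_z(mod, g, ld)
    if (inherits(res, "twas_skip")) c(NA_real_, NA_real_)
    else c(res$z_twas, res$p)
  }, numeric(2))
  data.frame(gene_id = gene, method = wrows$method[1], h2 = wrows$h2[1],
             cv_r2 = wrows$cv_r2[1], n_snps = length(w),
             z_overall = st[1, "overall"], p_overall = st[2, "overall"],
             z_er_pos = st[1, "er_pos"], p_er_pos = st[2, "er_pos"],
             z_er_neg = st[1, "er_neg"], p_er_neg = st[2, "er_neg"],
             z_case_only = st[1, "case_only"],
             p_case_only = st[2, "case_only"])
})
tab <- do.call(rbind, rows)

thr <- bonferroni_threshold(0.05, nrow(tab))
for (scan in c("p_overall", "p_er_pos", "p_er_neg", "p_case_only")) {
  tab[[sub("p_", "sig_", scan)]] <- tab[[scan]] < thr
}
utils::write.table(tab, "results/twas_results.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Bonferroni threshold 0.05/%d = %.2g\n", nrow(tab), thr))
cat(sprintf("significant genes: overall %d, ER+ %d, ER- %d, case-only %d\n",
            count_significant(tab, thr, "p_overall"),
            count_significant(tab, thr, "p_er_pos"),
            count_significant(tab, thr, "p_er_neg"),
            count_significant(tab, thr, "p_case_only")))
print(format(tab[, c("gene_id", "method", "h2", "cv_r2", "p_overall",
                     "p_er_pos", "p_er_neg", "p_case_only")], digits = 3),
      row.names = FALSE)
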