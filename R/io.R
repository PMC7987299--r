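#' Construct a GWAS summary-statistics object
#'
#' A \code{GwasSummary} is a data.frame with columns SNP, CHR, BP, A1
#' (effect allele), A2 (other allele), Z and N, plus a scan label identifying
#' which case-control contrast it comes from.
#'
#' @param df data.frame with the seven columns above.
#' @param scan_label One of \code{"overall"}, \code{"er_pos"},
#'   \code{"er_neg"}, \code{"case_only"}.
#' @return The validated data.frame with class \code{gwas_summary}.
#' @export
gwas_summary <- function(df, scan_label = c("overall", "er_pos", "er_neg",
                                            "case_only")) {
  scan_label <- match.arg(scan_label)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "N")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$SNP)) stop("snp ids must be unique within a scan")
  if (any(df$A1 == df$A2)) stop("effect and other allele must differ")
  if (any(!is.finite(df$Z))) stop("z-scores must be finite")
  structure(df, class = c("gwas_summary", "data.frame"),
            scan_label = scan_label)
}

#' @rdname gwas_summary
#' @param x Object to query.
#' @export
scan_label <- function(x) attr(x, "scan_label")

#' Read and write GWAS summary statistics
#'
#' Tab-delimited with header SNP, CHR, BP, A1, A2, Z, N.
#'
#' @param path File path.
#' @param scan_label Scan label to attach on read.
#' @return \code{read_gwas} returns a \code{gwas_summary};
#'   \code{write_gwas} returns the path invisibly.
#' @export
read_gwas <- function(path, scan_label = "overall") {
  df <- utils::read.delim(path, colClasses = c(
    SNP = "character", CHR = "character", BP = "integer", A1 = "character",
    A2 = "character", Z = "numeric", N = "integer"))
  gwas_summary(df, scan_label)
}

#' @rdname read_gwas
#' @param gwas A \code{gwas_summary}.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write and read a genotype panel as PLINK-style transposed text
#'
#' \code{write_panel_tped} emits \code{<prefix>.tped} (one row per SNP:
#' chrom, id, 0, pos, then two alleles per individual) and
#' \code{<prefix>.tfam} (one row per individual). \code{read_panel_tped}
#' inverts it; dosages count copies of the first-listed (A1) allele of each
#' SNP row as recorded during writing, recovered as the less frequent allele.
#'
#' @param panel A \code{genotype_panel}.
#' @param prefix Path prefix without extension.
#' @return \code{write_panel_tped}: the prefix, invisibly;
#'   \code{read_panel_tped}: a \code{genotype_panel}.
#' @export
write_panel_tped <- function(panel, prefix) {
  s <- panel$snps
  dos <- panel$dosage
  n <- nrow(dos)
  rows <- vapply(seq_len(nrow(s)), function(j) {
    d <- dos[, j]
    h1 <- ifelse(d >= 1, s$a1[j], s$a2[j])
    h2 <- ifelse(d == 2, s$a1[j], s$a2[j])
    paste(c(s$chrom[j], s$id[j], "0", s$pos[j], rbind(h1, h2)),
          collapse = "\t")
  }, character(1))
  writeLines(rows, paste0(prefix, ".tped"))
  writeLines(sprintf("FAM%04d %s 0 0 2 -9", seq_len(n), panel$ids),
             paste0(prefix, ".tfam"))
  invisible(prefix)
}

#' @rdname write_panel_tped
#' @export
read_panel_tped <- function(prefix) {
  tfam <- utils::read.table(paste0(prefix, ".tfam"), stringsAsFactors = FALSE)
  ids <- tfam[[2]]
  n <- length(ids)
  lines <- strsplit(readLines(paste0(prefix, ".tped")), "\t")
  m <- length(lines)
  dos <- matrix(0, n, m)
  snps <- data.frame(id = character(m), chrom = character(m), pos = integer(m),
                     a1 = character(m), a2 = character(m), maf = numeric(m),
                     stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- lines[[j]]
    al <- f[-(1:4)]
    tab <- sort(table(al))
    a1 <- names(tab)[1]
    a2 <- if (length(tab) > 1) names(tab)[2] else NA_character_
    cnt <- (al == a1) + 0
    dos[, j] <- cnt[seq(1, 2 * n, by = 2)] + cnt[seq(2, 2 * n, by = 2)]
    snps$id[j] <- f[2]; snps$chrom[j] <- f[1]; snps$pos[j] <- as.integer(f[4])
    snps$a1[j] <- a1; snps$a2[j] <- a2
  }
  freq <- colMeans(dos) / 2
  snps$maf <- pmin(freq, 1 - freq)
  dimnames(dos) <- list(ids, snps$id)
  structure(list(ids = ids, snps = snps, dosage = dos),
            class = "genotype_panel")
}

#' Write a genotype panel as VCF v4.2 text
#'
#' Hard genotype calls with A2 as REF and A1 (the dosage-counted allele) as
#' ALT, so the per-sample ALT allele count equals the stored dosage.
#'
#' @param panel A \code{genotype_panel}.
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  s <- panel$snps
  gt <- apply(panel$dosage, 2, function(d)
    c("0/0", "0/1", "1/1")[d + 1])      # individuals x SNPs
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(s)), function(j)
    paste(c(s$chrom[j], s$pos[j], s$id[j], s$a2[j], s$a1[j], ".", "PASS",
            ".", "GT", gt[, j]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize GWAS alleles against a reference panel
#'
#' Matches SNPs primarily by id (with a chrom/pos/allele-set fallback for ids
#' absent from the panel), drops SNPs not in the panel, flips the z-score
#' sign when effect/other alleles are swapped relative to the panel, resolves
#' strand flips by complementing when unambiguous, and (by default) drops
#' strand-ambiguous A/T and C/G SNPs. Irreconcilable allele pairs are
#' dropped, never silently kept.
#'
#' @param gwas A \code{gwas_summary}.
#' @param panel A \code{genotype_panel}.
#' @param drop_ambiguous Drop A/T and C/G SNPs (default TRUE).
#' @return Harmonized \code{gwas_summary} whose A1/A2 match the panel,
#'   restricted to panel SNPs, with a counts report in attribute
#'   \code{"harmonization"} (n_input, n_matched, n_flipped,
#'   n_strand_flipped, n_ambiguous_dropped, n_irreconcilable,
#'   n_missing_panel).
#' @export
harmonize_alleles <- function(gwas, panel, drop_ambiguous = TRUE) {
  stopifnot(inherits(gwas, "gwas_summary"), inherits(panel, "genotype_panel"))
  g <- as.data.frame(gwas)
  s <- panel$snps
  idx <- match(g$SNP, s$id)
  # positional fallback for ids the panel does not carry
  miss <- which(is.na(idx))
  if (length(miss)) {
    key_g <- paste(g$CHR[miss], g$BP[miss])
    key_s <- paste(s$chrom, s$pos)
    idx[miss] <- match(key_g, key_s)
  }
  rep <- c(n_input = nrow(g), n_matched = 0L, n_flipped = 0L,
           n_strand_flipped = 0L, n_ambiguous_dropped = 0L,
           n_irreconcilable = 0L, n_missing_panel = sum(is.na(idx)))
  keep <- logical(nrow(g))
  for (i in which(!is.na(idx))) {
    pa1 <- s$a1[idx[i]]; pa2 <- s$a2[idx[i]]
    ga1 <- g$A1[i]; ga2 <- g$A2[i]
    ambiguous <- DNA_COMPLEMENT[[ga1]] == ga2
    if (drop_ambiguous && ambiguous) {
      rep["n_ambiguous_dropped"] <- rep["n_ambiguous_dropped"] + 1L
      next
    }
    if (ga1 == pa1 && ga2 == pa2) {
      # identical labelling
    } else if (ga1 == pa2 && ga2 == pa1) {
      g$Z[i] <- -g$Z[i]
      rep["n_flipped"] <- rep["n_flipped"] + 1L
    } else if (!ambiguous && DNA_COMPLEMENT[[ga1]] == pa1 &&
               DNA_COMPLEMENT[[ga2]] == pa2) {
      rep["n_strand_flipped"] <- rep["n_strand_flipped"] + 1L
    } else if (!ambiguous && DNA_COMPLEMENT[[ga1]] == pa2 &&
               DNA_COMPLEMENT[[ga2]] == pa1) {
      g$Z[i] <- -g$Z[i]
      rep["n_strand_flipped"] <- rep["n_strand_flipped"] + 1L
      rep["n_flipped"] <- rep["n_flipped"] + 1L
    } else {
      rep["n_irreconcilable"] <- rep["n_irreconcilable"] + 1L
      next
    }
    g$A1[i] <- pa1; g$A2[i] <- pa2
    g$SNP[i] <- s$id[idx[i]]
    keep[i] <- TRUE
  }
  rep["n_matched"] <- sum(keep)
  out <- gwas_summary(g[keep, , drop = FALSE], scan_label(gwas))
  attr(out, "harmonization") <- rep
  out
}

#' Apply the summary-statistics input filters
#'
#' Retains only SNPs with minor allele frequency strictly above
#' \code{maf_min} and imputation quality strictly above \code{info_min};
#' SNPs without metadata are excluded and counted.
#'
#' @param gwas A \code{gwas_summary}.
#' @param maf_by_snp,info_by_snp Named numeric vectors keyed by SNP id.
#' @param maf_min,info_min Strict lower bounds (defaults 0.005 and 0.3, the
#'   conventional post-imputation GWAS filters).
#' @return Filtered \code{gwas_summary} with a report in attribute
#'   \code{"filter"} (n_input, n_retained, n_failed_maf, n_failed_info,
#'   n_missing_metadata).
#' @export
apply_input_filters <- function(gwas, maf_by_snp, maf_min = 0.005,
                                info_by_snp, info_min = 0.3) {
  stopifnot(inherits(gwas, "gwas_summary"))
  maf <- maf_by_snp[as.data.frame(gwas)$SNP]
  info <- info_by_snp[as.data.frame(gwas)$SNP]
  missing <- is.na(maf) | is.na(info)
  ok_maf <- !missing & maf > maf_min
  ok_info <- !missing & info > info_min
  keep <- ok_maf & ok_info
  out <- gwas_summary(as.data.frame(gwas)[keep, , drop = FALSE],
                      scan_label(gwas))
  attr(out, "filter") <- c(
    n_input = nrow(gwas), n_retained = sum(keep),
    n_failed_maf = sum(!missing & !ok_maf),
    n_failed_info = sum(!missing & !ok_info),
    n_missing_metadata = sum(missing))
  out
}

WEIGHT_FILE_HEADER <- "##twaskit-weights 1.0"
WEIGHT_FILE_COLS <- c("gene_id", "chrom", "gene_start", "gene_end",
                      "cis_start", "cis_end", "method", "cv_r2", "h2",
                      "h2_lrt_p", "snp_id", "a1", "a2", "weight")

#' Write and read per-gene expression weight files
#'
#' A portable tab-delimited dialect with a versioned header line: one row per
#' gene-SNP pair carrying the per-gene metadata (coordinates, cis window,
#' method, cross-validation r2, cis-h2 and its likelihood-ratio p) alongside
#' the SNP, its alleles and its weight on the standardized-dosage scale.
#'
#' @param weights data.frame in the layout above (as produced by
#'   \code{\link{weight_table}}).
#' @param path File path.
#' @return \code{write_weights}: the path invisibly; \code{read_weights}:
#'   the data.frame.
#' @export
write_weights <- function(weights, path) {
  stopifnot(all(WEIGHT_FILE_COLS %in% names(weights)))
  w <- weights[, WEIGHT_FILE_COLS]
  if (any(w$snp_id == "")) stop("empty snp id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(WEIGHT_FILE_HEADER, con)
  utils::write.table(w, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, WEIGHT_FILE_HEADER))
    stop("not a twaskit weight file (missing versioned header)")
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         chrom = "character",
                                         snp_id = "character",
                                         a1 = "character", a2 = "character"))
  for (g in split(df, df$gene_id)) {
    if (all(g$weight == 0))
      stop("gene ", g$gene_id[1], " has no nonzero weight")
  }
  df
}

#' Flatten fitted weight models into the weight-file table layout
#'
#' @param models List of \code{weight_model} objects (one per gene).
#' @param panel The training \code{genotype_panel} (supplies alleles).
#' @param genes data.frame with gene_id, chrom, start, end, cis_start,
#'   cis_end.
#' @return data.frame, one row per gene-SNP pair with nonzero weight.
#' @export
weight_table <- function(models, panel, genes) {
  rows <- lapply(models, function(mod) {
    nz <- which(mod$weights != 0)
    if (!length(nz)) return(NULL)
    gi <- genes[genes$gene_id == mod$gene_id, , drop = FALSE]
    idx <- match(names(mod$weights)[nz], panel$snps$id)
    data.frame(gene_id = mod$gene_id, chrom = gi$chrom,
               gene_start = gi$start, gene_end = gi$end,
               cis_start = gi$cis_start, cis_end = gi$cis_end,
               method = mod$method, cv_r2 = mod$cv_r2, h2 = mod$h2,
               h2_lrt_p = mod$h2_lrt_p,
               snp_id = panel$snps$id[idx], a1 = panel$snps$a1[idx],
               a2 = panel$snps$a2[idx], weight = unname(mod$weights[nz]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load the packaged transcriptions of the published result tables
#'
#' \code{table1_fixture}: per-gene association summary (cytoband, gene,
#' coordinates, SNP count, heritability, cross-validation r2, and the four
#' scan p-values). \code{table2_fixture}: per-gene conditional-analysis
#' summary (SNP counts and significance counts before/after conditioning,
#' index-SNP and minimum conditional p-values).
#'
#' @return data.frame.
#' @export
table1_fixture <- function() {
  utils::read.delim(system.file("extdata", "table1_fixture.tsv",
                                package = "twaskit"),
                    stringsAsFactors = FALSE)
}

#' @rdname table1_fixture
#' @export
table2_fixture <- function() {
  utils::read.delim(system.file("extdata", "table2_fixture.tsv",
                                package = "twaskit"),
                    stringsAsFactors = FALSE)
}
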