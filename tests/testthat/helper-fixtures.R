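# Builders and independent oracles shared across the suite.

# Hand-built genotype matrix: `geno` given subjects x variants.
make_gm <- function(geno, status, gq = NULL) {
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("S%03d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("V%03d", seq_len(ncol(geno)))
  if (!is.null(gq)) dimnames(gq) <- dimnames(geno)
  genotype_matrix(geno, status, gq)
}

# Variant table with sensible defaults, aligned to a genotype matrix.
make_variants <- function(gm, csqcat = "missense", polyphen = "unknown",
                          sift = "unknown", in_ref = FALSE, filter = "PASS",
                          genes = "GENEA", af_popa = NA_real_,
                          af_popb = NA_real_) {
  n <- ncol(gm$geno)
  rep_n <- function(x) rep_len(x, n)
  v <- data.frame(variant_id = colnames(gm$geno),
                  chrom = "1", pos = seq_len(n), ref = "A", alt = "C",
                  filter = rep_n(filter), csqcat = rep_n(csqcat),
                  polyphen = rep_n(polyphen), sift = rep_n(sift),
                  in_ref = rep_n(in_ref), af_popa = rep_n(af_popa),
                  af_popb = rep_n(af_popb), stringsAsFactors = FALSE)
  v$genes <- if (is.list(genes)) rep_len(genes, n) else
    as.list(rep_n(genes))
  v
}

# Naive triple-loop gene-score oracle (subject x gene x variant).
naive_gene_scores <- function(gm, variants, partition, genes) {
  sel <- switch(partition,
                all = rep(TRUE, nrow(variants)),
                singleton = variants$singleton,
                non_singleton = !variants$singleton)
  S <- matrix(0, nrow(gm$geno), length(genes),
              dimnames = list(rownames(gm$geno), genes))
  for (i in seq_len(nrow(gm$geno))) {
    for (j in seq_along(genes)) {
      for (v in which(sel)) {
        if (genes[j] %in% variants$genes[[v]]) {
          g <- gm$geno[i, variants$variant_id[v]]
          if (!is.na(g)) S[i, j] <- S[i, j] + variants$weight[v] * g
        }
      }
    }
  }
  S
}

# Permutation two-sided p for the pooled-t comparison of two score vectors.
# Exhaustive over all case-label choices when feasible, else Monte-Carlo.
perm_t_p <- function(case_scores, control_scores, max_exact = 20000,
                     n_mc = 20000) {
  x <- c(case_scores, control_scores)
  n1 <- length(case_scores)
  tstat <- function(idx) {
    a <- x[idx]; b <- x[-idx]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) return(0)
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  t_obs <- tstat(seq_len(n1))
  if (choose(length(x), n1) <= max_exact) {
    combs <- utils::combn(length(x), n1)
    ts <- apply(combs, 2, tstat)
  } else {
    ts <- replicate(n_mc, tstat(sample(length(x), n1)))
  }
  mean(abs(ts) >= abs(t_obs) - 1e-12)
}

# Variant table of a simulated cohort with the ground-truth singleton flag.
transform_truth_singletons <- function(co) {
  v <- co$variants
  v$singleton <- co$truth$is_singleton
  v
}

# Rank-based AUROC of a score against binary truth.
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Minimal VCF writer for hand-made records.
write_test_vcf <- function(path, samples, records,
                           format = "GT") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FILTER=<ID=q10,Description=\"low qual\">",
    "##INFO=<ID=CSQCAT,Number=1,Type=String,Description=\"csq\">",
    "##INFO=<ID=PPH,Number=1,Type=String,Description=\"pph\">",
    "##INFO=<ID=SIFTC,Number=1,Type=String,Description=\"sift\">",
    "##INFO=<ID=INREF,Number=1,Type=Integer,Description=\"inref\">",
    "##INFO=<ID=AF_POPA,Number=1,Type=Float,Description=\"afa\">",
    "##INFO=<ID=AF_POPB,Number=1,Type=Float,Description=\"afb\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

write_phenotypes <- function(path, samples, status) {
  writeLines(c("sample_id\tstatus", paste(samples, status, sep = "\t")),
             path)
  path
}

write_gene_map <- function(path, gene_id, chrom, start, end,
                           alias_group = "") {
  writeLines(c("gene_id\tchrom\tstart\tend\talias_group",
               paste(gene_id, chrom, start, end,
                     rep_len(alias_group, length(gene_id)), sep = "\t")),
             path)
  path
}
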