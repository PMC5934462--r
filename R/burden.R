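#' Per-subject gene-wise weighted burden scores
#'
#' For each subject and gene, the score is the sum over the gene's analysed
#' variants in the chosen partition of (functional weight x allele count);
#' missing genotypes contribute 0. A gene with no variants in the partition
#' yields all-zero scores. Scores under partition `all` equal the singleton
#' plus non-singleton scores elementwise.
#'
#' @param gm A [genotype_matrix()].
#' @param variants Variant table carrying columns `weight` (from
#'   [weight_variants()]), `singleton` (from [classify_singletons()]) and
#'   the `genes` list-column.
#' @param partition One of `"all"`, `"singleton"`, `"non_singleton"`.
#' @param genes Gene universe defining the columns; defaults to all genes
#'   appearing in `variants$genes`, sorted.
#' @return Numeric matrix subjects x genes with attribute `partition`.
#' @export
gene_scores <- function(gm, variants,
                        partition = c("all", "singleton", "non_singleton"),
                        genes = NULL) {
  partition <- match.arg(partition)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(c("weight", "singleton") %in% names(variants)))
    stop("gene_scores: variants need 'weight' and 'singleton' columns ",
         "(run weight_variants() and classify_singletons() first)",
         call. = FALSE)
  if (is.null(genes))
    genes <- sort(unique(unlist(variants$genes)))
  sel <- switch(partition,
                all = rep(TRUE, nrow(variants)),
                singleton = variants$singleton,
                non_singleton = !variants$singleton)
  v <- variants[sel, , drop = FALSE]
  S <- matrix(0, nrow(gm$geno), length(genes),
              dimnames = list(rownames(gm$geno), genes))
  if (nrow(v) && length(genes)) {
    vi <- rep(seq_len(nrow(v)), lengths(v$genes))
    gi <- match(unlist(v$genes), genes)
    keep <- !is.na(gi)
    if (any(keep)) {
      M <- Matrix::sparseMatrix(i = vi[keep], j = gi[keep],
                                x = v$weight[vi[keep]],
                                dims = c(nrow(v), length(genes)))
      g <- gm$geno[, v$variant_id, drop = FALSE]
      g[is.na(g)] <- 0L
      S <- as.matrix(g %*% M)
      dimnames(S) <- list(rownames(gm$geno), genes)
    }
  }
  attr(S, "partition") <- partition
  S
}

#' Signed log-p (SLP) test for one score vector pair
#'
#' Compares per-subject scores between cases and controls with a two-sample
#' t test (pooled variance by default, Welch optionally) and reports the
#' signed log10 p: `SLP = sign * log10(1/p)` with positive sign iff the case
#' mean exceeds the control mean. An SLP of 3 therefore indicates an excess
#' among cases with two-tailed p < 1e-3. When both groups are constant and
#' equal, p = 1 and SLP = 0. p values are floored at the smallest positive
#' representable double before taking logs.
#'
#' @param case_scores,control_scores Numeric score vectors (>= 2 subjects
#'   each; smaller groups yield an untestable result with `SLP = NA`).
#' @param var_equal Pooled-variance t test when `TRUE` (default), Welch
#'   otherwise.
#' @return A one-row data frame of class `slp_result`: `n_case`,
#'   `n_control`, `mean_case`, `mean_control`, `t`, `p`, `slp`,
#'   `degenerate`, `untestable`.
#' @export
slp_test <- function(case_scores, control_scores, var_equal = TRUE) {
  out <- slp_from_groups(matrix(case_scores, ncol = 1),
                         matrix(control_scores, ncol = 1),
                         var_equal = var_equal)
  out$unit <- NULL
  class(out) <- c("slp_result", "data.frame")
  out
}

## Vectorised SLP machinery over the columns of case/control score matrices.
slp_from_groups <- function(Sc, Sk, var_equal = TRUE) {
  n1 <- nrow(Sc); n0 <- nrow(Sk)
  unit <- colnames(Sc)
  if (is.null(unit)) unit <- rep(NA_character_, ncol(Sc))
  m1 <- colMeans(Sc); m0 <- colMeans(Sk)
  if (n1 < 2 || n0 < 2) {
    return(data.frame(unit = unit, n_case = n1, n_control = n0,
                      mean_case = m1, mean_control = m0, t = NA_real_,
                      p = NA_real_, slp = NA_real_, degenerate = FALSE,
                      untestable = TRUE, row.names = NULL))
  }
  v1 <- (colSums(Sc^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(Sk^2) - n0 * m0^2) / (n0 - 1)
  v1 <- pmax(v1, 0); v0 <- pmax(v0, 0)
  if (var_equal) {
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  diff <- m1 - m0
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  degenerate <- se == 0 & diff == 0
  ## two-sided p on the log scale for precision in the extreme tail
  logp <- log(2) + stats::pt(-abs(tstat), df, log.p = TRUE)
  logp[degenerate] <- 0
  slp_mag <- pmin(-logp / log(10), -log10(.Machine$double.xmin))
  sgn <- sign(diff)
  slp <- sgn * slp_mag
  slp[degenerate] <- 0
  p <- pmax(exp(logp), .Machine$double.xmin)
  p[degenerate] <- 1
  data.frame(unit = unit, n_case = n1, n_control = n0,
             mean_case = m1, mean_control = m0, t = tstat, p = p, slp = slp,
             degenerate = degenerate, untestable = FALSE, row.names = NULL)
}

## Shared pipeline front end: mask genotypes, filter sites, apply the MAF
## ceiling, classify singletons, attach weights. Returns the analysed
## variant table.
prepare_variants <- function(cohort, weights, qc) {
  gm <- mask_low_quality_genotypes(cohort$geno, qc)
  fs <- filter_sites(gm, cohort$variants, qc)
  kept <- apply_maf_ceiling(gm, fs$kept, qc)
  kept$singleton <- classify_singletons(gm, kept)
  kept$weight <- weight_variants(kept, weights)
  list(gm = gm, variants = kept, qc_report = fs$report)
}

#' Gene-wise weighted burden analysis
#'
#' Runs the full pipeline on a cohort -- genotype-quality masking, site
#' filters, MAF ceiling, singleton classification, weighting -- then
#' computes per-subject gene scores and the SLP test per gene for each
#' requested variant partition. Genes with all-zero scores in both groups
#' are reported with SLP 0 and flagged degenerate rather than dropped, so
#' the gene universe (and any Bonferroni denominator) stays stable.
#'
#' @param cohort A [burden_cohort()].
#' @param weights A [weight_table()].
#' @param qc A [qc_config()].
#' @param partitions Character subset of
#'   `c("singleton", "non_singleton", "all")`.
#' @param var_equal Pooled-variance t test when `TRUE` (default).
#' @param genes Optional gene universe; defaults to the gene map's genes
#'   when available, else all assigned genes.
#' @return Data frame with one row per (gene, partition): `unit`,
#'   `partition`, `n_case`, `n_control`, `mean_case`, `mean_control`, `t`,
#'   `p`, `slp`, `degenerate`, `untestable`.
#' @export
gene_wise_analysis <- function(cohort,
                               weights = default_weight_table(),
                               qc = qc_config(),
                               partitions = c("singleton", "non_singleton",
                                              "all"),
                               var_equal = TRUE,
                               genes = NULL) {
  partitions <- match.arg(partitions, several.ok = TRUE)
  prep <- prepare_variants(cohort, weights, qc)
  if (is.null(genes)) {
    genes <- if (!is.null(cohort$gene_map)) {
      grp <- cohort$gene_map$alias_group
      if (is.null(grp)) grp <- rep("", nrow(cohort$gene_map))
      sort(unique(ifelse(is.na(grp) | grp == "",
                         cohort$gene_map$gene_id, grp)))
    } else sort(unique(unlist(prep$variants$genes)))
  }
  is_case <- prep$gm$status == "case"
  out <- lapply(partitions, function(part) {
    S <- gene_scores(prep$gm, prep$variants, partition = part, genes = genes)
    res <- slp_from_groups(S[is_case, , drop = FALSE],
                           S[!is_case, , drop = FALSE],
                           var_equal = var_equal)
    res$partition <- part
    res
  })
  out <- do.call(rbind, out)
  out[, c("unit", "partition", "n_case", "n_control", "mean_case",
          "mean_control", "t", "p", "slp", "degenerate", "untestable")]
}

#' Per-subject gene-set scores
#'
#' For each subject, the set score is the sum of that subject's gene-wise
#' scores over the set's member genes present in the score matrix; missing
#' members contribute 0. Sets with no matched genes are flagged and
#' excluded.
#'
#' @param score_matrix Subjects x genes matrix from [gene_scores()].
#' @param sets A `gene_set_collection` from [load_gene_sets()], or a named
#'   list of gene-id vectors.
#' @return Subjects x sets matrix with attributes `matched` (matched gene
#'   count per retained set) and `empty_sets` (names of excluded sets).
#' @export
set_scores <- function(score_matrix, sets) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  genes <- colnames(score_matrix)
  matched <- vapply(sets, function(g) sum(g %in% genes), integer(1))
  empty <- names(sets)[matched == 0]
  keep <- names(sets)[matched > 0]
  sets <- sets[keep]
  if (!length(sets))
    stop("set_scores: no set has any gene in the score matrix",
         call. = FALSE)
  si <- rep(seq_along(sets), lengths(sets))
  gi <- match(unlist(sets), genes)
  ok <- !is.na(gi)
  B <- Matrix::sparseMatrix(i = gi[ok], j = si[ok], x = 1,
                            dims = c(length(genes), length(sets)))
  out <- as.matrix(score_matrix %*% B)
  dimnames(out) <- list(rownames(score_matrix), names(sets))
  attr(out, "matched") <- matched[keep]
  attr(out, "empty_sets") <- empty
  attr(out, "partition") <- attr(score_matrix, "partition")
  out
}

#' Set-wise weighted burden analysis
#'
#' As [gene_wise_analysis()], but per-subject gene scores are summed over
#' each gene set before the SLP test, for each requested variant partition.
#'
#' @inheritParams gene_wise_analysis
#' @param sets A `gene_set_collection` or named list of gene-id vectors.
#' @return Data frame with one row per (set, partition), same columns as
#'   [gene_wise_analysis()], plus `n_genes_matched`.
#' @export
set_wise_analysis <- function(cohort, sets,
                              weights = default_weight_table(),
                              qc = qc_config(),
                              partitions = c("singleton", "non_singleton",
                                             "all"),
                              var_equal = TRUE,
                              genes = NULL) {
  partitions <- match.arg(partitions, several.ok = TRUE)
  prep <- prepare_variants(cohort, weights, qc)
  if (is.null(genes))
    genes <- sort(unique(unlist(prep$variants$genes)))
  is_case <- prep$gm$status == "case"
  out <- lapply(partitions, function(part) {
    S <- gene_scores(prep$gm, prep$variants, partition = part, genes = genes)
    SS <- set_scores(S, sets)
    res <- slp_from_groups(SS[is_case, , drop = FALSE],
                           SS[!is_case, , drop = FALSE],
                           var_equal = var_equal)
    res$partition <- part
    res$n_genes_matched <- as.integer(attr(SS, "matched")[res$unit])
    res
  })
  out <- do.call(rbind, out)
  out[, c("unit", "partition", "n_genes_matched", "n_case", "n_control",
          "mean_case", "mean_control", "t", "p", "slp", "degenerate",
          "untestable")]
}
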