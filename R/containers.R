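#' Subjects-by-variants genotype matrix
#'
#' Container for the allele-count matrix the burden analysis operates on.
#' Rows are subjects, columns are (split, biallelic) variants; entries are
#' alternate-allele dosages 0/1/2 with `NA` for missing genotypes. Genotype
#' qualities, when available, are carried in a parallel matrix.
#'
#' @param geno Integer matrix of dosages (subjects x variants); `NA` =
#'   missing. Must have row and column names.
#' @param status Character or factor of per-subject labels, values in
#'   `{"case", "control"}`, aligned with `rownames(geno)`.
#' @param gq Optional numeric matrix of genotype qualities, same shape as
#'   `geno`; `NULL` when the input carries no GQ field.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, status, gq = NULL) {
  if (!is.matrix(geno)) stop("geno must be a matrix", call. = FALSE)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("geno must carry sample (row) and variant (column) names",
         call. = FALSE)
  status <- as.character(status)
  if (length(status) != nrow(geno))
    stop("status length must equal the number of subjects", call. = FALSE)
  bad <- setdiff(unique(status), c("case", "control"))
  if (length(bad))
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(c("case", "control") %in% status))
    stop("both cases and controls are required", call. = FALSE)
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype entries must be 0, 1, 2 or NA", call. = FALSE)
  if (!is.null(gq) && !identical(dim(gq), dim(geno)))
    stop("gq must have the same dimensions as geno", call. = FALSE)
  structure(list(geno = geno,
                 status = factor(status, levels = c("case", "control")),
                 gq = gq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n <- table(x$status)
  cat("genotype_matrix:", nrow(x$geno), "subjects (", n[["case"]], "cases /",
      n[["control"]], "controls ) x", ncol(x$geno), "variants\n")
  cat("  missing genotypes:",
      sprintf("%.2f%%", 100 * mean(is.na(x$geno))),
      if (is.null(x$gq)) " (no GQ)" else " (GQ present)", "\n")
  invisible(x)
}

#' Number of subjects per cohort
#' @param gm A [genotype_matrix()].
#' @return Named integer vector with elements `case` and `control`.
#' @export
cohort_sizes <- function(gm) {
  tab <- table(gm$status)
  c(case = as.integer(tab[["case"]]), control = as.integer(tab[["control"]]))
}

#' Per-variant genotype counts split by cohort
#'
#' Counts hom-ref, het, hom-alt and missing genotypes for cases and controls
#' at every variant column. These are the inputs of the site-level QC rules.
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame with one row per variant and columns
#'   `case_homref, case_het, case_homalt, case_miss, ctrl_homref, ctrl_het,
#'   ctrl_homalt, ctrl_miss`.
#' @export
variant_cohort_counts <- function(gm) {
  count_group <- function(rows) {
    g <- gm$geno[rows, , drop = FALSE]
    miss <- is.na(g)
    cbind(homref = colSums(g == 0L, na.rm = TRUE),
          het    = colSums(g == 1L, na.rm = TRUE),
          homalt = colSums(g == 2L, na.rm = TRUE),
          miss   = colSums(miss))
  }
  ca <- count_group(gm$status == "case")
  co <- count_group(gm$status == "control")
  out <- data.frame(variant_id = colnames(gm$geno),
                    case_homref = ca[, "homref"], case_het = ca[, "het"],
                    case_homalt = ca[, "homalt"], case_miss = ca[, "miss"],
                    ctrl_homref = co[, "homref"], ctrl_het = co[, "het"],
                    ctrl_homalt = co[, "homalt"], ctrl_miss = co[, "miss"],
                    row.names = NULL)
  out
}

#' Assemble a cohort object
#'
#' A `burden_cohort` bundles the genotype matrix with its annotated variant
#' table; all pipeline stages ([gene_wise_analysis()], [subject_covariates()],
#' ...) consume this object.
#'
#' @param geno A [genotype_matrix()].
#' @param variants Data frame of annotated variants, one row per (site,
#'   alternate allele), with at least columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `filter`, `csqcat`, `polyphen`, `sift`, `in_ref`,
#'   `af_popa`, `af_popb` and a list-column `genes`.
#' @param gene_map Optional gene interval table (gene_id, chrom, start, end).
#' @return An object of class `burden_cohort`.
#' @export
burden_cohort <- function(geno, variants, gene_map = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), is.data.frame(variants))
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "filter", "csqcat",
            "polyphen", "sift", "in_ref", "genes")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!identical(colnames(geno$geno), variants$variant_id))
    stop("genotype columns and variant table must align", call. = FALSE)
  if (any(variants$pos < 1))
    stop("variant positions must be >= 1", call. = FALSE)
  structure(list(geno = geno, variants = variants, gene_map = gene_map),
            class = "burden_cohort")
}

#' @export
print.burden_cohort <- function(x, ...) {
  print(x$geno)
  cat("  annotated variants:", nrow(x$variants), "\n")
  invisible(x)
}
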