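#' Quality-control configuration
#'
#' Thresholds for the genotype- and site-level QC filters: genotype calls
#' below the quality threshold are masked as missing; sites are removed when
#' not PASS in the VCF FILTER field, when more than the allowed fraction of
#' genotypes is missing or of low quality in either cohort, or when the
#' heterozygote count is smaller than both homozygote counts in both
#' cohorts; finally variants with per-cohort MAF above the ceiling in both
#' cohorts are excluded from the burden analysis.
#'
#' @param gq_threshold Minimum genotype quality; calls with `GQ <
#'   gq_threshold` are masked (default 30).
#' @param max_missing_fraction Maximum tolerated missing/low-quality
#'   fraction per cohort (default 0.10; strictly-greater removal).
#' @param maf_ceiling Per-cohort minor-allele-frequency ceiling (default
#'   0.01; removal only when exceeded in both cohorts).
#' @param het_hom_rule Enable the heterozygote-deficit rule (default TRUE).
#' @param absent_gq_passes How to treat genotypes without a GQ value:
#'   `TRUE` (default) keeps them, as for array-style inputs lacking GQ.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(gq_threshold = 30,
                      max_missing_fraction = 0.10,
                      maf_ceiling = 0.01,
                      het_hom_rule = TRUE,
                      absent_gq_passes = TRUE) {
  if (gq_threshold < 0) stop("gq_threshold must be >= 0", call. = FALSE)
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must lie in [0, 1]", call. = FALSE)
  if (maf_ceiling < 0 || maf_ceiling > 0.5)
    stop("maf_ceiling must lie in [0, 0.5]", call. = FALSE)
  structure(list(gq_threshold = gq_threshold,
                 max_missing_fraction = max_missing_fraction,
                 maf_ceiling = maf_ceiling,
                 het_hom_rule = isTRUE(het_hom_rule),
                 absent_gq_passes = isTRUE(absent_gq_passes)),
            class = "qc_config")
}

#' Mask low-quality genotype calls
#'
#' Sets genotype entries with quality below the threshold to missing;
#' nothing else changes. Genotypes without a quality value are treated as
#' passing by default (configurable via `absent_gq_passes`); a matrix with
#' no GQ layer is returned unchanged.
#'
#' @param gm A [genotype_matrix()].
#' @param config A [qc_config()].
#' @return The masked [genotype_matrix()].
#' @export
mask_low_quality_genotypes <- function(gm, config = qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$gq) || config$gq_threshold == 0) return(gm)
  low <- !is.na(gm$gq) & gm$gq < config$gq_threshold
  if (!config$absent_gq_passes)
    low <- low | (is.na(gm$gq) & !is.na(gm$geno))
  gm$geno[low] <- NA_integer_
  gm
}

#' Site-level QC filters
#'
#' Removes a site iff (a) its FILTER value is not `PASS`, or (b) its
#' missing-genotype fraction exceeds the threshold in cases or in controls,
#' or (c) its heterozygote count is smaller than its hom-ref count AND its
#' hom-alt count, in cases AND in controls. Rules are evaluated in the order
#' a, b, c, and the first failing rule is recorded per variant. Genotype
#' masking ([mask_low_quality_genotypes()]) must already have been applied
#' so that "missing" covers low-quality calls.
#'
#' @param gm A [genotype_matrix()] (post-masking).
#' @param variants Annotated variant table aligned with `gm`.
#' @param config A [qc_config()].
#' @return List with `kept` (the surviving variant rows), `report` (one row
#'   per input variant: `variant_id`, `pass`, `rule` in
#'   `not_pass_filter` / `missingness_cases` / `missingness_controls` /
#'   `het_lt_homs` / `NA`) and `counts` (removals per rule).
#' @export
filter_sites <- function(gm, variants, config = qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sizes <- cohort_sizes(gm)
  if (any(sizes == 0)) stop("filter_sites: empty cohort", call. = FALSE)
  cc <- variant_cohort_counts(gm)
  cc <- cc[match(variants$variant_id, cc$variant_id), , drop = FALSE]

  not_pass <- variants$filter != "PASS"
  miss_ca <- cc$case_miss / sizes[["case"]] > config$max_missing_fraction
  miss_co <- cc$ctrl_miss / sizes[["control"]] > config$max_missing_fraction
  het_rule <- if (config$het_hom_rule) {
    (cc$case_het < cc$case_homref & cc$case_het < cc$case_homalt) &
      (cc$ctrl_het < cc$ctrl_homref & cc$ctrl_het < cc$ctrl_homalt)
  } else rep(FALSE, nrow(variants))

  rule <- rep(NA_character_, nrow(variants))
  rule[het_rule] <- "het_lt_homs"
  rule[miss_co] <- "missingness_controls"
  rule[miss_ca] <- "missingness_cases"
  rule[not_pass] <- "not_pass_filter"
  pass <- is.na(rule)
  report <- data.frame(variant_id = variants$variant_id, pass = pass,
                       rule = rule, stringsAsFactors = FALSE)
  counts <- table(factor(rule, levels = c("not_pass_filter",
                                          "missingness_cases",
                                          "missingness_controls",
                                          "het_lt_homs")))
  list(kept = variants[pass, , drop = FALSE], report = report,
       counts = counts)
}

#' Per-cohort minor allele frequencies
#'
#' MAF per cohort computed from non-missing alleles:
#' `min(alt frequency, 1 - alt frequency)`. Monomorphic sites get MAF 0;
#' cohorts with no called genotypes at a site get `NaN`.
#'
#' @param gm A [genotype_matrix()].
#' @param variants Variant table aligned with `gm` (any subset).
#' @return Data frame with columns `variant_id`, `maf_case`, `maf_control`.
#' @export
cohort_mafs <- function(gm, variants) {
  cc <- variant_cohort_counts(gm)
  cc <- cc[match(variants$variant_id, cc$variant_id), , drop = FALSE]
  f_case <- (cc$case_het + 2 * cc$case_homalt) /
    (2 * (cc$case_homref + cc$case_het + cc$case_homalt))
  f_ctrl <- (cc$ctrl_het + 2 * cc$ctrl_homalt) /
    (2 * (cc$ctrl_homref + cc$ctrl_het + cc$ctrl_homalt))
  data.frame(variant_id = variants$variant_id,
             maf_case = pmin(f_case, 1 - f_case),
             maf_control = pmin(f_ctrl, 1 - f_ctrl))
}

#' Apply the MAF ceiling
#'
#' A variant is removed iff its MAF exceeds the ceiling in cases AND in
#' controls; a variant rare in either cohort is kept. (Retained variants
#' therefore have MAF below the ceiling in cases and/or controls.)
#'
#' @param gm A [genotype_matrix()].
#' @param variants Variant table (typically the QC survivors).
#' @param config A [qc_config()].
#' @return The surviving variant rows.
#' @export
apply_maf_ceiling <- function(gm, variants, config = qc_config()) {
  maf <- cohort_mafs(gm, variants)
  drop <- !is.na(maf$maf_case) & !is.na(maf$maf_control) &
    maf$maf_case > config$maf_ceiling & maf$maf_control > config$maf_ceiling
  variants[!drop, , drop = FALSE]
}

#' Classify singleton (ultra-rare) variants
#'
#' A variant is a singleton iff exactly one subject in the combined cohort
#' carries at least one alternate allele AND the variant is flagged absent
#' from the external reference panel. A single homozygous-alt carrier
#' counts: the definition is per subject, not per allele. All other
#' analysed variants are non-singleton, so the two classes partition the
#' analysed set.
#'
#' @param gm A [genotype_matrix()] (post-masking, post-exclusion if
#'   exclusion is applied first).
#' @param variants Variant table with column `in_ref`.
#' @return Logical vector, one flag per row of `variants`.
#' @export
classify_singletons <- function(gm, variants) {
  g <- gm$geno[, variants$variant_id, drop = FALSE]
  carriers <- colSums(g >= 1L, na.rm = TRUE)
  unname(carriers == 1L & !variants$in_ref)
}

#' Write a QC audit table
#'
#' @param report The `report` element of [filter_sites()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
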