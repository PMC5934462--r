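#' Ancestry allele-score configuration
#'
#' Parameters of the log-frequency-ratio allele score used to spot subjects
#' from a confounding subpopulation (e.g. a Finnish ancestry component in a
#' Swedish cohort). A variant is "discriminating" when its reference
#' frequency in population B is at least `min_ratio` times its frequency in
#' population A and the population-A frequency does not exceed
#' `max_base_freq`; rs6267 (MAF 0.002 in non-Finnish Europeans, 0.05 in
#' Finns) is the motivating example of such a variant.
#'
#' @param min_ratio Minimum `AF_POPB / AF_POPA` ratio (> 1) for a variant to
#'   discriminate.
#' @param max_base_freq Maximum population-A frequency of a discriminating
#'   variant.
#' @param sd_cutoff Subjects scoring more than `sd_cutoff` standard
#'   deviations above the mean are flagged for exclusion.
#' @param iterate Recompute mean/SD after each exclusion round until stable.
#' @param max_rounds Maximum exclusion rounds when iterating.
#' @return An object of class `ancestry_config`.
#' @export
ancestry_config <- function(min_ratio = 5,
                            max_base_freq = 0.01,
                            sd_cutoff = 3,
                            iterate = TRUE,
                            max_rounds = 10L) {
  if (min_ratio <= 1) stop("min_ratio must exceed 1", call. = FALSE)
  if (sd_cutoff <= 0 || max_rounds < 1)
    stop("cutoff parameters must be positive", call. = FALSE)
  structure(list(min_ratio = min_ratio, max_base_freq = max_base_freq,
                 sd_cutoff = sd_cutoff, iterate = isTRUE(iterate),
                 max_rounds = as.integer(max_rounds)),
            class = "ancestry_config")
}

#' Per-subject ancestry allele scores
#'
#' `score(subject) = sum over discriminating variants of allele count x
#' log10(AF_POPB / AF_POPA)`. Variants lacking either reference frequency
#' are skipped; missing genotypes contribute 0. The score is linear in
#' allele counts. Subjects with an excess of alleles that are much more
#' frequent in population B score high.
#'
#' @param gm A [genotype_matrix()].
#' @param variants Variant table with columns `af_popa`, `af_popb`.
#' @param config An [ancestry_config()].
#' @return Named numeric vector of scores, one per subject.
#' @export
ancestry_scores <- function(gm, variants, config = ancestry_config()) {
  ok <- !is.na(variants$af_popa) & !is.na(variants$af_popb) &
    variants$af_popa > 0
  disc <- ok & variants$af_popb / variants$af_popa >= config$min_ratio &
    variants$af_popa <= config$max_base_freq
  if (!any(disc))
    stop("ancestry_scores: no discriminating variants at ratio >= ",
         config$min_ratio, "; lower min_ratio or raise max_base_freq",
         call. = FALSE)
  w <- log10(variants$af_popb[disc] / variants$af_popa[disc])
  g <- gm$geno[, variants$variant_id[disc], drop = FALSE]
  g[is.na(g)] <- 0L
  stats::setNames(as.vector(g %*% w), rownames(gm$geno))
}

#' Flag ancestry-score outliers for exclusion
#'
#' Flags subjects whose score exceeds `mean + sd_cutoff * SD`, computed over
#' all (remaining) subjects. With `iterate = TRUE` the mean and SD are
#' recomputed after each exclusion round until no new subject is flagged or
#' `max_rounds` is reached, which sharpens the threshold when the outlying
#' subpopulation inflates the overall SD.
#'
#' @param scores Numeric scores from [ancestry_scores()].
#' @param config An [ancestry_config()].
#' @return Logical exclusion flags aligned with `scores`.
#' @export
exclude_outliers <- function(scores, config = ancestry_config()) {
  excl <- rep(FALSE, length(scores))
  for (round in seq_len(if (config$iterate) config$max_rounds else 1L)) {
    s <- scores[!excl]
    if (length(s) < 2) break
    cut <- mean(s) + config$sd_cutoff * stats::sd(s)
    if (is.na(cut)) break
    new <- !excl & scores > cut
    if (!any(new)) break
    excl <- excl | new
  }
  names(excl) <- names(scores)
  excl
}

#' Damaging / disruptive category configuration for dURV counting
#'
#' Loss-of-function categories count unconditionally; missense counts only
#' with a damaging PolyPhen class or a deleterious SIFT class. By default
#' the LOF list is every category whose base weight reaches the missense
#' base weight, excluding missense itself.
#'
#' @param weights A [weight_table()] from which the default LOF list is
#'   derived.
#' @param lof_categories Character vector overriding the LOF list.
#' @param missense_requires_annotation Require a damaging annotation for
#'   missense (default TRUE).
#' @return An object of class `damaging_config`.
#' @export
damaging_config <- function(weights = default_weight_table(),
                            lof_categories = NULL,
                            missense_requires_annotation = TRUE) {
  if (is.null(lof_categories)) {
    thr <- weights$base[["missense"]]
    lof_categories <- setdiff(names(weights$base)[weights$base >= thr],
                              "missense")
  }
  structure(list(lof_categories = lof_categories,
                 missense_requires_annotation =
                   isTRUE(missense_requires_annotation)),
            class = "damaging_config")
}

#' Classify variants as damaging/disruptive
#'
#' @param variants Variant table with `csqcat`, `polyphen`, `sift`.
#' @param config A [damaging_config()].
#' @return Logical vector, one flag per variant.
#' @export
is_damaging <- function(variants, config = damaging_config()) {
  lof <- variants$csqcat %in% config$lof_categories
  mis <- variants$csqcat == "missense"
  if (config$missense_requires_annotation) {
    mis <- mis & (variants$polyphen %in% POLYPHEN_DAMAGING |
                    variants$sift == "deleterious")
  }
  lof | mis
}

#' Per-subject URV and dURV counts
#'
#' `URV(subject)` is the number of singleton variants whose single carrier
#' is that subject; `dURV` is the subset whose consequence class is damaging
#' or disruptive per [is_damaging()]. Summed over subjects, URV equals the
#' number of singleton variants, and dURV <= URV per subject.
#'
#' @param gm A [genotype_matrix()].
#' @param variants Variant table with a `singleton` column (from
#'   [classify_singletons()]).
#' @param damaging A [damaging_config()].
#' @return Data frame `sample_id`, `urv`, `durv`.
#' @export
urv_counts <- function(gm, variants, damaging = damaging_config()) {
  if (!"singleton" %in% names(variants))
    stop("urv_counts: variants need a 'singleton' column", call. = FALSE)
  sng <- variants[variants$singleton, , drop = FALSE]
  urv <- durv <- stats::setNames(integer(nrow(gm$geno)), rownames(gm$geno))
  if (nrow(sng)) {
    g <- gm$geno[, sng$variant_id, drop = FALSE]
    idx <- which(g >= 1L, arr.ind = TRUE)
    carrier <- rep(NA_integer_, ncol(g))
    ## keep the first (lowest-index) carrier per column
    o <- order(idx[, 2], -idx[, 1])
    carrier[idx[o, 2]] <- idx[o, 1]
    dmg <- is_damaging(sng, damaging)
    has <- !is.na(carrier)
    urv[] <- tabulate(carrier[has], nbins = nrow(gm$geno))
    durv[] <- tabulate(carrier[has & dmg], nbins = nrow(gm$geno))
  }
  data.frame(sample_id = rownames(gm$geno), urv = as.integer(urv),
             durv = as.integer(durv), row.names = NULL)
}

#' Genotype principal components
#'
#' PCs of the centred, unit-variance-scaled allele-count matrix over
#' variants with minor allele frequency at least `maf_floor` (avoiding
#' singleton-dominated components) and non-zero variance. Missing entries
#' are mean-imputed per variant. Deterministic up to sign; the sign of each
#' component is fixed by making its largest-magnitude variant loading
#' positive.
#'
#' @param gm A [genotype_matrix()].
#' @param k Number of components (default 20; reduced with a warning when
#'   it exceeds the matrix rank).
#' @param maf_floor Minimum MAF of variants entering the PCA.
#' @return Subjects x k matrix of component scores (columns `PC1`, ...);
#'   a zero-column matrix when `k = 0`.
#' @export
genotype_pcs <- function(gm, k = 20L, maf_floor = 0.001) {
  n <- nrow(gm$geno)
  if (k == 0)
    return(matrix(numeric(0), n, 0, dimnames = list(rownames(gm$geno), NULL)))
  g <- gm$geno
  f <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= maf_floor
  g <- g[, keep, drop = FALSE]
  if (ncol(g) == 0)
    stop("genotype_pcs: no variants above the MAF floor", call. = FALSE)
  X <- apply(g, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  sds <- apply(X, 2, stats::sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  r <- min(n - 1L, ncol(X))
  if (k > r) {
    warning("genotype_pcs: k reduced to rank ", r)
    k <- r
  }
  ## n << p layout: eigen-decompose the subject-by-subject cross-product
  G <- tcrossprod(X) / (ncol(X) - 1)
  eig <- eigen(G, symmetric = TRUE)
  lam <- pmax(eig$values[seq_len(k)], 0)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  pcs <- U * rep(sqrt(lam * n), each = n)
  ## fix signs via the largest-magnitude variant loading
  for (j in seq_len(k)) {
    if (lam[j] <= 0) next
    load_j <- as.vector(crossprod(X, U[, j]))
    if (load_j[which.max(abs(load_j))] < 0) pcs[, j] <- -pcs[, j]
  }
  dimnames(pcs) <- list(rownames(gm$geno), paste0("PC", seq_len(k)))
  pcs
}

#' Covariate-adjusted dURV enrichment regression
#'
#' Logistic regression of case status on the per-subject dURV count, with a
#' configurable covariate set: none, the total URV count, the genotype
#' principal components, or both. Reports the dURV coefficient, its
#' standard error, z and two-sided p. Under population stratification the
#' unadjusted test is attenuated (or masked) relative to the adjusted one.
#'
#' @param covariates Data frame with columns `durv`, `urv` and optional
#'   `PC*` columns, e.g. from [subject_covariates()].
#' @param status Factor/character of `case` / `control` labels, aligned
#'   with `covariates` rows.
#' @param adjust One of `"both"`, `"none"`, `"urv"`, `"pcs"`.
#' @return List of class `durv_enrichment`: `estimate`, `se`, `z`, `p`,
#'   `adjust`, `separation` (TRUE when the fit is degenerate, in which case
#'   the estimate is NA).
#' @export
durv_enrichment <- function(covariates, status,
                            adjust = c("both", "none", "urv", "pcs")) {
  adjust <- match.arg(adjust)
  y <- as.integer(as.character(status) == "case")
  pc_cols <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
  terms <- switch(adjust,
                  none = "durv",
                  urv = c("durv", "urv"),
                  pcs = c("durv", pc_cols),
                  both = c("durv", "urv", pc_cols))
  dat <- cbind(y = y, covariates[, intersect(terms, names(covariates)),
                                 drop = FALSE])
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  sep <- !fit$converged || !"durv" %in% rownames(co) ||
    co["durv", "Std. Error"] > 1e3
  if (sep) {
    out <- list(estimate = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_, adjust = adjust, separation = TRUE)
  } else {
    out <- list(estimate = unname(co["durv", "Estimate"]),
                se = unname(co["durv", "Std. Error"]),
                z = unname(co["durv", "z value"]),
                p = unname(co["durv", "Pr(>|z|)"]),
                adjust = adjust, separation = FALSE)
  }
  class(out) <- "durv_enrichment"
  out
}

#' @export
print.durv_enrichment <- function(x, ...) {
  cat("dURV enrichment (adjust =", x$adjust, "):\n")
  if (x$separation) cat("  degenerate fit (separation); no estimate\n")
  else cat(sprintf("  beta = %.4f (se %.4f), z = %.2f, p = %.3g\n",
                   x$estimate, x$se, x$z, x$p))
  invisible(x)
}

#' Assemble per-subject covariates for the stratification analyses
#'
#' Runs the QC front end, classifies singletons, counts URVs/dURVs,
#' computes ancestry scores and exclusion flags, and attaches the first
#' `n_pcs` genotype principal components.
#'
#' @param cohort A [burden_cohort()].
#' @param weights A [weight_table()] (drives the damaging-category list).
#' @param qc A [qc_config()].
#' @param ancestry An [ancestry_config()]; set `NULL` to skip scoring
#'   (scores and flags become NA/FALSE).
#' @param n_pcs Number of genotype principal components (default 20).
#' @return Data frame: `sample_id`, `status`, `urv`, `durv`,
#'   `ancestry_score`, `excluded`, `PC1` ... `PCk`.
#' @export
subject_covariates <- function(cohort,
                               weights = default_weight_table(),
                               qc = qc_config(),
                               ancestry = ancestry_config(),
                               n_pcs = 20L) {
  prep <- prepare_variants(cohort, weights, qc)
  counts <- urv_counts(prep$gm, prep$variants, damaging_config(weights))
  out <- data.frame(sample_id = counts$sample_id,
                    status = as.character(prep$gm$status),
                    urv = counts$urv, durv = counts$durv,
                    ancestry_score = NA_real_, excluded = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(ancestry)) {
    sc <- tryCatch(ancestry_scores(prep$gm, prep$variants, ancestry),
                   error = function(e) {
                     message("subject_covariates: ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(sc)) {
      out$ancestry_score <- unname(sc)
      out$excluded <- unname(exclude_outliers(sc, ancestry))
    }
  }
  if (n_pcs > 0) {
    pcs <- genotype_pcs(prep$gm, k = n_pcs)
    out <- cbind(out, as.data.frame(pcs, row.names = NULL))
  }
  out
}

#' Drop subjects from a cohort
#'
#' Subsets the genotype matrix (and quality layer) to the retained
#' subjects, e.g. after [exclude_outliers()].
#'
#' @param cohort A [burden_cohort()].
#' @param exclude Logical flags (or sample ids) of subjects to remove.
#' @return The reduced [burden_cohort()].
#' @export
drop_subjects <- function(cohort, exclude) {
  if (is.character(exclude))
    exclude <- rownames(cohort$geno$geno) %in% exclude
  keep <- !exclude
  gm <- cohort$geno
  gm2 <- genotype_matrix(gm$geno[keep, , drop = FALSE],
                         as.character(gm$status)[keep],
                         if (is.null(gm$gq)) NULL
                         else gm$gq[keep, , drop = FALSE])
  out <- cohort
  out$geno <- gm2
  if (!is.null(out$subjects))
    out$subjects <- out$subjects[keep, , drop = FALSE]
  out
}
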