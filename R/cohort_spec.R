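#' Parameterisation of a synthetic case-control exome cohort
#'
#' A `cohort_spec` fixes every parameter of the synthetic cohort generator:
#' cohort sizes, the gene universe, the rare-allele frequency law, the
#' consequence/annotation mix, the disease model used to assign case status,
#' the singleton (ultra-rare variant) process, an optional confounding
#' subpopulation, and the genotype-quality corruption model. Together with the
#' seed it determines the generated cohort completely: the same spec and seed
#' always reproduce byte-identical output files.
#'
#' The disease model is logistic: a subject carrying dosage \eqn{g_v} at the
#' risk-gene variants has case probability
#' \eqn{logit^{-1}(\alpha + s \sum_v w_v g_v)}, where \eqn{w_v} is the
#' variant's functional weight, `effect_scale` is \eqn{s}, and \eqn{\alpha}
#' is set so the expected case fraction matches the requested cohort balance.
#' Population allele frequencies follow a Beta law truncated to
#' `(0, maf_ceiling]`; singletons are materialised afterwards as sites with
#' exactly one alternate allele in one subject, flagged absent from the
#' external reference panel.
#'
#' The confounding subpopulation emulates the Finnish-ancestry structure seen
#' in Swedish exome cohorts: a fraction of each cohort is drawn from a
#' subpopulation in which a subset of variants have their allele frequency
#' multiplied by `subpop_freq_shift` (mirrored in the emitted `AF_POPB`
#' reference frequency) and whose per-subject singleton rate is
#' `subpop_singleton_rate` instead of `singleton_rate`.
#'
#' @param n_cases,n_controls Number of cases and controls (both > 0).
#' @param n_genes Number of genes in the simulated exome (> 0).
#' @param variants_per_gene Poisson mean of the non-singleton variant count
#'   per gene.
#' @param maf_beta Length-2 shape parameters of the Beta frequency law,
#'   truncated above at `maf_ceiling`.
#' @param maf_ceiling Upper bound on simulated population frequencies.
#' @param consequence_probs Named probability vector over consequence
#'   categories; names must be categories of [default_weight_table()].
#'   Normalised internally.
#' @param polyphen_probs,sift_probs Named probability vectors over PolyPhen
#'   classes (`benign`, `possibly_damaging`, `probably_damaging`) and SIFT
#'   classes (`tolerated`, `deleterious`) assigned to missense variants; all
#'   other categories are annotated `unknown`.
#' @param risk_genes Character vector of gene ids carrying case enrichment
#'   (subset of the gene universe `GENE0001 ...`), or an integer count n
#'   meaning the first n genes.
#' @param effect_scale Log-odds increment per weighted risk allele unit
#'   (>= 0); 0 gives a null cohort.
#' @param singleton_rate Mean singleton (URV) count per main-population
#'   subject.
#' @param durv_case_excess Multiplier on the damaging-singleton rate in cases
#'   relative to controls (1 = no programmed dURV enrichment).
#' @param subpop_fraction_cases,subpop_fraction_controls Fraction of each
#'   cohort drawn from the confounding subpopulation, in `[0, 1]`.
#' @param subpop_freq_shift Multiplier applied to the shifted variants'
#'   allele frequencies in the subpopulation (capped at 0.5).
#' @param subpop_shift_fraction Fraction of non-singleton variants whose
#'   frequency is shifted in the subpopulation.
#' @param subpop_singleton_rate Mean singleton count per subpopulation
#'   subject; defaults to `singleton_rate`.
#' @param reference_membership_rate Probability that a non-singleton variant
#'   is flagged present in the external reference panel (`INREF`).
#' @param quality_model List with elements `low_gq_rate` (fraction of
#'   genotypes given a quality score below 30), `missing_rate` (fraction of
#'   genotypes emitted as missing), and `site_fail_rate` (fraction of sites
#'   given a non-PASS FILTER).
#' @param seed Integer seed; every random draw of the generator flows from it.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [simulate_cohort()], [inject_stratification()]
#' @export
cohort_spec <- function(n_cases,
                        n_controls,
                        n_genes,
                        variants_per_gene = 8,
                        maf_beta = c(0.5, 250),
                        maf_ceiling = 0.01,
                        consequence_probs = default_consequence_probs(),
                        polyphen_probs = c(benign = 0.4,
                                           possibly_damaging = 0.3,
                                           probably_damaging = 0.3),
                        sift_probs = c(tolerated = 0.5, deleterious = 0.5),
                        risk_genes = character(0),
                        effect_scale = 0,
                        singleton_rate = 2,
                        durv_case_excess = 1,
                        subpop_fraction_cases = 0,
                        subpop_fraction_controls = 0,
                        subpop_freq_shift = 1,
                        subpop_shift_fraction = 0.3,
                        subpop_singleton_rate = NULL,
                        reference_membership_rate = 0.2,
                        quality_model = list(low_gq_rate = 0.02,
                                             missing_rate = 0.01,
                                             site_fail_rate = 0.02),
                        seed = 1L) {
  stopifnot(length(n_cases) == 1, length(n_controls) == 1, length(n_genes) == 1)
  if (n_cases < 1 || n_controls < 1)
    stop("cohort_spec: need at least one case and one control", call. = FALSE)
  if (n_genes < 1)
    stop("cohort_spec: need at least one gene", call. = FALSE)
  if (!is.numeric(maf_beta) || length(maf_beta) != 2 || any(maf_beta <= 0))
    stop("cohort_spec: maf_beta must be two positive shape parameters",
         call. = FALSE)
  if (maf_ceiling <= 0 || maf_ceiling > 0.5)
    stop("cohort_spec: maf_ceiling must be in (0, 0.5]", call. = FALSE)
  if (!is.finite(effect_scale) || effect_scale < 0)
    stop("cohort_spec: effect_scale must be finite and >= 0", call. = FALSE)
  if (subpop_fraction_cases < 0 || subpop_fraction_cases > 1 ||
      subpop_fraction_controls < 0 || subpop_fraction_controls > 1)
    stop("cohort_spec: subpopulation fractions must lie in [0, 1]",
         call. = FALSE)
  if (subpop_freq_shift <= 0)
    stop("cohort_spec: subpop_freq_shift must be positive", call. = FALSE)
  if (singleton_rate < 0 || durv_case_excess < 0)
    stop("cohort_spec: rates must be non-negative", call. = FALSE)
  if (reference_membership_rate < 0 || reference_membership_rate > 1)
    stop("cohort_spec: reference_membership_rate must lie in [0, 1]",
         call. = FALSE)
  qm <- utils::modifyList(
    list(low_gq_rate = 0.02, missing_rate = 0.01, site_fail_rate = 0.02),
    quality_model)
  if (any(unlist(qm[c("low_gq_rate", "missing_rate", "site_fail_rate")]) < 0) ||
      any(unlist(qm[c("low_gq_rate", "missing_rate", "site_fail_rate")]) > 1))
    stop("cohort_spec: quality_model rates must lie in [0, 1]", call. = FALSE)

  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  if (is.numeric(risk_genes) && length(risk_genes) == 1 &&
      risk_genes == as.integer(risk_genes) && !grepl("GENE", risk_genes[1])) {
    if (risk_genes > n_genes)
      stop("cohort_spec: more risk genes than genes", call. = FALSE)
    risk_genes <- gene_ids[seq_len(risk_genes)]
  }
  risk_genes <- as.character(risk_genes)
  if (!all(risk_genes %in% gene_ids))
    stop("cohort_spec: risk_genes must be a subset of the gene universe",
         call. = FALSE)

  wt <- default_weight_table()
  if (!all(names(consequence_probs) %in% names(wt$base)))
    stop("cohort_spec: consequence_probs has categories outside the default ",
         "weight table", call. = FALSE)
  consequence_probs <- consequence_probs / sum(consequence_probs)
  polyphen_probs <- polyphen_probs / sum(polyphen_probs)
  sift_probs <- sift_probs / sum(sift_probs)

  spec <- list(
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes),
    gene_ids = gene_ids,
    variants_per_gene = variants_per_gene,
    maf_beta = maf_beta,
    maf_ceiling = maf_ceiling,
    consequence_probs = consequence_probs,
    polyphen_probs = polyphen_probs,
    sift_probs = sift_probs,
    risk_genes = risk_genes,
    effect_scale = effect_scale,
    singleton_rate = singleton_rate,
    durv_case_excess = durv_case_excess,
    subpop_fraction_cases = subpop_fraction_cases,
    subpop_fraction_controls = subpop_fraction_controls,
    subpop_freq_shift = subpop_freq_shift,
    subpop_shift_fraction = subpop_shift_fraction,
    subpop_singleton_rate = if (is.null(subpop_singleton_rate))
      singleton_rate else subpop_singleton_rate,
    reference_membership_rate = reference_membership_rate,
    quality_model = qm,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Default consequence-category sampling probabilities
#'
#' An exome-like mix over the categories of [default_weight_table()]:
#' mostly missense and synonymous sites with a minority of UTR, splice and
#' loss-of-function variants.
#'
#' @return Named numeric probability vector (sums to 1).
#' @export
default_consequence_probs <- function() {
  p <- c(synonymous = 0.315,
         missense = 0.45,
         intronic = 0.05,
         five_prime_utr = 0.02,
         three_prime_utr = 0.03,
         splice_region = 0.05,
         inframe_indel = 0.02,
         stop_gained = 0.03,
         frameshift = 0.02,
         splice_donor = 0.005,
         splice_acceptor = 0.005,
         stop_lost = 0.0025,
         start_lost = 0.0025)
  p / sum(p)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_cases, "cases /", x$n_controls,
      "controls,", x$n_genes, "genes\n")
  cat("  variants/gene (Poisson mean):", x$variants_per_gene,
      " MAF ~ Beta(", x$maf_beta[1], ",", x$maf_beta[2], ") <=",
      x$maf_ceiling, "\n")
  cat("  risk genes:", length(x$risk_genes),
      " effect scale:", x$effect_scale, "\n")
  cat("  singleton rate:", x$singleton_rate,
      " dURV case excess:", x$durv_case_excess, "\n")
  if (x$subpop_fraction_cases > 0 || x$subpop_fraction_controls > 0)
    cat("  subpopulation: fractions", x$subpop_fraction_cases, "/",
        x$subpop_fraction_controls, ", freq shift", x$subpop_freq_shift,
        ", singleton rate", x$subpop_singleton_rate, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
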