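#' Bonferroni threshold on the SLP scale
#'
#' The absolute SLP a test must exceed to remain significant at level
#' `alpha` after Bonferroni correction over `n` tests:
#' `log10(n / alpha)`. For example, 22023 gene-wise tests at alpha 0.05
#' give 5.64; 31 candidate gene sets give 2.8; 1454 GO sets give 4.5.
#' Strictly increasing in `n` and decreasing in `alpha`.
#'
#' @param n Number of tests (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return The SLP threshold (base-10 logarithm).
#' @export
bonferroni_slp_threshold <- function(n, alpha = 0.05) {
  if (!is.numeric(n) || any(n < 1))
    stop("bonferroni_slp_threshold: n must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1))
    stop("bonferroni_slp_threshold: alpha must lie in (0, 1)",
         call. = FALSE)
  log10(n / alpha)
}

#' Carrier 2x2 table
#'
#' Carrier (typically heterozygote) counts and cohort sizes for a single
#' variant, as tabulated in case-control reports (e.g. "heterozygous in
#' 51/6242 controls and 94/4962 cases").
#'
#' @param carrier_cases,n_cases Carrier count and cohort size, cases.
#' @param carrier_controls,n_controls Carrier count and cohort size,
#'   controls.
#' @return An object of class `carrier_table`.
#' @export
carrier_table <- function(carrier_cases, n_cases,
                          carrier_controls, n_controls) {
  if (n_cases <= 0 || n_controls <= 0)
    stop("carrier_table: cohort sizes must be positive", call. = FALSE)
  if (carrier_cases < 0 || carrier_controls < 0 ||
      carrier_cases > n_cases || carrier_controls > n_controls)
    stop("carrier_table: carrier counts must lie in [0, cohort size]",
         call. = FALSE)
  structure(list(carrier_cases = carrier_cases, n_cases = n_cases,
                 carrier_controls = carrier_controls,
                 n_controls = n_controls,
                 noncarrier_cases = n_cases - carrier_cases,
                 noncarrier_controls = n_controls - carrier_controls),
            class = "carrier_table")
}

#' Carrier odds ratio (and exact-test p)
#'
#' Cross-product odds ratio of carriers vs non-carriers between cases and
#' controls:
#' `(carrier_cases / noncarrier_cases) / (carrier_controls /
#' noncarrier_controls)`. With a zero cell a 0.5 continuity correction is
#' added to every cell. Swapping the two cohorts' rows gives the
#' reciprocal OR.
#'
#' @param table A [carrier_table()].
#' @param exact_p Also compute Fisher's exact two-sided p (default TRUE).
#' @return List: `or`, `p` (`NA` when `exact_p = FALSE`), `corrected`
#'   (whether the continuity correction was applied).
#' @export
carrier_or <- function(table, exact_p = TRUE) {
  stopifnot(inherits(table, "carrier_table"))
  cells <- c(table$carrier_cases, table$noncarrier_cases,
             table$carrier_controls, table$noncarrier_controls)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] / cc[2]) / (cc[3] / cc[4])
  p <- NA_real_
  if (exact_p) {
    m <- matrix(cells, 2, 2, byrow = TRUE)
    p <- stats::fisher.test(m)$p.value
  }
  list(or = or, p = p, corrected = corrected)
}

#' Expected signed-null SLP order statistics
#'
#' Under the null the SLP of an unbiased two-sided test is distributed as
#' `S * (-log10 U)` with `U ~ Uniform(0, 1)` and `S = +/-1` equiprobable.
#' Rank `i` of `n` (ascending) is assigned the quantile of this law at
#' `q = (i - 0.5) / n`: `log10(2q)` for `q < 0.5`, `0` at `q = 0.5`, and
#' `-log10(2(1 - q))` for `q > 0.5`. The sequence is antisymmetric about
#' its middle rank.
#'
#' @param n Number of tests (>= 1).
#' @return Numeric vector of expected SLPs, ascending.
#' @export
expected_signed_null_quantiles <- function(n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  q <- (seq_len(n) - 0.5) / n
  ifelse(q < 0.5, log10(2 * q),
         ifelse(q > 0.5, -log10(2 * (1 - q)), 0))
}

#' Least-squares QQ slope through the origin
#'
#' Slope of observed vs expected order statistics, constrained through the
#' origin. A slope near 1 indicates null calibration; overlapping
#' (positively correlated) tests flatten it below 1.
#'
#' @param observed,expected Equal-length numeric sequences.
#' @return The slope.
#' @export
qq_slope <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("qq_slope: sequences must have equal length", call. = FALSE)
  sum(observed * expected) / sum(expected^2)
}

#' QQ data for a vector of signed statistics
#'
#' Sorts the observed SLPs, pairs them with the expected signed-null order
#' statistics and fits the through-origin slope.
#'
#' @param observed_slp Numeric vector of SLPs.
#' @return List of class `qq_data`: `table` (data frame `rank`, `expected`,
#'   `observed`) and `slope`.
#' @export
qq_data <- function(observed_slp) {
  obs <- sort(observed_slp)
  exp_ <- expected_signed_null_quantiles(length(obs))
  structure(list(table = data.frame(rank = seq_along(obs),
                                    expected = exp_, observed = obs),
                 slope = qq_slope(obs, exp_)),
            class = "qq_data")
}

#' @export
print.qq_data <- function(x, ...) {
  cat("qq_data:", nrow(x$table), "tests; slope",
      sprintf("%.3f", x$slope), "\n")
  invisible(x)
}

#' Cohort accounting after exclusions
#'
#' @param initial Named vector or list with `case` and `control` initial
#'   sizes.
#' @param excluded Either a logical flag vector paired with `status`, or a
#'   named vector/list of per-cohort exclusion counts.
#' @param status Case/control labels aligned with logical `excluded`.
#' @return Named integer vector of remaining sizes (`case`, `control`).
#' @export
cohort_accounting <- function(initial, excluded, status = NULL) {
  initial <- unlist(initial)[c("case", "control")]
  if (is.logical(excluded)) {
    if (is.null(status))
      stop("cohort_accounting: logical flags need a status vector",
           call. = FALSE)
    excluded <- c(case = sum(excluded & status == "case"),
                  control = sum(excluded & status == "control"))
  } else {
    excluded <- unlist(excluded)[c("case", "control")]
  }
  if (any(excluded > initial))
    stop("cohort_accounting: more exclusions than subjects", call. = FALSE)
  out <- initial - excluded
  stats::setNames(as.integer(out), c("case", "control"))
}
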