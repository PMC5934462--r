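test_that("ancestry scores are log-frequency-ratio allele sums", {
  geno <- matrix(c(0L, 2L, 1L,   0L, 1L, 0L,   0L, 1L, 2L), 3)
  gm <- make_gm(geno, c("case", "case", "control"))
  v <- make_variants(gm,
                     af_popa = c(0.002, 0.01, 0.2),
                     af_popb = c(0.05, 0.01, 0.4))
  # only v1 discriminates (ratio 25, base freq <= 0.01)
  sc <- ancestry_scores(gm, v, ancestry_config(min_ratio = 5))
  expect_equal(unname(sc), c(0, 2, 1) * log10(25))
  # subject with no discriminating alleles scores 0
  expect_equal(unname(sc[1]), 0)
  # linearity in allele counts: a 'sum' subject scores the sum
  gm2 <- make_gm(rbind(geno, geno[1, ] + geno[3, ]),
                 c("case", "case", "control", "control"))
  sc2 <- ancestry_scores(gm2, make_variants(
    gm2, af_popa = c(0.002, 0.01, 0.2), af_popb = c(0.05, 0.01, 0.4)),
    ancestry_config(min_ratio = 5))
  expect_equal(unname(sc2[4]), unname(sc[1] + sc[3]))
  # no discriminating variants is a hard error
  v_eq <- make_variants(gm, af_popa = 0.01, af_popb = 0.01)
  expect_error(ancestry_scores(gm, v_eq), "no discriminating")
})

test_that("outlier exclusion flags high scorers and honours its limits", {
  expect_false(any(exclude_outliers(rep(3.2, 50))))
  set.seed(4)
  sc <- c(stats::rnorm(95), stats::rnorm(5, 12))
  fl <- exclude_outliers(sc, ancestry_config())
  expect_true(all(fl[96:100]))
  expect_false(any(fl[1:95]))
  # an enormous cutoff excludes nobody
  expect_false(any(exclude_outliers(sc, ancestry_config(sd_cutoff = 1e6))))
})

test_that("a planted subpopulation is found by score and exclusion", {
  spec <- cohort_spec(400, 400, 40, seed = 37,
                      subpop_fraction_cases = 0.15,
                      subpop_fraction_controls = 0.05,
                      subpop_freq_shift = 10,
                      singleton_rate = 1, subpop_singleton_rate = 0.5)
  co <- inject_stratification(spec)
  sc <- ancestry_scores(co$geno, co$variants)
  truth <- co$subjects$subpop
  expect_gt(mean(sc[truth]), mean(sc[!truth]))
  expect_gt(auroc(sc, truth), 0.9)
  fl <- exclude_outliers(sc)
  sens <- sum(fl & truth) / sum(truth)
  spec_ <- sum(!fl & !truth) / sum(!truth)
  expect_gt(sens, 0.7)
  expect_gt(spec_, 0.95)
})

test_that("URV and dURV counts honour definitions and conservation", {
  status <- rep(c("case", "control"), c(3, 3))
  geno <- matrix(0L, 6, 5)
  geno[2, 1] <- 1L; geno[2, 2] <- 1L; geno[2, 3] <- 2L  # subject 2: 3 URVs
  geno[5, 4] <- 1L                                       # subject 5: 1 URV
  geno[1, 5] <- 1L; geno[3, 5] <- 1L                     # not a singleton
  gm <- make_gm(geno, status)
  v <- make_variants(gm, csqcat = c("stop_gained", "synonymous", "missense",
                                    "missense", "stop_gained"),
                     polyphen = c("unknown", "unknown", "probably_damaging",
                                  "benign", "unknown"),
                     sift = c("unknown", "unknown", "unknown", "tolerated",
                              "unknown"))
  v$singleton <- classify_singletons(gm, v)
  cnt <- urv_counts(gm, v)
  expect_equal(cnt$urv, c(0L, 3L, 0L, 0L, 1L, 0L))
  # stop-gained counts unconditionally; damaging missense counts;
  # benign missense does not
  expect_equal(cnt$durv, c(0L, 2L, 0L, 0L, 0L, 0L))
  expect_true(all(cnt$durv <= cnt$urv))
  expect_equal(sum(cnt$urv), sum(v$singleton))
})

test_that("URV counting recovers a programmed subpopulation rate difference", {
  spec <- cohort_spec(300, 300, 20, seed = 43,
                      subpop_fraction_cases = 0.5,
                      subpop_fraction_controls = 0.5,
                      subpop_freq_shift = 10,
                      singleton_rate = 3, subpop_singleton_rate = 1,
                      quality_model = list(low_gq_rate = 0, missing_rate = 0,
                                           site_fail_rate = 0))
  co <- simulate_cohort_data(spec)
  v <- transform_truth_singletons(co)
  cnt <- urv_counts(co$geno, v)
  sub <- co$subjects$subpop
  m_main <- mean(cnt$urv[!sub]); m_sub <- mean(cnt$urv[sub])
  se <- sqrt(3 / sum(!sub) + 1 / sum(sub))
  expect_lt(abs(m_main - 3), 5 * sqrt(3 / sum(!sub)))
  expect_lt(abs(m_sub - 1), 5 * sqrt(1 / sum(sub)))
  expect_lt(abs((m_main - m_sub) - 2), 5 * se)
})

test_that("genotype PCs are deterministic, sign-fixed and separate subpopulations", {
  # strong, pervasive frequency shift so ancestry dominates the variance
  spec <- cohort_spec(250, 250, 60, seed = 47,
                      subpop_fraction_cases = 0.2,
                      subpop_fraction_controls = 0.2,
                      subpop_freq_shift = 10, subpop_shift_fraction = 0.6,
                      maf_beta = c(2, 300), singleton_rate = 0)
  co <- simulate_cohort_data(spec)
  pcs <- genotype_pcs(co$geno, k = 4)
  expect_identical(pcs, genotype_pcs(co$geno, k = 4))
  r <- stats::cor(pcs[, 1], as.numeric(co$subjects$subpop))
  expect_gt(abs(r), 0.9)

  # duplicated subjects coincide in PC space
  g <- co$geno$geno[c(1:20, 1), ]
  rownames(g) <- c(rownames(g)[1:20], "DUP")
  gm <- genotype_matrix(g, c(as.character(co$geno$status)[1:20], "control"))
  p2 <- genotype_pcs(gm, k = 2, maf_floor = 0)
  expect_equal(unname(p2[1, ]), unname(p2[21, ]), tolerance = 1e-8)

  # k = 0 gives an empty covariate block; k beyond rank warns and reduces
  expect_equal(ncol(genotype_pcs(co$geno, k = 0)), 0L)
  small <- genotype_matrix(co$geno$geno[1:5, ],
                           c("case", "case", "case", "control", "control"))
  expect_warning(p5 <- genotype_pcs(small, k = 10), "reduced")
  expect_lte(ncol(p5), 4L)
})

test_that("dURV enrichment regression behaves under the null and flags separation", {
  set.seed(53)
  n <- 400
  cov <- data.frame(durv = stats::rpois(n, 1.5), urv = stats::rpois(n, 3))
  status <- rep(c("case", "control"), each = n / 2)
  r <- durv_enrichment(cov, status, adjust = "none")
  expect_false(r$separation)
  expect_lt(abs(r$estimate), 0.5)
  expect_gt(r$p, 1e-3)
  # adjusted variant also runs with URV covariate
  r2 <- durv_enrichment(cov, status, adjust = "urv")
  expect_false(r2$separation)
  # perfect separation is flagged, no estimate reported
  sep <- data.frame(durv = c(rep(10, 20), rep(0, 20)))
  st <- rep(c("case", "control"), each = 20)
  rs <- durv_enrichment(sep, st, adjust = "none")
  expect_true(rs$separation)
  expect_true(is.na(rs$estimate))
})

test_that("subject_covariates assembles counts, scores, flags and PCs", {
  spec <- cohort_spec(120, 120, 15, seed = 59,
                      subpop_fraction_cases = 0.2,
                      subpop_fraction_controls = 0.05,
                      subpop_freq_shift = 10,
                      singleton_rate = 2, subpop_singleton_rate = 0.5)
  co <- inject_stratification(spec)
  cov <- subject_covariates(co, n_pcs = 3)
  expect_equal(nrow(cov), 240L)
  expect_true(all(c("urv", "durv", "ancestry_score", "excluded",
                    "PC1", "PC3") %in% names(cov)))
  expect_true(all(cov$durv <= cov$urv))
  expect_true(all(is.finite(cov$PC1)))
  # dropping flagged subjects shrinks the cohort consistently
  red <- drop_subjects(co, cov$excluded)
  expect_equal(nrow(red$geno$geno), sum(!cov$excluded))
  expect_equal(nrow(red$subjects), sum(!cov$excluded))
})
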