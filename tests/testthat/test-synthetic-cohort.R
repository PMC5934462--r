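test_that("cohort_spec rejects invalid parameterisations", {
  expect_error(cohort_spec(0, 10, 5), "at least one case")
  expect_error(cohort_spec(10, 10, 0), "at least one gene")
  expect_error(cohort_spec(10, 10, 5, risk_genes = "GENE9999"),
               "subset of the gene universe")
  expect_error(cohort_spec(10, 10, 5, subpop_fraction_cases = 1.2), "0, 1")
  expect_error(cohort_spec(10, 10, 5, effect_scale = -1), "effect_scale")
  expect_error(cohort_spec(10, 10, 5, maf_ceiling = 0), "maf_ceiling")
})

test_that("identical spec and seed give byte-identical output files", {
  spec <- cohort_spec(40, 50, 8, seed = 11,
                      subpop_fraction_cases = 0.2,
                      subpop_fraction_controls = 0.1,
                      subpop_freq_shift = 10, risk_genes = 2,
                      effect_scale = 0.03)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  p1 <- simulate_cohort(spec, d1)
  p2 <- simulate_cohort(spec, d2)
  for (f in c("vcf", "phenotype", "gene_map", "gene_sets", "truth_table")) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  }
  p3 <- simulate_cohort(cohort_spec(40, 50, 8, seed = 12), d1,
                        prefix = "other")
  expect_false(tools::md5sum(p1$vcf) == tools::md5sum(p3$vcf))
})

test_that("genotypes are Hardy-Weinberg at the simulated frequencies", {
  spec <- cohort_spec(1500, 1500, 30, variants_per_gene = 6,
                      singleton_rate = 0, seed = 21,
                      quality_model = list(low_gq_rate = 0,
                                           missing_rate = 0,
                                           site_fail_rate = 0))
  co <- simulate_cohort_data(spec)
  f <- co$truth$f_main
  n <- nrow(co$geno$geno)
  het <- colSums(co$geno$geno == 1L)
  exp_het <- n * 2 * f * (1 - f)
  # aggregate over variants: observed total het within 4 SD of binomial sum
  sd_tot <- sqrt(sum(n * 2 * f * (1 - f) * (1 - 2 * f * (1 - f))))
  expect_lt(abs(sum(het) - sum(exp_het)), 4 * sd_tot)
  # pre-corruption truth counts match the emitted genotypes exactly
  expect_identical(unname(colSums(co$geno$geno[co$geno$status == "case", ])),
                   as.numeric(co$truth$ac_case))
})

test_that("null spec gives equal case and control allele-frequency expectations", {
  spec <- cohort_spec(800, 800, 40, effect_scale = 0, singleton_rate = 0,
                      seed = 31,
                      quality_model = list(low_gq_rate = 0, missing_rate = 0,
                                           site_fail_rate = 0))
  co <- simulate_cohort_data(spec)
  d <- co$truth$ac_case / (2 * 800) - co$truth$ac_control / (2 * 800)
  # mean per-variant frequency difference ~ 0 within Monte-Carlo error
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * se + 1e-12)
})

test_that("singletons are single-subject, reference-absent sites", {
  spec <- cohort_spec(150, 150, 10, singleton_rate = 2, seed = 41)
  co <- simulate_cohort_data(spec)
  sng <- co$truth[co$truth$is_singleton, ]
  expect_gt(nrow(sng), 100)
  expect_true(all(sng$ac_case + sng$ac_control == 1))
  expect_true(all(!co$variants$in_ref[co$truth$is_singleton]))
  expect_true(all(sng$carrier %in% co$subjects$sample_id))
  # mean singleton count per subject ~ Poisson(singleton_rate)
  expect_lt(abs(nrow(sng) / 300 - 2), 4 * sqrt(2 / 300) + 0.05)
})

test_that("truth-table allele counts survive the VCF round trip", {
  spec <- cohort_spec(60, 70, 12, seed = 51,
                      quality_model = list(low_gq_rate = 0.05,
                                           missing_rate = 0,
                                           site_fail_rate = 0.05))
  d <- file.path(tempdir(), "rt")
  paths <- simulate_cohort(spec, d)
  co <- load_cohort(paths$vcf, paths$phenotype, paths$gene_map)
  expect_identical(co$variants$variant_id, paths$truth$variant_id)
  got_case <- colSums(co$geno$geno[co$geno$status == "case", , drop = FALSE])
  expect_equal(unname(got_case), paths$truth$ac_case)
  # gene assignment in the loaded cohort matches the generator's truth
  one_gene <- lengths(co$variants$genes) == 1
  expect_true(all(one_gene))
  expect_identical(unlist(co$variants$genes), paths$truth$gene_id)
})

test_that("an extreme effect scale is refused rather than saturated", {
  spec <- cohort_spec(50, 50, 4, risk_genes = 4, effect_scale = 50,
                      variants_per_gene = 20, maf_beta = c(5, 100),
                      seed = 61)
  expect_error(simulate_cohort_data(spec), "case probability")
})

test_that("inject_stratification enforces a genuinely confounded design", {
  base <- cohort_spec(50, 50, 5, seed = 71)
  expect_error(inject_stratification(base), "fractions must differ")
  sp <- cohort_spec(50, 50, 5, seed = 71, subpop_fraction_cases = 0.2,
                    subpop_fraction_controls = 0.05)
  expect_error(inject_stratification(sp), "singleton rate must differ")
  sp2 <- cohort_spec(200, 200, 10, seed = 71,
                     subpop_fraction_cases = 0.3,
                     subpop_fraction_controls = 0.05,
                     singleton_rate = 4, subpop_singleton_rate = 1,
                     subpop_freq_shift = 10)
  co <- inject_stratification(sp2)
  sub <- co$subjects$subpop
  expect_gt(mean(sub[co$subjects$status == "case"]),
            mean(sub[co$subjects$status == "control"]))
  cnt <- urv_counts(co$geno, transform_truth_singletons(co))
  expect_lt(mean(cnt$urv[sub]), mean(cnt$urv[!sub]))
})

test_that("a unit frequency shift leaves the subpopulation invisible to the ancestry score", {
  sp <- cohort_spec(100, 100, 10, seed = 81,
                    subpop_fraction_cases = 0.2,
                    subpop_fraction_controls = 0.05,
                    subpop_freq_shift = 1,
                    singleton_rate = 2, subpop_singleton_rate = 0.5)
  co <- inject_stratification(sp)
  expect_error(ancestry_scores(co$geno, co$variants), "no discriminating")
})
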