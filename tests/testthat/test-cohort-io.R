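test_that("GT fields decode to allele counts 0/1/2 with GQ carried along", {
  d <- tempdir()
  vcf <- write_test_vcf(
    file.path(d, "enc.vcf"), c("A1", "A2", "A3"),
    c("1\t150\t.\tA\tG\t.\tPASS\tCSQCAT=synonymous;INREF=0\tGT:GQ\t0/0:50\t0/1:40\t1/1:29",
      "1\t160\t.\tC\tT\t.\tq10\tCSQCAT=missense;PPH=probably_damaging;SIFTC=deleterious;INREF=1;AF_POPA=0.002;AF_POPB=0.05\tGT:GQ\t./.:.\t0|1:35\t0/0:90"))
  phe <- write_phenotypes(file.path(d, "enc_phe.tsv"), c("A1", "A2", "A3"),
                          c("case", "case", "control"))
  map <- write_gene_map(file.path(d, "enc_map.tsv"), "G1", "1", 100, 200)
  co <- load_cohort(vcf, phe, map)
  expect_equal(unname(co$geno$geno[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(co$geno$geno[, 2]), c(NA_integer_, 1L, 0L))
  expect_equal(unname(co$geno$gq[, 1]), c(50, 40, 29))
  expect_equal(co$variants$filter, c("PASS", "q10"))
  expect_equal(co$variants$csqcat, c("synonymous", "missense"))
  # absent annotation keys default to unknown, never to damaging
  expect_equal(co$variants$polyphen, c("unknown", "probably_damaging"))
  expect_equal(co$variants$sift, c("unknown", "deleterious"))
  expect_equal(co$variants$in_ref, c(FALSE, TRUE))
  expect_equal(co$variants$af_popb, c(NA, 0.05))
  expect_equal(co$variants$genes, list("G1", "G1"))
  expect_s3_class(co, "burden_cohort")
})

test_that("multi-allelic records split per alternate allele", {
  d <- tempdir()
  vcf <- write_test_vcf(
    file.path(d, "ma.vcf"), c("B1", "B2", "B3"),
    "1\t150\t.\tA\tG,T\t.\tPASS\tCSQCAT=missense;INREF=0\tGT:GQ\t1/2:60\t0/2:60\t1/1:60")
  phe <- write_phenotypes(file.path(d, "ma_phe.tsv"), c("B1", "B2", "B3"),
                          c("case", "control", "control"))
  map <- write_gene_map(file.path(d, "ma_map.tsv"), "G1", "1", 100, 200)
  co <- load_cohort(vcf, phe, map)
  expect_equal(ncol(co$geno$geno), 2L)
  expect_equal(co$variants$alt, c("G", "T"))
  # allele 1 dosages: 1/2 -> 1, 0/2 -> 0, 1/1 -> 2; other alt acts as ref
  expect_equal(unname(co$geno$geno[, 1]), c(1L, 0L, 2L))
  expect_equal(unname(co$geno$geno[, 2]), c(1L, 1L, 0L))
})

test_that("phenotype contract violations are hard errors", {
  d <- tempdir()
  vcf <- write_test_vcf(
    file.path(d, "ph.vcf"), c("C1", "C2", "C3"),
    "1\t150\t.\tA\tG\t.\tPASS\tCSQCAT=synonymous\tGT:GQ\t0/0:50\t0/1:50\t0/0:50")
  map <- write_gene_map(file.path(d, "ph_map.tsv"), "G1", "1", 100, 200)
  phe_bad <- write_phenotypes(file.path(d, "ph_bad.tsv"),
                              c("C1", "C2", "C3"),
                              c("case", "control", "unaffected"))
  expect_error(load_cohort(vcf, phe_bad, map), "unknown status.*unaffected")
  phe_missing <- write_phenotypes(file.path(d, "ph_mis.tsv"), c("C1", "C2"),
                                  c("case", "control"))
  expect_error(load_cohort(vcf, phe_missing, map), "C3")
})

test_that("gene assignment matches a brute-force interval-overlap oracle", {
  set.seed(202)
  for (rep in 1:8) {
    n_genes <- sample(3:8, 1)
    gmap <- data.frame(gene_id = sprintf("G%02d", seq_len(n_genes)),
                       chrom = sample(c("1", "2"), n_genes, replace = TRUE),
                       start = sample(1:500, n_genes))
    gmap$end <- gmap$start + sample(50:300, n_genes)
    v <- data.frame(chrom = sample(c("1", "2"), 40, replace = TRUE),
                    pos = sample(1:900, 40))
    got <- assign_genes(v, gmap)
    want <- lapply(seq_len(nrow(v)), function(i) {
      hit <- gmap$chrom == v$chrom[i] & gmap$start <= v$pos[i] &
        gmap$end >= v$pos[i]
      gmap$gene_id[hit]
    })
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("a variant inside two overlapping genes is listed under both", {
  gmap <- data.frame(gene_id = c("GA", "GB"), chrom = "1",
                     start = c(100, 150), end = c(200, 260))
  got <- assign_genes(data.frame(chrom = "1", pos = 180), gmap)
  expect_setequal(got[[1]], c("GA", "GB"))
})

test_that("gene aliases merge members into one label", {
  gm <- make_gm(matrix(c(0L, 1L, 1L, 0L), 2), c("case", "control"))
  v <- make_variants(gm, genes = list(c("PCDHGA1", "PCDHGA2"),
                                      c("PCDHGA1", "OTHER")))
  amap <- data.frame(member = c("PCDHGA1", "PCDHGA2"),
                     merged = "PCDHG", stringsAsFactors = FALSE)
  out <- merge_gene_aliases(v, amap)
  # both members collapse to one membership of the merged gene
  expect_equal(out$genes[[1]], "PCDHG")
  # union semantics with an unrelated gene
  expect_setequal(out$genes[[2]], c("PCDHG", "OTHER"))
  # empty alias map is the identity
  expect_identical(merge_gene_aliases(v, amap[0, ])$genes, v$genes)
  # contract violations
  expect_error(merge_gene_aliases(v, data.frame(
    member = c("A", "A"), merged = c("X", "Y"))), "two merged ids")
  expect_error(merge_gene_aliases(v, data.frame(
    member = c("A", "X"), merged = c("X", "Z"))), "cycle")
})

test_that("alias groups in the gene map merge at load time", {
  d <- tempdir()
  vcf <- write_test_vcf(
    file.path(d, "al.vcf"), c("D1", "D2"),
    "1\t150\t.\tA\tG\t.\tPASS\tCSQCAT=missense\tGT:GQ\t0/1:50\t0/0:50")
  phe <- write_phenotypes(file.path(d, "al_phe.tsv"), c("D1", "D2"),
                          c("case", "control"))
  map <- write_gene_map(file.path(d, "al_map.tsv"),
                        c("PCDHGA1", "PCDHGA2"), c("1", "1"),
                        c(100, 140), c(160, 220),
                        alias_group = c("PCDHG", "PCDHG"))
  co <- load_cohort(vcf, phe, map)
  expect_equal(co$variants$genes[[1]], "PCDHG")
})

test_that("GMT loading validates structure and reports matched counts", {
  d <- tempdir()
  gmt <- file.path(d, "sets.gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG9"), gmt)
  coll <- load_gene_sets(gmt, universe = c("G1", "G2", "G5"))
  expect_equal(coll$matched[["setA"]], 2L)
  expect_equal(coll$matched[["setB"]], 0L)
  expect_equal(coll$in_universe$setA, c(TRUE, TRUE, FALSE))
  # genes outside the universe are retained
  expect_equal(coll$sets$setA, c("G1", "G2", "G3"))

  single <- file.path(d, "single.gmt")
  writeLines("only\tdesc\tG1", single)
  expect_length(load_gene_sets(single)$sets, 1L)

  dup <- file.path(d, "dup.gmt")
  writeLines(c("s\td\tG1", "s\td\tG2"), dup)
  expect_error(load_gene_sets(dup), "duplicate set name")

  short <- file.path(d, "short.gmt")
  writeLines(c("ok\td\tG1", "bad\tdesc_only"), short)
  expect_error(load_gene_sets(short), "line 2")

  empty <- file.path(d, "empty.gmt")
  writeLines(character(0), empty)
  expect_error(load_gene_sets(empty), "empty")
})

test_that("gzipped GMT files load transparently", {
  gz <- file.path(tempdir(), "sets.gmt.gz")
  con <- gzfile(gz, "wt")
  writeLines("setA\tdesc\tG1\tG2", con)
  close(con)
  expect_equal(load_gene_sets(gz)$sets$setA, c("G1", "G2"))
})
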