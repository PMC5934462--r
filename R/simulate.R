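#' Simulate a case-control exome cohort in memory
#'
#' Generates a seeded synthetic cohort with the statistical structure the
#' weighted burden analysis assumes: genes on one chromosome, rare
#' non-singleton variants with Hardy-Weinberg genotypes at Beta-distributed
#' frequencies bounded by the MAF ceiling, case status assigned by a logistic
#' disease model over weighted risk-gene alleles, singleton (URV) sites
#' materialised as exactly one alternate allele in one subject and flagged
#' absent from the reference panel, an optional confounding subpopulation
#' with shifted frequencies and its own singleton rate, and per-genotype
#' quality/missingness corruption.
#'
#' @param spec A [cohort_spec()].
#' @return A [burden_cohort()] with additional elements `truth` (per-variant
#'   ground truth: true frequencies, risk flag, pre-corruption allele counts
#'   and singleton carrier), `subjects` (per-subject ground truth: cohort and
#'   subpopulation membership) and `gene_sets` (synthetic GMT content; the
#'   set `risk_set` collects the programmed risk genes when present).
#' @seealso [simulate_cohort()] writes the same cohort to standard files.
#' @export
simulate_cohort_data <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  wt <- default_weight_table()

  ## ---- gene map: non-overlapping intervals on one chromosome ----
  gene_map <- data.frame(
    gene_id = spec$gene_ids,
    chrom = "1",
    start = (seq_len(spec$n_genes) - 1L) * 10000L + 1L,
    end = (seq_len(spec$n_genes) - 1L) * 10000L + 5000L,
    alias_group = "",
    stringsAsFactors = FALSE)

  ## ---- non-singleton variant table ----
  n_per_gene <- stats::rpois(spec$n_genes, spec$variants_per_gene)
  if (sum(n_per_gene) == 0) n_per_gene[1] <- 1L
  v_gene <- rep(spec$gene_ids, n_per_gene)
  nv <- length(v_gene)
  f_main <- draw_truncated_beta(nv, spec$maf_beta, spec$maf_ceiling)
  shifted <- stats::runif(nv) < spec$subpop_shift_fraction
  f_sub <- ifelse(shifted, pmin(f_main * spec$subpop_freq_shift, 0.5), f_main)
  ann <- draw_annotations(nv, spec)
  in_ref <- stats::runif(nv) < spec$reference_membership_rate
  weight <- wt$base[ann$csqcat] +
    wt$polyphen_increment * (ann$polyphen %in% POLYPHEN_DAMAGING) +
    wt$sift_increment * (ann$sift == "deleterious")
  is_risk <- v_gene %in% spec$risk_genes
  beta <- ifelse(is_risk, spec$effect_scale * weight, 0)

  ## ---- subjects: stratified rejection sampling under the disease model ----
  n_case_sub <- round(spec$n_cases * spec$subpop_fraction_cases)
  n_ctrl_sub <- round(spec$n_controls * spec$subpop_fraction_controls)
  alpha <- stats::qlogis(spec$n_cases / (spec$n_cases + spec$n_controls))
  main <- sample_disease_group(spec$n_cases - n_case_sub,
                               spec$n_controls - n_ctrl_sub,
                               f_main, beta, alpha)
  sub <- sample_disease_group(n_case_sub, n_ctrl_sub, f_sub, beta, alpha)

  geno <- rbind(main$case, sub$case, main$control, sub$control)
  n_total <- spec$n_cases + spec$n_controls
  status <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  subpop <- c(rep(c(FALSE, TRUE), c(nrow(main$case), nrow(sub$case))),
              rep(c(FALSE, TRUE), c(nrow(main$control), nrow(sub$control))))
  sample_ids <- sprintf("S%05d", seq_len(n_total))
  rownames(geno) <- sample_ids

  ## ---- singletons: post-hoc single-allele placement ----
  sng <- place_singletons(spec, status, subpop)
  n_sng <- length(sng$gene)
  if (n_sng > 0) {
    sg <- matrix(0L, n_total, n_sng)
    sg[cbind(sng$carrier, seq_len(n_sng))] <- 1L
    rownames(sg) <- sample_ids
    geno <- cbind(geno, sg)
  }

  variants <- data.frame(
    gene = c(v_gene, sng$gene),
    csqcat = c(ann$csqcat, sng$csqcat),
    polyphen = c(ann$polyphen, sng$polyphen),
    sift = c(ann$sift, sng$sift),
    in_ref = c(in_ref, rep(FALSE, n_sng)),
    f_main = c(f_main, rep(NA_real_, n_sng)),
    f_sub = c(f_sub, rep(NA_real_, n_sng)),
    is_risk = c(is_risk, rep(FALSE, n_sng)),
    true_singleton = rep(c(FALSE, TRUE), c(nv, n_sng)),
    carrier = c(rep(NA_character_, nv), sample_ids[sng$carrier]),
    stringsAsFactors = FALSE)

  ## assign unique positions per gene and sort variants along the chromosome
  variants$pos <- assign_positions(variants$gene, gene_map)
  ord <- order(variants$pos)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, nrow(variants), replace = TRUE)
  variants$alt <- vapply(variants$ref,
                         function(r) sample(setdiff(bases, r), 1L), "")
  variants$chrom <- "1"
  variants$variant_id <- paste(variants$chrom, variants$pos, variants$ref,
                               variants$alt, sep = ":")
  colnames(geno) <- variants$variant_id

  ## ---- truth table (pre-corruption allele counts) ----
  truth <- data.frame(
    variant_id = variants$variant_id,
    gene_id = variants$gene,
    f_main = variants$f_main,
    f_sub = variants$f_sub,
    csqcat = variants$csqcat,
    polyphen = variants$polyphen,
    sift = variants$sift,
    is_risk = variants$is_risk,
    is_singleton = variants$true_singleton,
    carrier = variants$carrier,
    ac_case = colSums(geno[status == "case", , drop = FALSE]),
    ac_control = colSums(geno[status == "control", , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)

  ## ---- quality corruption ----
  qm <- spec$quality_model
  nelem <- length(geno)
  miss <- stats::runif(nelem) < qm$missing_rate
  low <- stats::runif(nelem) < qm$low_gq_rate
  gq <- matrix(ifelse(low,
                      sample(10:29, nelem, replace = TRUE),
                      sample(30:99, nelem, replace = TRUE)),
               nrow(geno), ncol(geno), dimnames = dimnames(geno))
  geno[miss] <- NA_integer_
  gq[miss] <- NA_integer_
  filter <- ifelse(stats::runif(nrow(variants)) < qm$site_fail_rate,
                   "q10", "PASS")

  vtab <- data.frame(
    variant_id = variants$variant_id,
    chrom = variants$chrom,
    pos = variants$pos,
    ref = variants$ref,
    alt = variants$alt,
    filter = filter,
    csqcat = variants$csqcat,
    polyphen = variants$polyphen,
    sift = variants$sift,
    in_ref = variants$in_ref,
    af_popa = variants$f_main,
    af_popb = variants$f_sub,
    stringsAsFactors = FALSE)
  vtab$genes <- as.list(variants$gene)

  cohort <- burden_cohort(genotype_matrix(geno, status, gq), vtab,
                          gene_map = gene_map)
  cohort$truth <- truth
  cohort$subjects <- data.frame(sample_id = sample_ids, status = status,
                                subpop = subpop, stringsAsFactors = FALSE)
  cohort$gene_sets <- make_synthetic_sets(spec)
  cohort$spec <- spec
  cohort
}

#' Simulate a cohort and write it to standard files
#'
#' Runs [simulate_cohort_data()] and writes the cohort as a VCF 4.2 file
#' (GT:GQ genotypes, annotations as INFO keys `CSQCAT`, `PPH`, `SIFTC`,
#' `INREF`, `AF_POPA`, `AF_POPB`), a phenotype TSV, a gene-map TSV, a GMT
#' gene-set file and a ground-truth TSV. Identical spec and seed reproduce
#' byte-identical files.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return List with elements `vcf`, `phenotype`, `gene_map`, `gene_sets`,
#'   `truth_table` (paths) and `truth` (the truth data frame).
#' @export
simulate_cohort <- function(spec, dir, prefix = "cohort") {
  cohort <- simulate_cohort_data(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    phenotype = file.path(dir, paste0(prefix, "_phenotype.tsv")),
    gene_map = file.path(dir, paste0(prefix, "_gene_map.tsv")),
    gene_sets = file.path(dir, paste0(prefix, "_sets.gmt")),
    truth_table = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_cohort_vcf(cohort, paths$vcf)
  utils::write.table(
    data.frame(sample_id = cohort$subjects$sample_id,
               status = cohort$subjects$status),
    paths$phenotype, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$gene_map, paths$gene_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(vapply(names(cohort$gene_sets), function(nm) {
    paste(c(nm, "synthetic", cohort$gene_sets[[nm]]), collapse = "\t")
  }, ""), paths$gene_sets)
  utils::write.table(cohort$truth, paths$truth_table, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  c(paths, list(truth = cohort$truth))
}

#' Generate a cohort with injected population stratification
#'
#' Validates that `spec` actually encodes a confounded design -- the
#' subpopulation fractions differ between cases and controls and the
#' subpopulation's singleton rate differs from the main population's -- and
#' generates the cohort. Such a cohort shows a different per-subject
#' singleton count in the subpopulation and an unequal subpopulation mixture
#' between cohorts, which masks (or reverses) a programmed dURV enrichment
#' when the enrichment regression is run without covariates.
#'
#' @param spec A [cohort_spec()] with confounding parameters set.
#' @return A [burden_cohort()], as from [simulate_cohort_data()].
#' @export
inject_stratification <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$subpop_fraction_cases == spec$subpop_fraction_controls)
    stop("inject_stratification: subpopulation fractions must differ ",
         "between cases and controls", call. = FALSE)
  if (spec$subpop_singleton_rate == spec$singleton_rate)
    stop("inject_stratification: subpopulation singleton rate must differ ",
         "from the main population's", call. = FALSE)
  simulate_cohort_data(spec)
}

## ---- internal helpers -----------------------------------------------------

## Beta(a, b) truncated to (0, ceiling]; rejection sampling.
draw_truncated_beta <- function(n, shape, ceiling) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    f <- stats::rbeta(length(todo), shape[1], shape[2])
    ok <- f > 0 & f <= ceiling
    out[todo[ok]] <- f[ok]
    todo <- todo[!ok]
  }
  out
}

POLYPHEN_DAMAGING <- c("possibly_damaging", "probably_damaging")

## consequence + PolyPhen/SIFT draws; non-missense sites are 'unknown'
draw_annotations <- function(n, spec) {
  cp <- spec$consequence_probs
  csq <- sample(names(cp), n, replace = TRUE, prob = cp)
  polyphen <- rep("unknown", n)
  sift <- rep("unknown", n)
  mis <- which(csq == "missense")
  if (length(mis)) {
    polyphen[mis] <- sample(names(spec$polyphen_probs), length(mis),
                            replace = TRUE, prob = spec$polyphen_probs)
    sift[mis] <- sample(names(spec$sift_probs), length(mis),
                        replace = TRUE, prob = spec$sift_probs)
  }
  list(csqcat = csq, polyphen = polyphen, sift = sift)
}

## Fill case/control quotas for one subpopulation by drawing HWE genotypes
## and assigning status under the logistic disease model. When no variant
## carries an effect the label is independent of the genotypes and quotas
## are filled directly.
sample_disease_group <- function(n_case, n_ctrl, freqs, beta, alpha,
                                 max_rounds = 60L) {
  nv <- length(freqs)
  draw <- function(m) {
    g <- matrix(0L, m, nv)
    for (j in seq_len(nv)) g[, j] <- stats::rbinom(m, 2L, freqs[j])
    g
  }
  if (n_case + n_ctrl == 0)
    return(list(case = matrix(0L, 0, nv), control = matrix(0L, 0, nv)))
  ridx <- which(beta > 0)
  if (!length(ridx)) {
    g <- draw(n_case + n_ctrl)
    return(list(case = g[seq_len(n_case), , drop = FALSE],
                control = g[n_case + seq_len(n_ctrl), , drop = FALSE]))
  }
  cases <- list(); ctrls <- list()
  got_case <- 0L; got_ctrl <- 0L
  p_case <- stats::plogis(alpha)
  for (round in seq_len(max_rounds)) {
    need_c <- n_case - got_case; need_k <- n_ctrl - got_ctrl
    if (need_c <= 0 && need_k <= 0) break
    m <- as.integer(ceiling(max(need_c / p_case, need_k / (1 - p_case)) *
                              1.15) + 20L)
    g <- draw(m)
    eta <- alpha + as.vector(g[, ridx, drop = FALSE] %*% beta[ridx])
    pc <- stats::plogis(eta)
    if (any(pc <= 0 | pc >= 1))
      stop("simulate_cohort: effect scale drives case probability to the ",
           "boundary of (0, 1); reduce effect_scale", call. = FALSE)
    is_case <- stats::runif(m) < pc
    take_c <- which(is_case)[seq_len(min(need_c, sum(is_case)))]
    take_k <- which(!is_case)[seq_len(min(need_k, sum(!is_case)))]
    if (length(take_c)) cases[[length(cases) + 1L]] <-
        g[take_c, , drop = FALSE]
    if (length(take_k)) ctrls[[length(ctrls) + 1L]] <-
        g[take_k, , drop = FALSE]
    got_case <- got_case + length(take_c)
    got_ctrl <- got_ctrl + length(take_k)
  }
  if (got_case < n_case || got_ctrl < n_ctrl)
    stop("simulate_cohort: could not fill cohort quotas under the disease ",
         "model", call. = FALSE)
  list(case = do.call(rbind, c(cases, list(matrix(0L, 0, nv)))),
       control = do.call(rbind, c(ctrls, list(matrix(0L, 0, nv)))))
}

## Per-subject Poisson singleton counts, split into damaging and benign
## streams so a case excess of damaging singletons can be programmed.
place_singletons <- function(spec, status, subpop) {
  n <- length(status)
  cp <- spec$consequence_probs
  dmg <- damaging_config()
  p_pph_dmg <- sum(spec$polyphen_probs[POLYPHEN_DAMAGING], na.rm = TRUE)
  p_sift_dmg <- unname(spec$sift_probs["deleterious"])
  if (is.na(p_sift_dmg)) p_sift_dmg <- 0
  p_mis_dmg <- 1 - (1 - p_pph_dmg) * (1 - p_sift_dmg)
  lof_p <- cp[names(cp) %in% dmg$lof_categories]
  p_mis <- if ("missense" %in% names(cp)) cp[["missense"]] else 0
  d_mass <- sum(lof_p) + p_mis * p_mis_dmg

  rate <- ifelse(subpop, spec$subpop_singleton_rate, spec$singleton_rate)
  excess <- ifelse(status == "case", spec$durv_case_excess, 1)
  n_dmg <- stats::rpois(n, rate * d_mass * excess)
  n_ben <- stats::rpois(n, rate * (1 - d_mass))

  carrier <- c(rep(seq_len(n), n_dmg), rep(seq_len(n), n_ben))
  m_d <- sum(n_dmg); m_b <- sum(n_ben)

  ## damaging stream: LOF categories, or missense conditioned on a damaging
  ## PolyPhen/SIFT pair (drawn by rejection from the unconditional law)
  d_cats <- c(names(lof_p), "missense")
  d_prob <- c(lof_p, p_mis * p_mis_dmg)
  csq_d <- if (m_d) sample(d_cats, m_d, replace = TRUE, prob = d_prob)
           else character(0)
  pph_d <- rep("unknown", m_d); sift_d <- rep("unknown", m_d)
  mis_d <- which(csq_d == "missense")
  while (length(mis_d)) {
    pph_d[mis_d] <- sample(names(spec$polyphen_probs), length(mis_d),
                           replace = TRUE, prob = spec$polyphen_probs)
    sift_d[mis_d] <- sample(names(spec$sift_probs), length(mis_d),
                            replace = TRUE, prob = spec$sift_probs)
    mis_d <- mis_d[!(pph_d[mis_d] %in% POLYPHEN_DAMAGING |
                       sift_d[mis_d] == "deleterious")]
  }

  ## benign stream: everything else; benign missense gets the one
  ## non-damaging annotation pair
  b_cats <- setdiff(names(cp), dmg$lof_categories)
  b_prob <- cp[b_cats]
  if ("missense" %in% b_cats)
    b_prob["missense"] <- p_mis * (1 - p_mis_dmg)
  csq_b <- if (m_b) sample(b_cats, m_b, replace = TRUE, prob = b_prob)
           else character(0)
  pph_b <- ifelse(csq_b == "missense", "benign", "unknown")
  sift_b <- ifelse(csq_b == "missense", "tolerated", "unknown")

  gene <- sample(spec$gene_ids, m_d + m_b, replace = TRUE)
  list(gene = gene, carrier = carrier,
       csqcat = c(csq_d, csq_b),
       polyphen = c(pph_d, pph_b),
       sift = c(sift_d, sift_b))
}

## unique positions within each gene's interval
assign_positions <- function(gene, gene_map) {
  pos <- integer(length(gene))
  idx <- split(seq_along(gene), gene)
  for (g in names(idx)) {
    row <- match(g, gene_map$gene_id)
    k <- length(idx[[g]])
    span <- gene_map$end[row] - gene_map$start[row] + 1L
    if (k > span)
      stop("simulate_cohort: more variants than positions in gene ", g,
           call. = FALSE)
    pos[idx[[g]]] <- gene_map$start[row] +
      sample.int(span, k, replace = FALSE) - 1L
  }
  pos
}

make_synthetic_sets <- function(spec, n_sets = 20L) {
  size <- max(2L, min(30L, spec$n_genes))
  sets <- lapply(seq_len(min(n_sets, spec$n_genes)), function(i) {
    sort(sample(spec$gene_ids, min(size, spec$n_genes)))
  })
  names(sets) <- sprintf("random_set_%02d", seq_along(sets))
  if (length(spec$risk_genes))
    sets <- c(list(risk_set = spec$risk_genes), sets)
  sets
}

## plain-text VCF 4.2 emission; deterministic given the cohort
write_cohort_vcf <- function(cohort, path) {
  gm <- cohort$geno
  v <- cohort$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=slpburden_synthetic_cohort",
    "##contig=<ID=1>",
    "##FILTER=<ID=q10,Description=\"Synthetic low-quality site\">",
    "##INFO=<ID=CSQCAT,Number=1,Type=String,Description=\"Consequence category\">",
    "##INFO=<ID=PPH,Number=1,Type=String,Description=\"PolyPhen class\">",
    "##INFO=<ID=SIFTC,Number=1,Type=String,Description=\"SIFT class\">",
    "##INFO=<ID=INREF,Number=1,Type=Integer,Description=\"Present in external reference panel\">",
    "##INFO=<ID=AF_POPA,Number=1,Type=Float,Description=\"Reference frequency, population A\">",
    "##INFO=<ID=AF_POPB,Number=1,Type=Float,Description=\"Reference frequency, population B\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$geno)), collapse = "\t"))
  info <- paste0(
    "CSQCAT=", v$csqcat,
    ifelse(v$polyphen == "unknown", "", paste0(";PPH=", v$polyphen)),
    ifelse(v$sift == "unknown", "", paste0(";SIFTC=", v$sift)),
    ";INREF=", as.integer(v$in_ref),
    ifelse(is.na(v$af_popa), "",
           paste0(";AF_POPA=", sprintf("%.6g", v$af_popa))),
    ifelse(is.na(v$af_popb), "",
           paste0(";AF_POPB=", sprintf("%.6g", v$af_popb))))
  g <- gm$geno
  codes <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  codes[is.na(g)] <- "./."
  gqs <- matrix(as.character(gm$gq), nrow(g), ncol(g))
  gqs[is.na(gm$gq)] <- "."
  fields <- matrix(paste0(codes, ":", gqs), nrow(g), ncol(g))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i], ".",
            v$filter[i], info[i], "GT:GQ", fields[, i]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
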