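#' Load a cohort from VCF, phenotype and gene-map files
#'
#' Reads a multi-sample VCF 4.2 (via vcfR), a phenotype TSV and a gene
#' interval map, and assembles the [burden_cohort()] the pipeline operates
#' on. Multi-allelic records are split into one variant per alternate
#' allele, with the other alternate alleles treated as reference for that
#' allele's dosage. Variants are assigned to every gene whose interval
#' overlaps their position (1-based inclusive on both sides); variants
#' overlapping no gene are retained with an empty gene list. If the gene map
#' carries a non-empty `alias_group` column the member genes are merged
#' under the group label (see [merge_gene_aliases()]), as done for the
#' protocadherin-gamma cluster.
#'
#' Annotations are consumed from the INFO keys `CSQCAT` (consequence
#' category), `PPH` (PolyPhen class), `SIFTC` (SIFT class), `INREF`
#' (reference-panel membership, 0/1) and `AF_POPA` / `AF_POPB`
#' (per-population reference frequencies). Missing annotation keys default
#' to class `unknown`, never to a damaging class.
#'
#' @param vcf_path Path to the VCF (plain or gzipped).
#' @param phenotype_path TSV with columns `sample_id` and `status`
#'   (`case` / `control`). Every VCF sample must appear.
#' @param gene_map_path TSV with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `alias_group`; 1-based inclusive coordinates.
#' @param apply_aliases Merge `alias_group` members (default `TRUE`).
#' @return A [burden_cohort()].
#' @export
load_cohort <- function(vcf_path, phenotype_path, gene_map_path,
                        apply_aliases = TRUE) {
  phen <- read_phenotypes(phenotype_path)
  gene_map <- load_gene_map(gene_map_path)

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("load_cohort: VCF contains no records",
                           call. = FALSE)
  fix$POS <- as.integer(fix$POS)
  if (anyNA(fix$POS) || any(fix$POS < 1))
    stop("load_cohort: malformed POS at VCF record ",
         which(is.na(fix$POS) | fix$POS < 1)[1], call. = FALSE)
  samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(samples, phen$sample_id)
  if (length(missing_samples))
    stop("load_cohort: sample(s) absent from phenotype file: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  status <- phen$status[match(samples, phen$sample_id)]

  gt <- vcfR::extract.gt(v, "GT")
  gq <- if ("GQ" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID)
    suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE)) else NULL
  gt <- gsub("|", "/", gt, fixed = TRUE)
  a1 <- sub("/.*", "", gt)
  a2 <- sub(".*/", "", gt)
  miss <- is.na(gt) | a1 == "." | a2 == "."

  info_key <- function(key) vcfR::extract.info(v, element = key)
  csq <- info_key("CSQCAT")
  pph <- info_key("PPH")
  sif <- info_key("SIFTC")
  inref <- info_key("INREF")
  af_a <- suppressWarnings(as.numeric(info_key("AF_POPA")))
  af_b <- suppressWarnings(as.numeric(info_key("AF_POPB")))

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  rec <- rep(seq_len(nrow(fix)), lengths(alt_list))
  allele <- as.character(sequence(lengths(alt_list)))

  n_out <- length(rec)
  geno <- matrix(NA_integer_, length(samples), n_out)
  for (k in seq_len(n_out)) {
    i <- rec[k]
    d <- (a1[i, ] == allele[k]) + (a2[i, ] == allele[k])
    d[miss[i, ]] <- NA_integer_
    geno[, k] <- as.integer(d)
  }
  rownames(geno) <- samples
  gq_out <- if (is.null(gq)) NULL else t(gq[rec, , drop = FALSE])

  fill <- function(x, default) ifelse(is.na(x) | x == "", default, x)
  variants <- data.frame(
    chrom = fix$CHROM[rec],
    pos = fix$POS[rec],
    ref = fix$REF[rec],
    alt = unlist(alt_list),
    filter = fill(fix$FILTER[rec], "."),
    csqcat = fill(csq[rec], "unknown"),
    polyphen = fill(pph[rec], "unknown"),
    sift = fill(sif[rec], "unknown"),
    in_ref = fill(inref[rec], "0") == "1",
    af_popa = af_a[rec],
    af_popb = af_b[rec],
    stringsAsFactors = FALSE)
  variants$variant_id <- make.unique(
    paste(variants$chrom, variants$pos, variants$ref, variants$alt,
          sep = ":"))
  colnames(geno) <- variants$variant_id
  if (!is.null(gq_out)) dimnames(gq_out) <- dimnames(geno)

  variants$genes <- assign_genes(variants, gene_map)
  if (apply_aliases && "alias_group" %in% names(gene_map)) {
    grp <- gene_map[!is.na(gene_map$alias_group) &
                      gene_map$alias_group != "", , drop = FALSE]
    if (nrow(grp))
      variants <- merge_gene_aliases(
        variants, data.frame(member = grp$gene_id, merged = grp$alias_group,
                             stringsAsFactors = FALSE))
  }
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                           "filter", "csqcat", "polyphen", "sift", "in_ref",
                           "af_popa", "af_popb", "genes")]
  burden_cohort(genotype_matrix(geno, status, gq_out), variants,
                gene_map = gene_map)
}

#' Read a phenotype file
#'
#' @param path TSV with columns `sample_id` and `status`; every status must
#'   be `case` or `control` and both labels must occur.
#' @return Data frame with columns `sample_id`, `status`.
#' @export
read_phenotypes <- function(path) {
  phen <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(phen)))
    stop("phenotype file needs columns 'sample_id' and 'status'",
         call. = FALSE)
  bad <- setdiff(unique(phen$status), c("case", "control"))
  if (length(bad))
    stop("phenotype file has unknown status label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(phen$sample_id))
    stop("phenotype file has duplicate sample ids", call. = FALSE)
  if (!all(c("case", "control") %in% phen$status))
    stop("phenotype file must contain both cases and controls",
         call. = FALSE)
  phen[, c("sample_id", "status")]
}

#' Read a gene interval map
#'
#' @param path TSV with columns `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `alias_group`.
#' @return Data frame of gene intervals.
#' @export
load_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(gm)))
    stop("gene map needs columns gene_id, chrom, start, end", call. = FALSE)
  if (nrow(gm) == 0) stop("gene map is empty", call. = FALSE)
  if (any(gm$start < 1) || any(gm$end < gm$start))
    stop("gene map has invalid intervals", call. = FALSE)
  gm
}

#' Assign variants to overlapping gene intervals
#'
#' A variant is assigned to every gene whose (1-based, inclusive) interval
#' on the same chromosome contains its position.
#'
#' @param variants Data frame with columns `chrom`, `pos`.
#' @param gene_map Data frame of gene intervals.
#' @return List-column: character vector of gene ids per variant (possibly
#'   empty).
#' @export
assign_genes <- function(variants, gene_map) {
  vr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  gr <- GenomicRanges::GRanges(
    seqnames = gene_map$chrom,
    ranges = IRanges::IRanges(start = gene_map$start, end = gene_map$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, gr))
  genes <- split(gene_map$gene_id[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_len(nrow(variants))))
  unname(lapply(genes, function(g) unique(as.character(g))))
}

#' Merge gene aliases into a single gene label
#'
#' Replaces every member gene id in each variant's gene list by its merged
#' label and collapses duplicates, so a variant counts exactly once per
#' merged gene. This reproduces the treatment of RefSeq gene clusters whose
#' transcripts overlap (e.g. the protocadherin-gamma cluster analysed under
#' a single label).
#'
#' @param variants Data frame with list-column `genes`.
#' @param alias_map Data frame with columns `member`, `merged`.
#' @return `variants` with merged gene ids.
#' @export
merge_gene_aliases <- function(variants, alias_map) {
  if (nrow(alias_map) == 0) return(variants)
  if (!all(c("member", "merged") %in% names(alias_map)))
    stop("alias map needs columns 'member' and 'merged'", call. = FALSE)
  dup <- unique(alias_map$member[duplicated(alias_map$member)])
  conflicting <- vapply(dup, function(m) {
    length(unique(alias_map$merged[alias_map$member == m])) > 1
  }, logical(1))
  if (any(conflicting))
    stop("alias map maps member to two merged ids: ",
         paste(dup[conflicting], collapse = ", "), call. = FALSE)
  cyc <- alias_map$merged %in% alias_map$member &
    alias_map$merged != alias_map$member
  if (any(cyc))
    stop("alias map contains a cycle through: ",
         paste(unique(alias_map$merged[cyc]), collapse = ", "),
         call. = FALSE)
  lut <- stats::setNames(alias_map$merged, alias_map$member)
  variants$genes <- lapply(variants$genes, function(g) {
    hit <- g %in% names(lut)
    g[hit] <- lut[g[hit]]
    unique(g)
  })
  variants
}

#' Load gene sets from a GMT file
#'
#' GMT format: one set per line, tab-separated fields `name`, `description`,
#' then member gene ids. Gzipped files are read transparently. When a gene
#' `universe` is supplied, members outside it are retained but flagged and
#' the matched count per set is recorded.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector of analysed gene ids.
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   vectors), `matched` (matched gene count per set, `NA` without a
#'   universe), `in_universe` (per-set logical vectors, or `NULL`) and
#'   `provenance` (the source path).
#' @export
load_gene_sets <- function(path, universe = NULL) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stop("load_gene_sets: file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("load_gene_sets: fewer than 3 fields at line ", short[1],
         call. = FALSE)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("load_gene_sets: duplicate set name: ",
         nms[duplicated(nms)][1], call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  matched <- rep(NA_integer_, length(sets))
  names(matched) <- nms
  in_universe <- NULL
  if (!is.null(universe)) {
    in_universe <- lapply(sets, function(g) g %in% universe)
    matched <- vapply(in_universe, sum, integer(1))
  }
  structure(list(sets = sets, matched = matched, in_universe = in_universe,
                 provenance = path),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets from", x$provenance,
      "\n")
  if (!all(is.na(x$matched)))
    cat("  matched genes per set: median",
        stats::median(x$matched), "\n")
  invisible(x)
}
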