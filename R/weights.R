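#' Construct a functional weight table
#'
#' Maps each consequence category to a non-negative base weight and carries
#' the annotation increments: a PolyPhen increment added for classes
#' `possibly_damaging` / `probably_damaging` and a SIFT increment added for
#' class `deleterious` (both default 10). An optional rarity multiplier flag
#' is carried for completeness; it defaults to off because under the MAF
#' ceiling rarity weighting has negligible effect.
#'
#' @param base Named numeric vector, consequence category -> base weight.
#' @param polyphen_increment,sift_increment Non-negative increments.
#' @param rarity_weighting Logical flag; when off the rarity multiplier is 1.
#' @return An object of class `weight_table`.
#' @export
weight_table <- function(base,
                         polyphen_increment = 10,
                         sift_increment = 10,
                         rarity_weighting = FALSE) {
  if (is.null(names(base)) || any(names(base) == ""))
    stop("weight_table: base weights must be named by category", call. = FALSE)
  if (anyDuplicated(names(base)))
    stop("weight_table: duplicate category: ",
         names(base)[duplicated(names(base))][1], call. = FALSE)
  if (any(base < 0) || polyphen_increment < 0 || sift_increment < 0)
    stop("weight_table: weights must be non-negative", call. = FALSE)
  structure(list(base = base,
                 polyphen_increment = polyphen_increment,
                 sift_increment = sift_increment,
                 rarity_weighting = isTRUE(rarity_weighting)),
            class = "weight_table")
}

#' Default functional weight table
#'
#' A severity-ordered ladder over VEP-style consequence categories, anchored
#' at 5 for synonymous and 20 for stop-gained variants, with +10 increments
#' for damaging PolyPhen and deleterious SIFT annotations. Every value can be
#' overridden via [weight_table()] or [load_weight_table()].
#'
#' @return A `weight_table`.
#' @export
default_weight_table <- function() {
  weight_table(c(intergenic = 0,
                 intronic = 1,
                 five_prime_utr = 3,
                 three_prime_utr = 3,
                 synonymous = 5,
                 splice_region = 10,
                 inframe_indel = 10,
                 missense = 10,
                 splice_donor = 20,
                 splice_acceptor = 20,
                 frameshift = 20,
                 stop_lost = 20,
                 start_lost = 20,
                 stop_gained = 20))
}

#' @export
print.weight_table <- function(x, ...) {
  cat("weight_table:", length(x$base), "categories;",
      "PolyPhen +", x$polyphen_increment, "; SIFT +", x$sift_increment,
      "; rarity weighting", if (x$rarity_weighting) "on" else "off", "\n")
  b <- sort(x$base)
  cat(paste0("  ", names(b), " = ", b, collapse = "\n"), "\n")
  invisible(x)
}

#' Weight variants from their consequence and annotations
#'
#' Each variant's weight is the base weight of its consequence category,
#' plus the PolyPhen increment if its PolyPhen class is possibly or probably
#' damaging, plus the SIFT increment if its SIFT class is deleterious.
#' Weight is a pure function of (category, PolyPhen class, SIFT class,
#' table); `unknown` annotation classes never add an increment.
#'
#' @param variants Data frame with columns `csqcat`, `polyphen`, `sift` (a
#'   single variant row works too).
#' @param table A [weight_table()].
#' @return Numeric vector of non-negative weights, one per row.
#' @export
weight_variants <- function(variants, table = default_weight_table()) {
  stopifnot(inherits(table, "weight_table"))
  unknown <- setdiff(unique(variants$csqcat), names(table$base))
  if (length(unknown))
    stop("weight_variants: consequence category not in weight table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  unname(table$base[variants$csqcat]) +
    table$polyphen_increment * (variants$polyphen %in% POLYPHEN_DAMAGING) +
    table$sift_increment * (variants$sift == "deleterious")
}

#' Read a weight table from a two-column TSV
#'
#' The file has a header row `category<TAB>weight` followed by one row per
#' consequence category. Two reserved category names configure the
#' increments: `polyphen_increment` and `sift_increment` (defaults 10 when
#' omitted). A `rarity_weighting` row with weight 1 switches the rarity flag
#' on. Gzipped files are read transparently.
#'
#' @param path Path to the TSV.
#' @return A [weight_table()].
#' @export
load_weight_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("category", "weight") %in% names(tab)))
    stop("load_weight_table: need columns 'category' and 'weight'",
         call. = FALSE)
  if (anyDuplicated(tab$category))
    stop("load_weight_table: duplicate category: ",
         tab$category[duplicated(tab$category)][1], call. = FALSE)
  if (any(!is.finite(tab$weight)) || any(tab$weight < 0))
    stop("load_weight_table: weights must be non-negative numbers",
         call. = FALSE)
  special <- c("polyphen_increment", "sift_increment", "rarity_weighting")
  opts <- tab[tab$category %in% special, , drop = FALSE]
  base <- tab[!tab$category %in% special, , drop = FALSE]
  if (nrow(base) == 0)
    stop("load_weight_table: no consequence categories in file",
         call. = FALSE)
  get_opt <- function(key, default) {
    i <- match(key, opts$category)
    if (is.na(i)) default else opts$weight[i]
  }
  weight_table(stats::setNames(base$weight, base$category),
               polyphen_increment = get_opt("polyphen_increment", 10),
               sift_increment = get_opt("sift_increment", 10),
               rarity_weighting = get_opt("rarity_weighting", 0) != 0)
}
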