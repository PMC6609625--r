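#' Per-category union gene sets
#'
#' For one categorical dimension (milk fraction or lactation stage), pools
#' each category's datasets and deduplicates: a gene identified more than
#' once within a category is kept once. The sum of the resulting set sizes
#' is the per-dimension unique-gene total.
#'
#' @param atlas A `milk_atlas` whose manifest has the dimension column
#'   filled for every dataset.
#' @param dimension Manifest column to group by, typically
#'   `"fraction_class"` or `"stage_class"`.
#' @param categories Optional declared category levels; declared categories
#'   with no datasets yield an empty set with a warning. Defaults to the
#'   levels observed in the manifest.
#' @return Named list of character vectors (sorted gene names), one per
#'   category, in lexicographic category order.
#' @export
category_union_sets <- function(atlas, dimension = c("fraction_class", "stage_class"),
                                categories = NULL) {
  stopifnot(inherits(atlas, "milk_atlas"))
  dimension <- if (length(dimension) > 1L) match.arg(dimension) else dimension
  if (!dimension %in% names(atlas$manifest)) {
    abort(sprintf("manifest has no column '%s'", dimension))
  }
  cls <- atlas$manifest[[dimension]]
  if (anyNA(cls)) {
    abort(sprintf("all datasets must be classified on '%s' (found NA)", dimension))
  }
  categories <- categories %||% unique(cls)
  empty <- setdiff(categories, cls)
  if (length(empty) > 0L) {
    warn(sprintf("no datasets in declared categor%s: %s",
                 if (length(empty) > 1) "ies" else "y", paste(empty, collapse = ", ")))
  }
  lut <- setNames(cls, atlas$manifest$dataset_id)
  sets <- lapply(setNames(nm = sort(categories)), function(cat) {
    ds <- names(lut)[lut == cat]
    sort(unique(atlas$records$gene_name[atlas$records$dataset_id %in% ds]))
  })
  sets
}

signature_key <- function(categories) paste(sort(categories), collapse = "&")

#' Decompose category sets into exact Venn regions
#'
#' Assigns every element of the union to the region given by its exact
#' membership signature (the subset of categories whose sets contain it),
#' producing the full 2^k - 1 decomposition that underlies an
#' all-or-nothing (presence/absence) comparison. Signatures are
#' canonicalized by lexicographic category order, joined with `"&"`.
#'
#' @param category_sets Named list (1-6 categories) of character vectors.
#'   For more than 6 categories use [membership_table()].
#' @param dimension Label recorded on the partition (e.g.
#'   `"fraction_class"`); `"custom"` by default.
#' @return A `category_partition`: list with `dimension`, `category_sets`
#'   (deduplicated, sorted), and `regions` (named list keyed by signature;
#'   all 2^k - 1 signatures present, possibly empty).
#' @export
#' @examples
#' p <- venn_regions(list(skimmed = c("A", "B"), MFGM = c("B", "C")))
#' p$regions[["skimmed"]]        # "A"
#' p$regions[["MFGM&skimmed"]]   # "B"
venn_regions <- function(category_sets, dimension = "custom") {
  k <- length(category_sets)
  if (k == 0L) abort("at least one category set is required")
  if (k > 6L) abort("more than 6 categories: use membership_table() for an UpSet-style report")
  if (is.null(names(category_sets)) || any(!nzchar(names(category_sets))) ||
      anyDuplicated(names(category_sets))) {
    abort("category_sets must have unique non-empty names")
  }
  cats <- sort(names(category_sets))
  sets <- lapply(category_sets[cats], function(s) sort(unique(as.character(s))))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  # membership signature per element of the union
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1, dimnames = list(NULL, cats))
  sig <- apply(member, 1L, function(row) signature_key(cats[row]))
  all_sigs <- unlist(lapply(seq_len(2^k - 1L), function(i) {
    signature_key(cats[as.logical(intToBits(i)[seq_len(k)])])
  }))
  regions <- lapply(setNames(nm = all_sigs), function(s) {
    if (length(universe) == 0L) character() else sort(universe[sig == s])
  })
  partition <- structure(
    list(dimension = dimension, category_sets = sets, regions = regions),
    class = "category_partition"
  )
  validate_partition(partition)
}

validate_partition <- function(partition) {
  regions <- partition$regions
  universe <- sort(unique(unlist(partition$category_sets, use.names = FALSE)))
  pooled <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(pooled) || !setequal(pooled, universe) ||
      sum(lengths(regions)) != length(universe)) {
    abort("partition invariant violated: regions are not a disjoint cover of the union")
  }
  for (cat in names(partition$category_sets)) {
    in_cat <- unlist(regions[vapply(strsplit(names(regions), "&", fixed = TRUE),
                                    function(s) cat %in% s, logical(1))],
                     use.names = FALSE)
    if (!setequal(in_cat, partition$category_sets[[cat]])) {
      abort(sprintf("partition invariant violated for category '%s'", cat))
    }
  }
  partition
}

#' @export
print.category_partition <- function(x, ...) {
  cat(sprintf("<category_partition> dimension: %s | %d categories | %d elements\n",
              x$dimension, length(x$category_sets),
              sum(lengths(x$regions))))
  print(region_counts(x), n = Inf)
  invisible(x)
}

#' Region counts of a partition
#'
#' Counts-only summary mirroring a Venn-diagram legend.
#'
#' @param partition A `category_partition`.
#' @return Tibble with `signature`, `n_categories`, `n`, ordered by
#'   signature breadth then name.
#' @export
region_counts <- function(partition) {
  stopifnot(inherits(partition, "category_partition"))
  sig <- names(partition$regions)
  out <- tibble(
    signature = sig,
    n_categories = lengths(strsplit(sig, "&", fixed = TRUE)),
    n = lengths(partition$regions)
  )
  out[order(out$n_categories, out$signature), ]
}

#' Genes exclusive to one category
#'
#' The region whose membership signature is exactly the given category —
#' genes detected in that category and in no other, the candidates of an
#' all-or-nothing biomarker screen.
#'
#' @param partition A `category_partition`.
#' @param category Category name (must be present in the partition).
#' @return Sorted character vector of gene names.
#' @export
exclusive_to <- function(partition, category) {
  stopifnot(inherits(partition, "category_partition"))
  if (!category %in% names(partition$category_sets)) {
    abort(sprintf("unknown category '%s'", category))
  }
  sort(partition$regions[[category]])
}

#' UpSet-style membership table
#'
#' Long-form membership report for any number of category sets: one row per
#' element of the union, with its signature and per-category membership
#' flags. Used in place of named Venn regions when there are more than six
#' categories.
#'
#' @param category_sets Named list of character vectors.
#' @return Tibble with `gene_name`, `signature`, `n_categories`, and one
#'   logical column per category.
#' @export
membership_table <- function(category_sets) {
  if (length(category_sets) == 0L) abort("at least one category set is required")
  cats <- sort(names(category_sets))
  sets <- lapply(category_sets[cats], unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  flags <- lapply(sets, function(s) universe %in% s)
  sig <- vapply(seq_along(universe), function(i) {
    signature_key(cats[vapply(flags, `[`, logical(1), i)])
  }, character(1))
  dplyr::bind_cols(
    tibble(gene_name = universe, signature = sig,
           n_categories = lengths(strsplit(sig, "&", fixed = TRUE))),
    as_tibble(setNames(flags, cats))
  )
}
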