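#' Lactation-stage rule set
#'
#' Stage boundaries in days in milk (DIM). Defaults follow the usual
#' physiological windows: colostrum during the first 5 days post-partum,
#' early lactation 6-21 DIM (the classic window of negative energy
#' balance), peak lactation 22-80 DIM, and mid (post-peak) lactation from
#' 81 DIM onward. The intervals must be disjoint, ordered and jointly tile
#' the non-negative integers so every DIM has exactly one stage.
#'
#' @param colostrum_max_dim Last DIM of the colostrum period (default 5).
#' @param early_range Inclusive DIM interval for early lactation (default `c(6, 21)`).
#' @param peak_range Inclusive DIM interval for peak lactation (default `c(22, 80)`).
#' @param mid_min_dim First DIM of mid-lactation (default 81; open-ended above).
#' @return A `stage_rules` list.
#' @export
stage_rules <- function(colostrum_max_dim = 5L,
                        early_range = c(6L, 21L),
                        peak_range = c(22L, 80L),
                        mid_min_dim = 81L) {
  ok <- colostrum_max_dim >= 0 &&
    early_range[1] == colostrum_max_dim + 1L &&
    early_range[2] >= early_range[1] &&
    peak_range[1] == early_range[2] + 1L &&
    peak_range[2] >= peak_range[1] &&
    mid_min_dim == peak_range[2] + 1L
  if (!ok) {
    abort("stage intervals must be disjoint, ordered, and jointly cover all non-negative DIM")
  }
  structure(
    list(colostrum_max_dim = as.integer(colostrum_max_dim),
         early_range = as.integer(early_range),
         peak_range = as.integer(peak_range),
         mid_min_dim = as.integer(mid_min_dim)),
    class = "stage_rules"
  )
}

#' The five lactation-stage classes
#' @return Character vector of stage labels in chronological order.
#' @export
stage_levels <- function() c("colostrum", "early", "peak", "mid", "drying_off")

#' The four milk-fraction classes
#' @return Character vector of fraction labels.
#' @export
fraction_levels <- function() c("skimmed", "whey", "MFGM", "exosomes")

#' Classify a dataset's lactation stage
#'
#' Milk collected after regular milking stopped is `drying_off` regardless
#' of day; otherwise the DIM is mapped through the stage intervals. Exactly
#' one of `dim` / `dryoff_day` must be present.
#'
#' @param dim Days in milk (single non-negative integer), or `NA`.
#' @param dryoff_day Days after milking cessation (single non-negative
#'   integer), or `NA`.
#' @param rules A [stage_rules()] object.
#' @return One of [stage_levels()].
#' @export
#' @examples
#' classify_stage(dim = 3)            # colostrum
#' classify_stage(dim = 10)           # early
#' classify_stage(dryoff_day = 3)     # drying_off
classify_stage <- function(dim = NA_integer_, dryoff_day = NA_integer_,
                           rules = stage_rules()) {
  stopifnot(inherits(rules, "stage_rules"), length(dim) == 1L, length(dryoff_day) == 1L)
  has_dim <- !is.na(dim)
  has_dry <- !is.na(dryoff_day)
  if (has_dim == has_dry) {
    abort("exactly one of dim / dryoff_day must be present")
  }
  if (has_dry) {
    if (dryoff_day < 0) abort("dryoff_day must be non-negative")
    return("drying_off")
  }
  if (dim < 0) abort("dim must be non-negative")
  if (dim <= rules$colostrum_max_dim) "colostrum"
  else if (dim <= rules$early_range[2]) "early"
  else if (dim <= rules$peak_range[2]) "peak"
  else "mid"
}

#' Classify a dataset's milk fraction from its isolation protocol
#'
#' The fraction is defined operationally by how proteins were isolated:
#' sucrose-gradient ultracentrifugation yields exosomes, cream separation
#' yields the milk fat globule membrane (MFGM), and plain
#' (ultra)centrifugation splits on g-force — at or above 100,000 x g the
#' casein micelles are pelleted and the supernatant is whey, below that it
#' is skimmed milk. Acidification and major-protein depletion do not change
#' the class. Rule precedence is sucrose gradient > cream separation >
#' g-force, because exosome isolation also involves centrifuging skimmed
#' milk.
#'
#' @param method An [isolation_descriptor()].
#' @param whey_min_g g-force threshold separating whey from skimmed milk
#'   (default 1e5; the threshold itself classifies as whey).
#' @return One of [fraction_levels()].
#' @export
#' @examples
#' classify_fraction(isolation_descriptor("centrifugation", max_g = 50000,
#'                                        acidification = TRUE))   # skimmed
#' classify_fraction(isolation_descriptor("sucrose_gradient"))     # exosomes
classify_fraction <- function(method, whey_min_g = 1e5) {
  stopifnot(inherits(method, "isolation_descriptor"))
  switch(method$technique,
    sucrose_gradient = "exosomes",
    cream_separation = "MFGM",
    {
      if (is.na(method$max_g)) {
        abort(sprintf("g-force required to classify '%s'", method$technique))
      }
      if (method$max_g >= whey_min_g) "whey" else "skimmed"
    }
  )
}

#' Classify every dataset in a manifest
#'
#' Applies [classify_stage()] and [classify_fraction()] row-wise to a
#' manifest tibble (columns `dim`, `dryoff_day`, `technique`, `max_g`,
#' `acidification`, `major_protein_depletion`), filling or overwriting the
#' `stage_class` and `fraction_class` columns.
#'
#' @param manifest Tibble as returned by [read_manifest()].
#' @param rules A [stage_rules()] object.
#' @param whey_min_g Passed to [classify_fraction()].
#' @return The manifest with `fraction_class` and `stage_class` assigned.
#' @export
classify_manifest <- function(manifest, rules = stage_rules(), whey_min_g = 1e5) {
  stopifnot(is.data.frame(manifest))
  manifest$stage_class <- purrr::map2_chr(
    manifest$dim, manifest$dryoff_day,
    function(d, dd) classify_stage(d, dd, rules = rules)
  )
  manifest$fraction_class <- purrr::pmap_chr(
    manifest[c("technique", "max_g", "acidification", "major_protein_depletion")],
    function(technique, max_g, acidification, major_protein_depletion) {
      classify_fraction(
        isolation_descriptor(technique, max_g, acidification, major_protein_depletion),
        whey_min_g = whey_min_g
      )
    }
  )
  manifest
}
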