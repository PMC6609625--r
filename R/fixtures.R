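#' Packaged fixture: early-lactation exclusive milk proteins
#'
#' The 59 proteins detected exclusively in early-lactation (6-21 days in
#' milk) bovine milk, with protein identifiers, curated protein names, and
#' milk-fraction localization (`"Skimmed"`, `"MFGM"`, or both,
#' semicolon-separated). See `inst/extdata/README.md` for provenance.
#'
#' @return Tibble with columns `no`, `gene_name`, `protein_id`,
#'   `protein_name`, `fraction_localization`, `refs`.
#' @export
early_milk_proteins <- function() {
  readr::read_tsv(system.file("extdata", "early_milk_proteins.tsv", package = "milkatlas"),
                  col_types = readr::cols(no = readr::col_integer(),
                                          .default = readr::col_character()),
                  progress = FALSE)
}

#' Packaged fixture: the 35-dataset study manifest
#'
#' Study metadata for the 35 source milk-proteomics datasets, in the
#' manifest format consumed by the pipeline, plus the published
#' `fraction_class` / `stage_class` assignments for cross-checking the
#' classification rules.
#'
#' @return Tibble (see [read_manifest()] for column semantics).
#' @export
milk_dataset_manifest <- function() {
  read_manifest(system.file("extdata", "milk_dataset_manifest.tsv", package = "milkatlas"))
}

#' Packaged fixture: curated evidence for the 59 candidates
#'
#' Declarative tissue-hit, pathway-flag and literature-support evidence for
#' the early-lactation candidates, as consumed by [select_candidates()].
#'
#' @return An [evidence_table()].
#' @export
neb_candidate_evidence <- function() {
  read_evidence(system.file("extdata", "neb_candidate_evidence.tsv", package = "milkatlas"))
}

#' Category sets from a localization column
#'
#' Turns per-gene multi-label localization strings (semicolon-separated)
#' into named category sets suitable for [venn_regions()].
#'
#' @param genes Character vector of gene names.
#' @param localization Parallel character vector of semicolon-separated
#'   labels.
#' @return Named list, label -> character vector of gene names.
#' @export
#' @examples
#' localization_sets(c("A", "B"), c("Skimmed", "Skimmed;MFGM"))
localization_sets <- function(genes, localization) {
  stopifnot(length(genes) == length(localization))
  labels <- strsplit(localization, ";", fixed = TRUE)
  long <- tibble(gene_name = rep(genes, lengths(labels)),
                 label = trimws(unlist(labels, use.names = FALSE)))
  lapply(split(long$gene_name, long$label), function(g) sort(unique(g)))
}
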