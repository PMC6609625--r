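#' Read a curated evidence table
#'
#' Loads the declarative per-gene evidence used by the biomarker-selection
#' workflow: tissue proteome hits, metabolic-pathway flags, and whether the
#' literature supports a mechanistic link. Multi-valued cells are
#' semicolon-separated; empty cells mean "none".
#'
#' @param path TSV with header columns `gene_name`, `tissue_hits`,
#'   `pathway_flags`, `literature_support`, `notes`.
#' @return An `evidence_table` tibble (one row per gene; `tissue_hits` and
#'   `pathway_flags` are list-columns of character vectors).
#' @export
read_evidence <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("gene_name", "tissue_hits", "pathway_flags", "literature_support")
  if (!all(need %in% names(df))) {
    abort(sprintf("evidence table requires columns: %s", paste(need, collapse = ", ")))
  }
  evidence_table(tibble(
    gene_name = df$gene_name,
    tissue_hits = strsplit(ifelse(is.na(df$tissue_hits), "", df$tissue_hits), ";", fixed = TRUE),
    pathway_flags = strsplit(ifelse(is.na(df$pathway_flags), "", df$pathway_flags), ";", fixed = TRUE),
    literature_support = toupper(df$literature_support) %in% c("TRUE", "T", "1", "YES"),
    notes = df$notes %||% NA_character_
  ))
}

#' Construct an evidence table
#'
#' @param df Tibble with `gene_name`, list-columns `tissue_hits` and
#'   `pathway_flags`, logical `literature_support`, optional `notes`.
#' @return An `evidence_table` tibble.
#' @export
evidence_table <- function(df) {
  stopifnot(is.data.frame(df))
  out <- as_tibble(df)
  out$gene_name <- normalize_gene_name(out$gene_name)
  if (anyDuplicated(out$gene_name)) {
    abort("evidence table must have one row per gene_name")
  }
  if (!"notes" %in% names(out)) out$notes <- NA_character_
  out$tissue_hits <- lapply(out$tissue_hits, function(x) x[nzchar(x)])
  out$pathway_flags <- lapply(out$pathway_flags, function(x) x[nzchar(x)])
  class(out) <- c("evidence_table", class(out))
  out
}

#' Cross-reference candidates against tissue proteome lists
#'
#' Restricts each tissue's protein list to the candidate set and decomposes
#' the overlaps into exact Venn regions, reporting how many candidates were
#' previously identified in at least one tissue (e.g. liver, adipose
#' tissue, mammary gland of lactating cows).
#'
#' @param candidates Character vector of candidate gene names.
#' @param tissue_lists Non-empty named list, tissue -> character vector of
#'   gene names.
#' @return List with `partition` (a `category_partition` over the
#'   candidate-restricted tissue sets), `n_in_any` (candidates found in >= 1
#'   tissue), and `not_in_any` (sorted candidates absent from all tissues).
#' @export
crossref_tissues <- function(candidates, tissue_lists) {
  if (length(tissue_lists) == 0L || is.null(names(tissue_lists))) {
    abort("tissue_lists must be a non-empty named list")
  }
  candidates <- unique(normalize_gene_name(candidates))
  sets <- lapply(tissue_lists, function(s) intersect(candidates, normalize_gene_name(s)))
  partition <- venn_regions(sets, dimension = "tissue")
  in_any <- sort(unique(unlist(sets, use.names = FALSE)))
  list(partition = partition,
       n_in_any = length(in_any),
       not_in_any = sort(setdiff(candidates, in_any)))
}

#' Default biomarker-selection criteria
#'
#' A candidate is shortlisted when it carries at least one flag among the
#' listed pathways (energy-metabolism pathways upregulated under negative
#' energy balance, plus mammary cell proliferation) and has literature
#' support for the link.
#'
#' @param pathway_any Pathway flags of which at least one is required.
#' @param require_literature Require `literature_support` to be `TRUE`.
#' @return A named list of criteria.
#' @export
selection_criteria <- function(pathway_any = c("gluconeogenesis",
                                               "ketone_metabolism",
                                               "oxidative_phosphorylation",
                                               "cell_proliferation"),
                               require_literature = TRUE) {
  list(pathway_any = pathway_any, require_literature = isTRUE(require_literature))
}

#' Select biomarker candidates from curated evidence
#'
#' Applies the declarative selection criteria to a candidate set. A
#' candidate absent from the evidence table is treated as an all-false row
#' (and logged). The shortlist is ranked by the number of satisfied
#' criteria (matching pathway flags plus literature support), then gene
#' name.
#'
#' @param candidates Character vector of candidate gene names.
#' @param evidence An [evidence_table()].
#' @param criteria A [selection_criteria()] list.
#' @return Tibble `gene_name`, `n_pathway_flags`, `literature_support`,
#'   `n_criteria`, `selected`, sorted with the shortlist first. Use
#'   `shortlist()` for just the selected gene names.
#' @export
select_candidates <- function(candidates, evidence, criteria = selection_criteria()) {
  stopifnot(inherits(evidence, "evidence_table"))
  candidates <- sort(unique(normalize_gene_name(candidates)))
  missing <- setdiff(candidates, evidence$gene_name)
  if (length(missing) > 0L) {
    inform(sprintf("%d candidate(s) absent from evidence table, treated as all-false: %s",
                   length(missing), paste(missing, collapse = ", ")))
  }
  idx <- match(candidates, evidence$gene_name)
  flags <- lapply(idx, function(i) if (is.na(i)) character() else evidence$pathway_flags[[i]])
  lit <- ifelse(is.na(idx), FALSE, evidence$literature_support[idx])
  n_path <- vapply(flags, function(f) length(intersect(f, criteria$pathway_any)), integer(1))
  selected <- n_path >= 1L & (!criteria$require_literature | lit)
  out <- tibble(
    gene_name = candidates,
    n_pathway_flags = n_path,
    literature_support = lit,
    n_criteria = n_path + as.integer(lit),
    selected = selected
  )
  out[order(-out$selected, -out$n_criteria, out$gene_name), ]
}

#' Shortlisted gene names from a selection result
#'
#' @param selection Result of [select_candidates()].
#' @return Sorted character vector of selected gene names.
#' @export
shortlist <- function(selection) {
  sort(selection$gene_name[selection$selected])
}
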