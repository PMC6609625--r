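#' Normalize gene-name and identifier strings
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace
#' to a single space, and uppercases. Applied uniformly to raw identifiers
#' and gene names so that matching is case-insensitive; mixed-case symbols
#' such as `"Bt.64131"` or `"Man8"` are kept verbatim apart from casing.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_gene_name(c("  hist1h4a ", "Sec.  11c"))
normalize_gene_name <- function(x) {
  toupper(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Construct an identifier-to-gene-name mapping table
#'
#' Builds the lookup used to harmonize heterogeneous protein identifiers
#' (UniProt accessions, entry names, local IDs) to gene names. Rows sharing
#' a raw identifier are merged, preserving first-seen gene-name order and
#' dropping duplicate names per key.
#'
#' @param df Data frame with columns `raw_id` and `gene_name` (an optional
#'   `source` column is ignored for lookup).
#' @param source_tag Free-text label recording where the table came from.
#' @return An `id_mapping_table`: a list with `entries` (named list,
#'   normalized raw identifier -> character vector of gene names),
#'   `source_tag`, `n_rows`, and `n_keys`.
#' @export
id_mapping_table <- function(df, source_tag = "user") {
  stopifnot(is.data.frame(df))
  if (!all(c("raw_id", "gene_name") %in% names(df))) {
    abort("mapping table requires columns 'raw_id' and 'gene_name'")
  }
  raw <- normalize_gene_name(df$raw_id)
  gn <- normalize_gene_name(df$gene_name)
  blank <- !nzchar(gn) | is.na(df$gene_name) | !nzchar(raw)
  if (any(blank)) {
    warn(sprintf("dropping %d mapping row(s) with blank identifier or gene name", sum(blank)))
    raw <- raw[!blank]
    gn <- gn[!blank]
  }
  entries <- lapply(split(gn, factor(raw, levels = unique(raw))), unique)
  structure(
    list(entries = entries, source_tag = source_tag,
         n_rows = length(gn), n_keys = length(entries)),
    class = "id_mapping_table"
  )
}

#' Load a mapping table from a delimited file
#'
#' Reads a UTF-8 tab-separated file with header columns `raw_id` and
#' `gene_name` (extra columns such as `source` are permitted). Rows with a
#' blank gene name are skipped with a warning; duplicate rows collapse to a
#' single entry.
#'
#' @param path Path to the TSV file.
#' @param source_tag Label stored on the table; defaults to the file name.
#' @return An [id_mapping_table()].
#' @export
load_mapping <- function(path, source_tag = basename(path)) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("raw_id", "gene_name") %in% names(df))) {
    abort(sprintf("mapping file '%s' must have columns 'raw_id' and 'gene_name'", path))
  }
  tbl <- id_mapping_table(df, source_tag = source_tag)
  inform(sprintf("loaded mapping '%s': %d rows, %d keys", source_tag, nrow(df), tbl$n_keys))
  tbl
}

#' @export
print.id_mapping_table <- function(x, ...) {
  cat(sprintf("<id_mapping_table> %d keys (source: %s)\n", x$n_keys, x$source_tag))
  invisible(x)
}

#' Harmonize one raw identifier to gene names
#'
#' Looks up a raw protein identifier and returns its gene name(s). Lookup is
#' case-insensitive; if the identifier is absent as written, a trailing
#' isoform suffix (`-1`, `-2`, ...) is stripped and the lookup retried,
#' reflecting the collapse of protein isoforms onto a single gene symbol.
#' Multi-mapped identifiers are resolved by `policy`:
#' \describe{
#'   \item{first}{the first gene name listed for the key (default);}
#'   \item{all}{every gene name for the key;}
#'   \item{drop_ambiguous}{an empty result, i.e. multi-mapped IDs are discarded.}
#' }
#'
#' @param raw_id A single identifier string.
#' @param table An [id_mapping_table()].
#' @param policy One of `"first"`, `"all"`, `"drop_ambiguous"`.
#' @return Character vector of gene names; empty when unmapped (or dropped).
#' @export
#' @examples
#' m <- id_mapping_table(data.frame(raw_id = "P62803", gene_name = "HIST1H4A"))
#' harmonize("P62803", m)
#' harmonize("ZZZ_NOT_PRESENT", m)
harmonize <- function(raw_id, table, policy = c("first", "all", "drop_ambiguous")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "id_mapping_table"), length(raw_id) == 1L)
  key <- normalize_gene_name(raw_id)
  hit <- table$entries[[key]]
  if (is.null(hit)) {
    stripped <- sub("-[0-9]+$", "", key)
    if (!identical(stripped, key)) hit <- table$entries[[stripped]]
  }
  if (is.null(hit)) return(character())
  switch(policy,
    first = hit[1L],
    all = hit,
    drop_ambiguous = if (length(hit) > 1L) character() else hit
  )
}

#' Harmonize a vector of raw identifiers
#'
#' Vectorized convenience over [harmonize()].
#'
#' @inheritParams harmonize
#' @param raw_ids Character vector of identifiers.
#' @return A list of character vectors, one per input identifier.
#' @export
harmonize_ids <- function(raw_ids, table, policy = "first") {
  lapply(raw_ids, harmonize, table = table, policy = policy)
}
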