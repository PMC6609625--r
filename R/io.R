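#' Read a dataset manifest
#'
#' Tab-separated UTF-8 with header; one row per proteomics dataset. The
#' standard columns are `dataset_id`, `source_ref`, `dim`, `dryoff_day`,
#' `technique`, `max_g`, `acidification`, `major_protein_depletion`,
#' `breed`, `country`; an empty cell means "absent". Extra columns are
#' retained as character.
#'
#' @param path Path to the manifest TSV.
#' @return Tibble, typed standard columns first.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = c("", "NA"))
  if (!"dataset_id" %in% names(df)) abort("manifest requires a 'dataset_id' column")
  if (anyDuplicated(df$dataset_id)) {
    abort(sprintf("duplicate dataset_id in manifest: %s",
                  paste(unique(df$dataset_id[duplicated(df$dataset_id)]), collapse = ", ")))
  }
  to_int <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  to_dbl <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  to_lgl <- function(x) {
    if (is.null(x)) return(NA)
    ifelse(is.na(x), NA, toupper(x) %in% c("TRUE", "T", "1", "YES"))
  }
  df$dim <- to_int(df[["dim"]])
  df$dryoff_day <- to_int(df[["dryoff_day"]])
  df$max_g <- to_dbl(df[["max_g"]])
  df$acidification <- to_lgl(df[["acidification"]])
  df$major_protein_depletion <- to_lgl(df[["major_protein_depletion"]])
  for (col in c("source_ref", "technique", "breed", "country")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df
}

#' Read a per-dataset identifier list
#'
#' One raw identifier per line; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of raw identifiers (order preserved).
#' @export
read_id_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read tissue proteome lists
#'
#' Each file holds one tissue's gene-name list (one per line, `#` comments
#' allowed); the tissue name is the file name without extension.
#'
#' @param paths Named character vector of file paths, or unnamed (names are
#'   derived from file names).
#' @return Named list, tissue -> character vector of gene names.
#' @export
read_tissue_lists <- function(paths) {
  nm <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  setNames(lapply(paths, read_id_list), nm)
}

#' Export an atlas to long-format TSV with a provenance sidecar
#'
#' Writes the presence pairs as tab-separated long format (`gene_name`,
#' `dataset_id`, `fraction_class`, `stage_class`), rows sorted for
#' byte-stable output, and the ingestion provenance to a
#' `*.provenance.json` sidecar.
#'
#' @param atlas A `milk_atlas`.
#' @param path Output TSV path.
#' @return Invisibly, the TSV path.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "milk_atlas"))
  idx <- match(atlas$records$dataset_id, atlas$manifest$dataset_id)
  out <- tibble(
    gene_name = atlas$records$gene_name,
    dataset_id = atlas$records$dataset_id,
    fraction_class = atlas$manifest[["fraction_class"]][idx] %||% NA_character_,
    stage_class = atlas$manifest[["stage_class"]][idx] %||% NA_character_
  )
  out <- out[order(out$dataset_id, out$gene_name), ]
  readr::write_tsv(out, path)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(atlas$provenance, paste0(sidecar, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Re-ingest an exported atlas TSV
#'
#' Reconstructs a `milk_atlas` from a file written by [write_atlas()]. The
#' manifest carries only what the long format retains (dataset_id and the
#' two class columns); provenance is re-read from the sidecar when present.
#'
#' @param path Path to the atlas TSV.
#' @return A `milk_atlas`.
#' @export
read_atlas <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = c("", "NA"))
  need <- c("gene_name", "dataset_id")
  if (!all(need %in% names(df))) abort("atlas file requires gene_name and dataset_id columns")
  manifest <- dplyr::distinct(df[intersect(c("dataset_id", "fraction_class", "stage_class"),
                                           names(df))])
  sidecar <- paste0(sub("\\.tsv$", "", path), ".provenance.json")
  provenance <- if (file.exists(sidecar)) {
    as_tibble(jsonlite::fromJSON(sidecar))
  } else {
    tibble(dataset_id = manifest$dataset_id)
  }
  validate_atlas(structure(
    list(records = tibble(gene_name = df$gene_name, dataset_id = df$dataset_id),
         manifest = manifest, provenance = provenance),
    class = "milk_atlas"
  ))
}

#' Write a Venn-region report
#'
#' TSV with one row per region (`signature`, `n_categories`, `n`,
#' semicolon-joined gene names) and, optionally, a JSON mirror of the
#' counts summary.
#'
#' @param partition A `category_partition`.
#' @param path Output TSV path.
#' @param json Also write a `.json` twin (default TRUE).
#' @return Invisibly, the TSV path.
#' @export
write_region_report <- function(partition, path, json = TRUE) {
  stopifnot(inherits(partition, "category_partition"))
  counts <- region_counts(partition)
  counts$genes <- vapply(partition$regions[counts$signature],
                         paste, character(1), collapse = ";")
  readr::write_tsv(counts, path)
  if (json) {
    jsonlite::write_json(
      setNames(as.list(counts$n), counts$signature),
      paste0(sub("\\.tsv$", "", path), ".json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}
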