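#' Describe how a milk fraction was isolated
#'
#' Captures the protein-isolation protocol of a dataset, which is what the
#' milk-fraction classification rules operate on: the technique, the maximum
#' relative centrifugal force, and whether caseins were removed by
#' acidification or by depletion of major proteins.
#'
#' @param technique One of `"centrifugation"`, `"ultracentrifugation"`,
#'   `"cream_separation"`, `"sucrose_gradient"`.
#' @param max_g Maximum relative centrifugal force (x g), or `NA` when not
#'   applicable. Must be positive when present.
#' @param acidification Logical; casein depletion by acidification.
#' @param major_protein_depletion Logical; depletion of major milk proteins.
#' @return An `isolation_descriptor` list.
#' @export
isolation_descriptor <- function(technique,
                                 max_g = NA_real_,
                                 acidification = FALSE,
                                 major_protein_depletion = FALSE) {
  technique <- match.arg(technique, c("centrifugation", "ultracentrifugation",
                                      "cream_separation", "sucrose_gradient"))
  max_g <- as.numeric(max_g)
  if (!is.na(max_g) && max_g <= 0) abort("max_g, when present, must be > 0")
  structure(
    list(technique = technique, max_g = max_g,
         acidification = isTRUE(acidification),
         major_protein_depletion = isTRUE(major_protein_depletion)),
    class = "isolation_descriptor"
  )
}

#' Construct a dataset record
#'
#' One proteomics dataset: its study metadata plus (after ingestion) the
#' deduplicated set of gene names identified in it. Exactly one of `dim`
#' (days in milk) and `dryoff_day` (days after milking cessation) governs
#' the lactation-stage assignment, so both may not be present at once.
#'
#' @param dataset_id Short unique label.
#' @param source_ref Free-text citation key.
#' @param dim Integer days in milk, or `NA`.
#' @param dryoff_day Integer days after drying-off, or `NA`.
#' @param method An [isolation_descriptor()], or `NULL`.
#' @param breed,country Free text.
#' @param fraction_class,stage_class Assigned classes (normally filled by
#'   [classify_fraction()] / [classify_stage()]), or `NA`.
#' @param gene_names Character vector; stored deduplicated and normalized.
#' @return A `dataset_record` list.
#' @export
dataset_record <- function(dataset_id, source_ref = NA_character_,
                           dim = NA_integer_, dryoff_day = NA_integer_,
                           method = NULL, breed = NA_character_,
                           country = NA_character_,
                           fraction_class = NA_character_,
                           stage_class = NA_character_,
                           gene_names = character()) {
  stopifnot(length(dataset_id) == 1L, nzchar(dataset_id))
  if (!is.na(dim) && !is.na(dryoff_day)) {
    abort(sprintf("dataset '%s': dim and dryoff_day cannot both be present", dataset_id))
  }
  structure(
    list(dataset_id = as.character(dataset_id), source_ref = source_ref,
         dim = dim, dryoff_day = dryoff_day, method = method,
         breed = breed, country = country,
         fraction_class = fraction_class, stage_class = stage_class,
         gene_names = unique(normalize_gene_name(gene_names)),
         provenance = NULL),
    class = "dataset_record"
  )
}

#' Ingest a raw identifier list into a dataset record
#'
#' Harmonizes each raw protein identifier to a gene name through the mapping
#' table, then deduplicates within the dataset: a gene name identified more
#' than once in one dataset is kept once, since the atlas records presence,
#' not abundance. Unmapped identifiers are excluded but counted in the
#' record's provenance; setting `keep_unmapped = TRUE` retains them under a
#' reserved `"UNMAPPED:"` prefix for audit.
#'
#' @param raw_ids Character vector of raw identifiers. Identifiers that
#'   still contain internal whitespace after normalization are treated as
#'   malformed lines and skipped with a warning.
#' @param record A [dataset_record()] with metadata set.
#' @param mapping An [id_mapping_table()].
#' @param policy Multi-mapping policy passed to [harmonize()].
#' @param keep_unmapped Retain unmapped identifiers as `"UNMAPPED:<id>"`.
#' @return The record with `gene_names` populated and `provenance` set to a
#'   list with counts `n_raw`, `n_malformed`, `n_mapped`, `n_unmapped`,
#'   `n_after_dedup`.
#' @export
#' @examples
#' m <- id_mapping_table(data.frame(raw_id = c("P62803", "Q95M55"),
#'                                  gene_name = c("HIST1H4A", "LF")))
#' r <- ingest_dataset(c("P62803", "P62803", "Q95M55"),
#'                     dataset_record("d1"), m)
#' r$gene_names     # "HIST1H4A" "LF"
#' r$provenance$n_after_dedup
ingest_dataset <- function(raw_ids, record, mapping,
                           policy = "first", keep_unmapped = FALSE) {
  stopifnot(inherits(record, "dataset_record"), inherits(mapping, "id_mapping_table"))
  raw_ids <- as.character(raw_ids)
  n_raw <- length(raw_ids)
  if (n_raw == 0L) {
    warn(sprintf("dataset '%s': empty identifier list", record$dataset_id))
  }
  norm <- normalize_gene_name(raw_ids)
  malformed <- grepl(" ", norm, fixed = TRUE) | !nzchar(norm)
  if (any(malformed)) {
    warn(sprintf("dataset '%s': skipping %d malformed identifier line(s)",
                 record$dataset_id, sum(malformed)))
  }
  ids <- norm[!malformed]
  mapped <- harmonize_ids(ids, mapping, policy = policy)
  hit <- lengths(mapped) > 0L
  genes <- as.character(unlist(mapped[hit], use.names = FALSE))
  if (keep_unmapped) genes <- c(genes, paste0("UNMAPPED:", ids[!hit]))
  record$gene_names <- unique(genes)
  record$provenance <- list(
    n_raw = n_raw,
    n_malformed = sum(malformed),
    n_mapped = sum(hit),
    n_unmapped = sum(!hit),
    n_after_dedup = length(record$gene_names)
  )
  record
}

#' Assemble the presence/absence atlas from dataset records
#'
#' Stacks the per-dataset gene-name sets into a long-format table of
#' (gene_name, dataset_id) presence pairs — sparse, append-friendly, and
#' faithful to all-or-nothing identification — together with the manifest of
#' dataset metadata and an ingestion-provenance table.
#'
#' @param datasets List of [dataset_record()]s with unique `dataset_id`s.
#' @return A `milk_atlas`: list with `records` (tibble: gene_name,
#'   dataset_id), `manifest` (tibble of metadata, one row per dataset), and
#'   `provenance` (tibble of ingestion counts).
#' @export
build_atlas <- function(datasets) {
  stopifnot(is.list(datasets), all(vapply(datasets, inherits, logical(1), "dataset_record")))
  ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate dataset_id: %s", paste(dup, collapse = ", ")))
  }
  if (length(datasets) == 0L) {
    return(structure(
      list(records = tibble(gene_name = character(), dataset_id = character()),
           manifest = tibble(dataset_id = character(),
                             fraction_class = character(),
                             stage_class = character()),
           provenance = tibble(dataset_id = character(), n_raw = integer(),
                               n_malformed = integer(), n_mapped = integer(),
                               n_unmapped = integer(), n_after_dedup = integer())),
      class = "milk_atlas"
    ))
  }
  records <- purrr::map_dfr(datasets, function(d) {
    tibble(gene_name = d$gene_names, dataset_id = d$dataset_id)
  })
  if (nrow(records) == 0L) {
    records <- tibble(gene_name = character(), dataset_id = character())
  }
  manifest <- purrr::map_dfr(datasets, function(d) {
    tibble(
      dataset_id = d$dataset_id, source_ref = d$source_ref,
      dim = d$dim, dryoff_day = d$dryoff_day,
      technique = if (is.null(d$method)) NA_character_ else d$method$technique,
      max_g = if (is.null(d$method)) NA_real_ else d$method$max_g,
      acidification = if (is.null(d$method)) NA else d$method$acidification,
      major_protein_depletion = if (is.null(d$method)) NA else d$method$major_protein_depletion,
      breed = d$breed, country = d$country,
      fraction_class = d$fraction_class, stage_class = d$stage_class
    )
  })
  provenance <- purrr::map_dfr(datasets, function(d) {
    p <- d$provenance %||% list(n_raw = NA_integer_, n_malformed = NA_integer_,
                                n_mapped = NA_integer_, n_unmapped = NA_integer_,
                                n_after_dedup = length(d$gene_names))
    tibble(dataset_id = d$dataset_id, n_raw = p$n_raw, n_malformed = p$n_malformed,
           n_mapped = p$n_mapped, n_unmapped = p$n_unmapped,
           n_after_dedup = p$n_after_dedup)
  })
  atlas <- structure(list(records = records, manifest = manifest, provenance = provenance),
                     class = "milk_atlas")
  validate_atlas(atlas)
}

validate_atlas <- function(atlas) {
  r <- atlas$records
  if (anyDuplicated(paste(r$gene_name, r$dataset_id, sep = "\r"))) {
    abort("atlas invariant violated: duplicated (gene_name, dataset_id) pair")
  }
  if (!all(r$dataset_id %in% atlas$manifest$dataset_id)) {
    abort("atlas invariant violated: presence pair refers to unknown dataset_id")
  }
  atlas
}

#' @export
print.milk_atlas <- function(x, ...) {
  cat(sprintf("<milk_atlas> %d presence pairs | %d unique gene names | %d datasets\n",
              nrow(x$records), length(unique(x$records$gene_name)), nrow(x$manifest)))
  invisible(x)
}

#' Unique proteins in an atlas
#'
#' The union of gene names over all presence pairs — the atlas's
#' non-redundant protein complement.
#'
#' @param atlas A `milk_atlas`.
#' @return Sorted character vector of gene names.
#' @export
unique_proteins <- function(atlas) {
  stopifnot(inherits(atlas, "milk_atlas"))
  sort(unique(atlas$records$gene_name))
}

#' Total presence pairs in an atlas
#'
#' The number of (gene name, dataset) presence pairs after per-dataset
#' deduplication, i.e. the sum over datasets of their gene-set sizes.
#'
#' @param atlas A `milk_atlas`.
#' @return Integer count.
#' @export
n_presence_pairs <- function(atlas) {
  stopifnot(inherits(atlas, "milk_atlas"))
  nrow(atlas$records)
}
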