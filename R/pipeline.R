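#' Run the full atlas pipeline over input files
#'
#' Orchestrates every stage in order: read manifest and per-dataset ID
#' lists, harmonize identifiers, per-dataset dedup, classify milk fraction
#' and lactation stage, assemble the atlas, decompose both categorical
#' dimensions into Venn regions, and — when the corresponding inputs are
#' supplied — run over-representation analysis on a chosen exclusive list,
#' cross-reference it against tissue lists, and apply the
#' biomarker-selection criteria. Reports (TSV and/or JSON) are written
#' progressively, so a failing stage leaves earlier outputs in place and
#' raises an error naming the stage.
#'
#' @param manifest_path Manifest TSV (see [read_manifest()]).
#' @param ids_dir Directory with one `<dataset_id>.txt` list per dataset.
#' @param mapping_path Mapping TSV (see [load_mapping()]).
#' @param out_dir Output directory (created if needed).
#' @param annotations_path Optional GAF/TSV annotation file.
#' @param evidence_path Optional evidence TSV (see [read_evidence()]).
#' @param tissue_paths Optional named vector of tissue-list files.
#' @param candidate_dimension,candidate_category Which exclusive list feeds
#'   enrichment / cross-referencing / selection (default: the
#'   early-lactation stage list).
#' @param policy Multi-mapping policy for [harmonize()].
#' @param rules A [stage_rules()] object.
#' @param alpha,top_k Enrichment settings (see [enrich()]).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Invisibly, a list with the `atlas`, the two `partitions`, any
#'   `enrichment` / `crossref` / `selection` results, and the `summary`
#'   list mirrored in `summary.json`.
#' @export
run_pipeline <- function(manifest_path, ids_dir, mapping_path, out_dir,
                         annotations_path = NULL, evidence_path = NULL,
                         tissue_paths = NULL,
                         candidate_dimension = "stage_class",
                         candidate_category = "early",
                         policy = "first", rules = stage_rules(),
                         alpha = 0.05, top_k = 50,
                         formats = c("tsv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  manifest <- stage("ingest", read_manifest(manifest_path))
  mapping <- stage("ingest", load_mapping(mapping_path))
  datasets <- stage("harmonize", lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rec <- dataset_record(
      row$dataset_id, source_ref = row$source_ref,
      dim = row$dim, dryoff_day = row$dryoff_day,
      method = if (is.na(row$technique)) NULL else
        isolation_descriptor(row$technique, row$max_g,
                             isTRUE(row$acidification),
                             isTRUE(row$major_protein_depletion)),
      breed = row$breed, country = row$country,
      fraction_class = row[["fraction_class"]] %||% NA_character_,
      stage_class = row[["stage_class"]] %||% NA_character_
    )
    ingest_dataset(read_id_list(file.path(ids_dir, paste0(row$dataset_id, ".txt"))),
                   rec, mapping, policy = policy)
  }))
  # classify from raw metadata where available; a pre-assigned class on the
  # manifest is kept for rows that carry no DIM / isolation descriptor
  datasets <- stage("classify", lapply(datasets, function(d) {
    if (!is.na(d$dim) || !is.na(d$dryoff_day)) {
      d$stage_class <- classify_stage(d$dim, d$dryoff_day, rules = rules)
    }
    if (!is.null(d$method)) d$fraction_class <- classify_fraction(d$method)
    d
  }))
  atlas <- stage("atlas", build_atlas(datasets))
  if (nrow(atlas$manifest) > 0) write_atlas(atlas, file.path(out_dir, "atlas.tsv"))

  partitions <- list()
  for (dim_col in c("fraction_class", "stage_class")) {
    partitions[[dim_col]] <- stage("partition", {
      if (nrow(atlas$manifest) == 0L || all(is.na(atlas$manifest[[dim_col]]))) NULL
      else {
        sets <- category_union_sets(atlas, dimension = dim_col)
        p <- venn_regions(sets, dimension = dim_col)
        if ("tsv" %in% formats) {
          write_region_report(p, file.path(out_dir, paste0("regions_", dim_col, ".tsv")),
                              json = "json" %in% formats)
        }
        p
      }
    })
  }

  candidates <- NULL
  cand_part <- partitions[[candidate_dimension]]
  if (!is.null(cand_part) && candidate_category %in% names(cand_part$category_sets)) {
    candidates <- exclusive_to(cand_part, candidate_category)
  }

  enrichment <- NULL
  if (!is.null(annotations_path) && !is.null(candidates) && length(candidates) > 0L) {
    enrichment <- stage("enrich", {
      ann <- read_annotations(annotations_path)
      res <- enrich(candidates, unique_proteins(atlas), ann,
                    alpha = alpha, top_k = top_k)
      if ("tsv" %in% formats) {
        res_out <- res
        res_out$p_raw <- signif(res_out$p_raw, 6)
        res_out$p_adj <- signif(res_out$p_adj, 6)
        readr::write_tsv(res_out, file.path(out_dir, "enrichment.tsv"))
      }
      res
    })
  }

  crossref <- NULL
  if (!is.null(tissue_paths) && !is.null(candidates)) {
    crossref <- stage("crossref", {
      cr <- crossref_tissues(candidates, read_tissue_lists(tissue_paths))
      if ("tsv" %in% formats) {
        write_region_report(cr$partition, file.path(out_dir, "crossref_tissues.tsv"),
                            json = "json" %in% formats)
      }
      cr
    })
  }

  selection <- NULL
  if (!is.null(evidence_path) && !is.null(candidates)) {
    selection <- stage("select", {
      sel <- select_candidates(candidates, read_evidence(evidence_path))
      if ("tsv" %in% formats) {
        sel_out <- sel
        readr::write_tsv(sel_out, file.path(out_dir, "shortlist.tsv"))
      }
      sel
    })
  }

  summary <- list(
    n_datasets = nrow(atlas$manifest),
    n_presence_pairs = n_presence_pairs(atlas),
    n_unique_proteins = length(unique_proteins(atlas)),
    region_counts = lapply(partitions, function(p) {
      if (is.null(p)) NULL else setNames(as.list(lengths(p$regions)), names(p$regions))
    }),
    exclusive_counts = lapply(partitions, function(p) {
      if (is.null(p)) NULL
      else setNames(lapply(names(p$category_sets), function(cat) length(exclusive_to(p, cat))),
                    names(p$category_sets))
    }),
    n_candidates = length(candidates %||% character()),
    shortlist = if (is.null(selection)) NULL else shortlist(selection)
  )
  if ("json" %in% formats) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(atlas = atlas, partitions = partitions, enrichment = enrichment,
                 crossref = crossref, selection = selection, summary = summary))
}
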