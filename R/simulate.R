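#' Configuration for the detection-list simulator
#'
#' Describes a synthetic multi-study design: a protein universe partitioned
#' into a core set present in every category, planted category-exclusive
#' sets, and background proteins whose category memberships are drawn
#' independently (Bernoulli 0.5 per category, which populates the
#' intermediate Venn regions). Each dataset observes its category's
#' proteins with detection probability `p_detect`, and each emitted
#' identifier may be replaced by a mappable synonym or an unmappable ID,
#' emulating the identifier heterogeneity and conversion loss of real
#' multi-study aggregation.
#'
#' Defaults emulate a five-stage, 35-dataset milk-proteome meta-analysis:
#' a universe of 1000 proteins, a core of 100 detected at all stages, 50
#' planted exclusives per stage, 90% per-dataset detection, 5% synonym and
#' 2% unmappable emissions.
#'
#' @param n_proteins Universe size.
#' @param categories Category labels, or a named list of length one
#'   (`dimension = labels`).
#' @param dimension Name of the categorical dimension (manifest column).
#' @param n_datasets_per_category Datasets simulated per category.
#' @param core_size Proteins present in all categories.
#' @param exclusive_per_category Planted exclusive proteins per category.
#' @param p_detect Per-dataset detection probability in (0, 1].
#' @param synonym_prob Probability an emission uses an alternative raw ID
#'   (still mappable).
#' @param unmapped_prob Probability an emission uses an unmappable ID.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1000L,
                             categories = stage_levels(),
                             dimension = "stage_class",
                             n_datasets_per_category = 7L,
                             core_size = 100L,
                             exclusive_per_category = 50L,
                             p_detect = 0.9,
                             synonym_prob = 0.05,
                             unmapped_prob = 0.02,
                             seed = 0L) {
  if (is.list(categories)) {
    stopifnot(length(categories) == 1L, !is.null(names(categories)))
    dimension <- names(categories)[1]
    categories <- categories[[1]]
  }
  categories <- as.character(categories)
  if (length(categories) == 0L || anyDuplicated(categories)) {
    abort("categories must be a non-empty set of distinct labels")
  }
  if (core_size + length(categories) * exclusive_per_category > n_proteins) {
    abort("infeasible config: core_size + total planted exclusives exceeds n_proteins")
  }
  if (p_detect <= 0 || p_detect > 1) abort("p_detect must be in (0, 1]")
  if (synonym_prob < 0 || synonym_prob > 1 || unmapped_prob < 0 || unmapped_prob > 1 ||
      synonym_prob + unmapped_prob > 1) {
    abort("synonym_prob and unmapped_prob must be probabilities with sum <= 1")
  }
  structure(
    list(n_proteins = as.integer(n_proteins), categories = categories,
         dimension = dimension,
         n_datasets_per_category = as.integer(n_datasets_per_category),
         core_size = as.integer(core_size),
         exclusive_per_category = as.integer(exclusive_per_category),
         p_detect = p_detect, synonym_prob = synonym_prob,
         unmapped_prob = unmapped_prob, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate multi-dataset detection lists with known ground truth
#'
#' Draws the design described by a [synthetic_config()]: assigns proteins
#' to core / planted-exclusive / background roles, samples per-dataset
#' detections, and perturbs emitted identifiers. Unmappable emissions get a
#' unique `UNK_` identifier absent from the mapping table, so atlas
#' provenance can be reconciled against the generator's emission counts.
#'
#' @param config A [synthetic_config()].
#' @return A `milk_simulation`: list with `config`, `manifest` (tibble:
#'   dataset_id plus the dimension column), `id_lists` (named list of raw
#'   identifier vectors per dataset), `mapping` (an [id_mapping_table()]
#'   covering canonical `ACC` and synonym `ALT` identifiers), and `truth`
#'   (core set, per-category `planted` designed-exclusive sets, the full
#'   `exclusives` ground truth — every protein whose membership is exactly
#'   one category, i.e. planted plus single-category background — the
#'   protein-by-category `membership` matrix, and per-dataset unmapped
#'   emission counts).
#' @export
simulate_detection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  cats <- config$categories
  k <- length(cats)
  genes <- sprintf("G%05d", seq_len(n))
  acc <- sprintf("ACC%05d", seq_len(n))
  alt <- sprintf("ALT%05d", seq_len(n))

  core <- genes[seq_len(config$core_size)]
  excl <- list()
  offset <- config$core_size
  for (cat in cats) {
    excl[[cat]] <- genes[offset + seq_len(config$exclusive_per_category)]
    offset <- offset + config$exclusive_per_category
  }
  background <- genes[seq(offset + 1, length.out = n - offset)]

  # membership matrix: protein x category
  member <- matrix(FALSE, nrow = n, ncol = k, dimnames = list(genes, cats))
  member[core, ] <- TRUE
  for (cat in cats) member[excl[[cat]], cat] <- TRUE
  if (length(background) > 0L) {
    member[background, ] <- matrix(rbinom(length(background) * k, 1L, 0.5) == 1L,
                                   ncol = k)
  }

  id_lists <- list()
  manifest_rows <- list()
  unmapped_counts <- integer()
  for (cat in cats) {
    pool_idx <- which(member[, cat])
    for (j in seq_len(config$n_datasets_per_category)) {
      ds <- sprintf("SIM_%s_%d", cat, j)
      detected <- pool_idx[runif(length(pool_idx)) <= config$p_detect]
      u <- runif(length(detected))
      raw <- acc[detected]
      raw[u < config$synonym_prob] <- alt[detected[u < config$synonym_prob]]
      is_unk <- u >= config$synonym_prob &
        u < config$synonym_prob + config$unmapped_prob
      raw[is_unk] <- sprintf("UNK_%s_%d", ds, seq_len(sum(is_unk)))
      id_lists[[ds]] <- raw
      unmapped_counts[[ds]] <- sum(is_unk)
      manifest_rows[[ds]] <- tibble(dataset_id = ds, category = cat)
    }
  }
  manifest <- dplyr::bind_rows(manifest_rows)
  names(manifest)[names(manifest) == "category"] <- config$dimension
  mapping <- id_mapping_table(
    tibble(raw_id = c(acc, alt), gene_name = c(genes, genes)),
    source_tag = sprintf("synthetic(seed=%d)", config$seed)
  )
  # ground-truth exclusives: proteins whose true membership is exactly one
  # category — the planted sets plus background proteins whose Bernoulli
  # draws landed them in a single category
  single <- rowSums(member) == 1L
  exclusives_true <- lapply(setNames(nm = cats), function(cat) {
    sort(genes[single & member[, cat]])
  })
  structure(
    list(config = config, manifest = manifest, id_lists = id_lists,
         mapping = mapping,
         truth = list(core = core, planted = excl,
                      exclusives = exclusives_true,
                      membership = member,
                      unmapped_counts = unmapped_counts)),
    class = "milk_simulation"
  )
}

#' @export
print.milk_simulation <- function(x, ...) {
  cat(sprintf("<milk_simulation> %d proteins | %d categories x %d datasets | seed %d\n",
              x$config$n_proteins, length(x$config$categories),
              x$config$n_datasets_per_category, x$config$seed))
  invisible(x)
}

#' Build an atlas from a simulation
#'
#' Ingests every simulated dataset through the standard mapping/harmonize/
#' dedup path and assembles the presence atlas, carrying the simulated
#' category labels on the manifest.
#'
#' @param sim A `milk_simulation`.
#' @param policy Multi-mapping policy for [harmonize()].
#' @return A `milk_atlas`.
#' @export
atlas_from_simulation <- function(sim, policy = "first") {
  stopifnot(inherits(sim, "milk_simulation"))
  records <- lapply(names(sim$id_lists), function(ds) {
    suppressWarnings(
      ingest_dataset(sim$id_lists[[ds]], dataset_record(ds), sim$mapping, policy = policy)
    )
  })
  atlas <- build_atlas(records)
  dim_col <- sim$config$dimension
  atlas$manifest[[dim_col]] <-
    sim$manifest[[dim_col]][match(atlas$manifest$dataset_id, sim$manifest$dataset_id)]
  atlas
}

#' Recover category-exclusive sets from a simulation
#'
#' Runs the full pipeline — ingest, harmonize, per-dataset dedup, atlas,
#' per-category union, Venn decomposition — and extracts the exclusive set
#' of every category.
#'
#' @param sim A `milk_simulation`.
#' @param policy Multi-mapping policy for [harmonize()].
#' @return Named list, category -> sorted recovered exclusive gene names.
#' @export
recover_exclusives <- function(sim, policy = "first") {
  atlas <- atlas_from_simulation(sim, policy = policy)
  sets <- category_union_sets(atlas, dimension = sim$config$dimension,
                              categories = sim$config$categories)
  if (length(sets) <= 6L) {
    partition <- venn_regions(sets, dimension = sim$config$dimension)
    lapply(setNames(nm = names(sets)), exclusive_to, partition = partition)
  } else {
    mt <- membership_table(sets)
    lapply(setNames(nm = names(sets)), function(cat) {
      sort(mt$gene_name[mt$signature == cat])
    })
  }
}

#' Precision/recall of exclusive-set recovery
#'
#' Compares recovered exclusive sets against the ground-truth exclusive
#' sets (proteins whose true membership is exactly one category).
#' Precision is the fraction of recovered genes that are truly exclusive;
#' recall the fraction of truly exclusive genes recovered; both are
#' defined as 1 when their denominator is 0.
#'
#' @param truth The `truth` element of a `milk_simulation` (or the
#'   simulation itself).
#' @param recovered Named list, category -> recovered exclusive gene names
#'   (e.g. from [recover_exclusives()]). Category labels must match the
#'   truth exactly.
#' @return Tibble: `category`, `n_true`, `n_recovered`, `precision`,
#'   `recall`.
#' @export
recovery_report <- function(truth, recovered) {
  if (inherits(truth, "milk_simulation")) truth <- truth$truth
  planted <- truth$exclusives
  if (!setequal(names(planted), names(recovered))) {
    abort("category labels of truth and recovered sets do not match")
  }
  purrr::map_dfr(names(planted), function(cat) {
    p <- planted[[cat]]
    r <- recovered[[cat]]
    hits <- length(intersect(p, r))
    tibble(
      category = cat,
      n_true = length(p),
      n_recovered = length(r),
      precision = if (length(r) == 0L) 1 else hits / length(r),
      recall = if (length(p) == 0L) 1 else hits / length(p)
    )
  })
}

#' Write a simulation to disk in pipeline input formats
#'
#' Emits exactly the files the atlas pipeline consumes — a manifest TSV, a
#' directory of one-identifier-per-line dataset lists, a mapping TSV — plus
#' a `truth.json` sidecar.
#'
#' @param sim A `milk_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "milk_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids_dir <- file.path(dir, "ids")
  dir.create(ids_dir, showWarnings = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(sim$manifest, manifest_path)
  for (ds in names(sim$id_lists)) {
    writeLines(sim$id_lists[[ds]], file.path(ids_dir, paste0(ds, ".txt")))
  }
  mapping_path <- file.path(dir, "mapping.tsv")
  readr::write_tsv(
    tibble(raw_id = rep(names(sim$mapping$entries), lengths(sim$mapping$entries)),
           gene_name = unlist(sim$mapping$entries, use.names = FALSE)),
    mapping_path
  )
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = sim$config$seed, core = sim$truth$core,
         planted = sim$truth$planted,
         exclusives = sim$truth$exclusives,
         unmapped_counts = as.list(sim$truth$unmapped_counts)),
    truth_path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(manifest = manifest_path, ids_dir = ids_dir,
              mapping = mapping_path, truth = truth_path))
}
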