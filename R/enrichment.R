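#' Construct an annotation table
#'
#' A flat gene-to-term association table covering Gene Ontology namespaces
#' (BP, MF, CC) plus subcellular `location` and protein-`complex`
#' groupings. Associations are used as given: no term-to-ancestor
#' propagation is applied, matching a flat import of curated annotations.
#' Duplicate (gene_name, term_id, taxon) triples are dropped.
#'
#' @param df Data frame with columns `gene_name`, `term_id`, `term_label`,
#'   `namespace`, `evidence_code`, `taxon` (missing optional columns are
#'   filled with `NA`; `term_label` falls back to `term_id`).
#' @return An `annotation_table` tibble.
#' @export
annotation_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene_name", "term_id")
  if (!all(need %in% names(df))) {
    abort("annotation table requires columns 'gene_name' and 'term_id'")
  }
  out <- as_tibble(df)
  if (!"term_label" %in% names(out)) out$term_label <- out$term_id
  for (col in c("namespace", "evidence_code", "taxon")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  out <- out[c("gene_name", "term_id", "term_label", "namespace", "evidence_code", "taxon")]
  out$gene_name <- normalize_gene_name(out$gene_name)
  if (any(!nzchar(out$term_id) | is.na(out$term_id))) {
    abort("term_id must be non-empty")
  }
  bad_ns <- setdiff(unique(out$namespace), c("BP", "MF", "CC", "location", "complex", NA))
  if (length(bad_ns) > 0L) {
    abort(sprintf("unknown namespace(s): %s", paste(bad_ns, collapse = ", ")))
  }
  out <- dplyr::distinct(out, .data$gene_name, .data$term_id, .data$taxon, .keep_all = TRUE)
  class(out) <- c("annotation_table", class(out))
  out
}

#' Read gene annotations from GAF or simplified TSV
#'
#' Two formats are supported. A GAF 2.x gene-association file (lines
#' starting with `!` are headers; tab-separated, no column header): the
#' object symbol, GO ID, evidence code, aspect and taxon columns are used,
#' with aspect P/F/C mapped to the BP/MF/CC namespaces. Or a simplified
#' TSV with header columns `gene_name`, `term_id`, and optionally
#' `term_label`, `namespace`, `evidence_code`, `taxon`.
#'
#' @param path File path.
#' @param format `"auto"` (sniff: a first line starting with `!` or 15+
#'   tab-separated fields means GAF), `"gaf"`, or `"tsv"`.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "!") ||
                  length(strsplit(first, "\t", fixed = TRUE)[[1]]) >= 15L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
                              character(1))
    aspect <- c(P = "BP", F = "MF", C = "CC")
    df <- tibble(
      gene_name = get(3L),
      term_id = get(5L),
      term_label = get(5L),
      namespace = unname(aspect[get(9L)]),
      evidence_code = get(7L),
      taxon = sub("^taxon:", "", get(13L))
    )
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  }
  annotation_table(df)
}

#' Filter associations by evidence code
#'
#' Retains associations whose evidence code is in the whitelist (e.g.
#' experimental codes EXP, IDA, IPI, IMP, IGI, IEP).
#'
#' @param table An [annotation_table()].
#' @param whitelist Non-empty character vector of evidence codes.
#' @return The filtered `annotation_table`.
#' @export
filter_evidence <- function(table, whitelist) {
  stopifnot(inherits(table, "annotation_table"))
  if (length(whitelist) == 0L) abort("evidence whitelist must be non-empty")
  out <- table[table$evidence_code %in% whitelist, ]
  class(out) <- class(table)
  out
}

#' Merge annotation tables across taxa
#'
#' Unions association tables from several species (e.g. bovine plus human,
#' to benefit from the more complete human GO annotation). Taxon
#' provenance is retained on every row; a gene-term pair annotated in both
#' taxa keeps both rows but counts once in enrichment.
#'
#' @param tables List of [annotation_table()]s.
#' @return A merged `annotation_table`.
#' @export
merge_taxa <- function(tables) {
  stopifnot(is.list(tables), all(vapply(tables, inherits, logical(1), "annotation_table")))
  if (length(tables) == 0L) abort("at least one annotation table is required")
  annotation_table(dplyr::bind_rows(lapply(tables, as_tibble)))
}

#' Hypergeometric upper-tail probability
#'
#' Exact over-representation p-value: the probability of drawing at least
#' `x` annotated genes in a query of size `n` from a background of `N`
#' genes of which `K` carry the term,
#' `P(X >= x) = sum_{k=x}^{min(n,K)} C(K,k) C(N-K,n-k) / C(N,n)`.
#' The sum is accumulated in log space (log-binomials plus log-sum-exp) so
#' that large backgrounds do not underflow.
#'
#' @param x Observed query successes (0 <= x <= min(n, K)).
#' @param K Background genes carrying the term.
#' @param n Query size.
#' @param N Background size.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1/252
hypergeom_pvalue <- function(x, K, n, N) {
  stopifnot(length(x) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (K > N || n > N || x < 0 || x > min(n, K)) {
    abort("require 0 <= x <= min(n, K), K <= N, n <= N")
  }
  if (x == 0) return(1)
  k <- x:min(n, K)
  lt <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with sorted p-values p_(1) <=
#' ... <= p_(m), adjusted_(i) = min(1, min_{j >= i} p_(j) * m / j),
#' returned in the original order.
#'
#' @param p_values Numeric vector with all values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(scaled))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Over-representation analysis of a gene set
#'
#' Tests, per namespace, whether each term annotating at least one query
#' gene is over-represented relative to the background, using the exact
#' hypergeometric upper tail and Benjamini-Hochberg correction. The
#' effective universe within a namespace is the background genes carrying
#' at least one annotation in that namespace (logged on each run), so
#' unannotated genes do not dilute the test. Gene-term pairs duplicated
#' across taxa count once. Results significant at `p_adj < alpha` are
#' ranked by (p_adj, p_raw, term_id) and truncated to `top_k` per
#' namespace.
#'
#' @param query Character vector of gene names; must be a subset of
#'   `background`.
#' @param background Character vector of gene names (the universe before
#'   annotation filtering).
#' @param annotations An [annotation_table()].
#' @param alpha Significance threshold on the adjusted p-value (default 0.05).
#' @param top_k Maximum reported terms per namespace (default 50).
#' @param namespaces Namespaces to test (default BP, MF, CC).
#' @param adjust_within_namespace Adjust within each namespace separately
#'   (default) or globally across all tested terms.
#' @return Tibble of results: `term_id`, `term_label`, `namespace`, `x`,
#'   `K`, `n`, `N`, `p_raw`, `p_adj`, `rank`.
#' @export
enrich <- function(query, background, annotations, alpha = 0.05, top_k = 50,
                   namespaces = c("BP", "MF", "CC"),
                   adjust_within_namespace = TRUE) {
  stopifnot(inherits(annotations, "annotation_table"))
  query <- unique(normalize_gene_name(query))
  background <- unique(normalize_gene_name(background))
  if (!all(query %in% background)) {
    abort("query must be a subset of background")
  }
  empty <- tibble(term_id = character(), term_label = character(),
                  namespace = character(), x = integer(), K = integer(),
                  n = integer(), N = integer(), p_raw = numeric(),
                  p_adj = numeric(), rank = integer())
  ann <- dplyr::distinct(as_tibble(annotations), .data$gene_name, .data$term_id,
                         .keep_all = TRUE)
  per_ns <- lapply(namespaces, function(ns) {
    a <- ann[!is.na(ann$namespace) & ann$namespace == ns &
               ann$gene_name %in% background, ]
    if (nrow(a) == 0L) return(empty)  # namespace not annotated at all
    universe <- unique(a$gene_name)
    q <- intersect(query, universe)
    inform(sprintf("enrich [%s]: universe %d annotated background genes, %d annotated query genes",
                   ns, length(universe), length(q)))
    if (length(q) == 0L) {
      warn(sprintf("no annotated query genes in namespace %s", ns))
      return(empty)
    }
    counts <- a |>
      dplyr::group_by(.data$term_id, .data$term_label) |>
      dplyr::summarise(K = dplyr::n_distinct(.data$gene_name),
                       x = sum(unique(.data$gene_name) %in% q),
                       .groups = "drop") |>
      dplyr::filter(.data$x > 0L)
    counts$namespace <- ns
    counts$n <- length(q)
    counts$N <- length(universe)
    counts$p_raw <- purrr::pmap_dbl(counts[c("x", "K", "n", "N")], hypergeom_pvalue)
    counts
  })
  res <- dplyr::bind_rows(per_ns)
  if (nrow(res) == 0L) return(empty)
  if (adjust_within_namespace) {
    res <- res |>
      dplyr::group_by(.data$namespace) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p_raw)) |>
      dplyr::ungroup()
  } else {
    res$p_adj <- bh_adjust(res$p_raw)
  }
  res <- res[res$p_adj < alpha, ]
  res <- res |>
    dplyr::group_by(.data$namespace) |>
    dplyr::arrange(.data$p_adj, .data$p_raw, .data$term_id, .by_group = TRUE) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  res[c("term_id", "term_label", "namespace", "x", "K", "n", "N", "p_raw", "p_adj", "rank")]
}

#' Flag genes carrying a subcellular-location annotation
#'
#' Returns the subset of `genes` annotated with the given location term
#' (matched against term_id or term_label in the `location` namespace).
#'
#' @param genes Character vector of gene names.
#' @param annotations An [annotation_table()] including `location` rows.
#' @param location_term Term identifier or label, e.g. `"mitochondrion"`.
#' @return Sorted character vector (subset of `genes`).
#' @export
flag_subcellular <- function(genes, annotations, location_term) {
  stopifnot(inherits(annotations, "annotation_table"))
  loc <- annotations[!is.na(annotations$namespace) & annotations$namespace == "location", ]
  hit <- loc$term_id == location_term | loc$term_label == location_term
  if (nrow(loc) > 0L && !any(hit)) {
    abort(sprintf("unknown location term '%s'", location_term))
  }
  genes <- normalize_gene_name(genes)
  sort(intersect(genes, loc$gene_name[hit]))
}

#' Group genes into protein complexes
#'
#' @param genes Character vector of gene names.
#' @param annotations An [annotation_table()] including `complex` rows.
#' @return Named list, complex label -> sorted member genes (restricted to
#'   `genes`); complexes with no member among `genes` are omitted.
#' @export
assign_complexes <- function(genes, annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  genes <- normalize_gene_name(genes)
  cx <- annotations[!is.na(annotations$namespace) & annotations$namespace == "complex" &
                      annotations$gene_name %in% genes, ]
  if (nrow(cx) == 0L) return(setNames(list(), character()))
  out <- lapply(split(cx$gene_name, cx$term_label), function(g) sort(unique(g)))
  out[sort(names(out))]
}

#' Derive location annotations from protein-name text
#'
#' Builds a `location` annotation table by scanning free-text protein names
#' for a token (default `"mitochondrial"`), the way curated name suffixes
#' such as "..., mitochondrial" encode subcellular origin.
#'
#' @param genes,protein_names Parallel character vectors.
#' @param token Regular expression matched case-insensitively.
#' @param term_label Label given to the derived term.
#' @return An [annotation_table()] with one row per matching gene.
#' @export
locations_from_protein_names <- function(genes, protein_names,
                                         token = "mitochondrial",
                                         term_label = "mitochondrion") {
  stopifnot(length(genes) == length(protein_names))
  hit <- grepl(token, protein_names, ignore.case = TRUE)
  annotation_table(tibble(
    gene_name = genes[hit],
    term_id = paste0("LOC:", toupper(term_label)),
    term_label = term_label,
    namespace = "location",
    evidence_code = "name_scan",
    taxon = NA_character_
  ))
}

#' Derive protein-complex annotations from protein-name prefixes
#'
#' Groups genes whose protein names start with a known complex prefix
#' (case-insensitive), e.g. "ATP synthase ..." or "60S ribosomal protein ...".
#'
#' @param genes,protein_names Parallel character vectors.
#' @param prefixes Character vector of complex-name prefixes.
#' @return An [annotation_table()] with `complex` namespace rows.
#' @export
complexes_from_protein_names <- function(genes, protein_names,
                                         prefixes = c("ATP synthase",
                                                      "Cytochrome c oxidase",
                                                      "60S ribosomal protein")) {
  stopifnot(length(genes) == length(protein_names))
  rows <- purrr::map_dfr(prefixes, function(p) {
    hit <- startsWith(tolower(protein_names), tolower(p))
    tibble(gene_name = genes[hit],
           term_id = paste0("CPX:", toupper(gsub("[^A-Za-z0-9]+", "_", p))),
           term_label = p, namespace = "complex",
           evidence_code = "name_scan", taxon = NA_character_)
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(gene_name = character(), term_id = character(),
                   term_label = character(), namespace = character(),
                   evidence_code = character(), taxon = character())
  }
  annotation_table(rows)
}
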