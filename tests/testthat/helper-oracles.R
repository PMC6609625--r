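# Shared test helpers: tiny constructors and independent brute-force oracles.

tiny_mapping <- function(ids, genes, ...) {
  id_mapping_table(data.frame(raw_id = ids, gene_name = genes), ...)
}

# dataset record with gene names and classes set directly (bypasses ingestion)
ds <- function(id, genes, fraction = NA_character_, stage = NA_character_) {
  dataset_record(id, fraction_class = fraction, stage_class = stage,
                 gene_names = genes)
}

# element-wise membership oracle for Venn regions: for every element of the
# union, recompute its signature by direct set membership
oracle_regions <- function(sets) {
  cats <- sort(names(sets))
  universe <- sort(unique(unlist(sets)))
  sig <- vapply(universe, function(el) {
    paste(cats[vapply(sets[cats], function(s) el %in% s, logical(1))], collapse = "&")
  }, character(1))
  split(universe, sig)
}

# exhaustive hypergeometric upper tail: enumerate every n-subset of a
# universe whose first K elements are "successes"
oracle_hyper_tail <- function(x, K, n, N) {
  if (n == 0) return(as.numeric(x == 0))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= x)
}
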