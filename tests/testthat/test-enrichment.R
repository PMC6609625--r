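test_that("hypergeometric tail matches closed forms and rejects bad bounds", {
  expect_equal(hypergeom_pvalue(0, 3, 4, 10), 1)
  expect_equal(hypergeom_pvalue(0, 0, 0, 5), 1)
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_error(hypergeom_pvalue(6, 5, 5, 10), "require")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "require")
})

test_that("hypergeometric tail equals exhaustive enumeration for all N <= 12", {
  for (N in 2:12) {
    for (K in 0:N) {
      for (n in unique(c(0, 1, N %/% 2, N))) {
        xs <- unique(c(0, 1, min(n, K) %/% 2, min(n, K)))
        for (x in xs[xs <= min(n, K)]) {
          expect_equal(hypergeom_pvalue(x, K, n, N),
                       oracle_hyper_tail(x, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("x=%d K=%d n=%d N=%d", x, K, n, N))
        }
      }
    }
  }
})

test_that("hypergeometric tail agrees with the distribution function on larger cases", {
  set.seed(5)
  for (i in 1:50) {
    N <- sample(20:5000, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    x <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_pvalue(x, K, n, N),
                 stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # m = 4, sorted scaled values (.02, .018, .0667, .5); right-to-left cummin
  expect_equal(bh_adjust(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.2 / 3, 0.5), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("bh_adjust matches p.adjust and satisfies its defining properties", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # permutation equivariance
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
    # monotone raw order yields monotone adjusted order
    expect_false(is.unsorted(bh_adjust(sort(p))))
  }
})

# 20 genes, one term covering the first 5, one covering everything (so the
# annotated universe is the full background)
toy_annotation <- function() {
  genes <- sprintf("G%02d", 1:20)
  annotation_table(tibble::tibble(
    gene_name = c(genes[1:5], genes),
    term_id = c(rep("T:SMALL", 5), rep("T:ALL", 20)),
    term_label = c(rep("small", 5), rep("all", 20)),
    namespace = "BP", evidence_code = "IEA", taxon = "9913"
  ))
}

test_that("enrich reproduces closed-form p-values", {
  genes <- sprintf("G%02d", 1:20)
  ann <- toy_annotation()
  # query the exact carriers of the small term: p = 1 / C(20, 5)
  res <- suppressMessages(enrich(genes[1:5], genes, ann, alpha = 0.05))
  expect_equal(res$term_id, "T:SMALL")
  expect_equal(res$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$x, 5L)
  expect_equal(res$K, 5L)
  expect_equal(res$N, 20L)
  # query = background: every term has p_raw = 1, nothing reported
  res_all <- suppressMessages(enrich(genes, genes, ann))
  expect_equal(nrow(res_all), 0L)
  # singleton query: p_raw = K / N for each of its terms
  res_one <- suppressMessages(enrich(genes[1], genes, ann, alpha = 1.01))
  expect_equal(res_one$p_raw[res_one$term_id == "T:SMALL"], 5 / 20, tolerance = 1e-12)
  expect_equal(res_one$p_raw[res_one$term_id == "T:ALL"], 1, tolerance = 1e-12)
})

test_that("enrich validates the query and warns on unannotated queries", {
  ann <- toy_annotation()
  expect_error(suppressMessages(enrich("ZZZ", "G01", ann)), "subset")
  expect_warning(
    r <- suppressMessages(enrich("H1", c("H1", sprintf("G%02d", 1:20)), ann)),
    "no annotated"
  )
  expect_equal(nrow(r), 0L)
})

test_that("a planted enriched term ranks first in nearly all simulated queries", {
  set.seed(123)
  n_bg <- 200
  genes <- sprintf("B%03d", seq_len(n_bg))
  planted <- genes[1:20]
  rows <- tibble::tibble(gene_name = planted, term_id = "T:PLANT", term_label = "planted")
  for (j in 1:10) {
    rows <- rbind(rows, tibble::tibble(gene_name = sample(genes, 20),
                                       term_id = sprintf("T:R%02d", j),
                                       term_label = sprintf("rand%02d", j)))
  }
  rows <- rbind(rows, tibble::tibble(gene_name = genes, term_id = "T:ALL",
                                     term_label = "all"))
  ann <- annotation_table(transform(rows, namespace = "BP",
                                    evidence_code = "IEA", taxon = "9913"))
  top_hits <- 0L
  for (i in 1:200) {
    query <- c(sample(planted, 8), sample(setdiff(genes, planted), 2))
    res <- suppressMessages(enrich(query, genes, ann, alpha = 0.05))
    if (nrow(res) > 0 && res$term_id[res$rank == 1] == "T:PLANT") top_hits <- top_hits + 1L
  }
  expect_gte(top_hits / 200, 0.95)
})

test_that("evidence filtering keeps exactly the whitelisted rows", {
  set.seed(3)
  codes <- c("EXP", "IDA", "IEA", "ISS", "TAS")
  df <- tibble::tibble(
    gene_name = sprintf("G%02d", 1:40), term_id = sprintf("T%02d", 1:40),
    term_label = "t", namespace = "BP",
    evidence_code = sample(codes, 40, replace = TRUE), taxon = "9913"
  )
  ann <- annotation_table(df)
  expect_identical(tibble::as_tibble(filter_evidence(ann, codes)),
                   tibble::as_tibble(ann))
  kept <- filter_evidence(ann, c("EXP", "IDA"))
  expect_identical(tibble::as_tibble(kept),
                   tibble::as_tibble(ann)[ann$evidence_code %in% c("EXP", "IDA"), ])
  expect_error(filter_evidence(ann, character()), "non-empty")
})

test_that("merge_taxa unions associations and keeps taxon provenance", {
  bov <- annotation_table(tibble::tibble(gene_name = "G1", term_id = "t1",
                                         term_label = "t1", namespace = "BP",
                                         evidence_code = "IEA", taxon = "9913"))
  hum <- annotation_table(tibble::tibble(gene_name = c("G1", "G1"),
                                         term_id = c("t2", "t1"),
                                         term_label = c("t2", "t1"), namespace = "BP",
                                         evidence_code = "IEA", taxon = "9606"))
  empty <- annotation_table(bov[0, ])
  expect_identical(tibble::as_tibble(merge_taxa(list(bov, empty))),
                   tibble::as_tibble(bov))
  merged <- merge_taxa(list(bov, hum))
  expect_setequal(merged$term_id[merged$gene_name == "G1"], c("t1", "t2"))
  # t1 present in both taxa: both provenance rows survive ...
  expect_equal(sum(merged$term_id == "t1"), 2L)
  # ... but it counts once in enrichment contingency tables
  res <- suppressMessages(enrich("G1", "G1", merged, alpha = 1.01))
  expect_equal(res$K[res$term_id == "t1"], 1L)
})

test_that("GAF and simplified TSV annotation files parse to the same model", {
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("UniProtKB", "P12345", "ACAT1", "", "GO:0004813", "PMID:1", "IDA", "",
          "P", "Acetyl-CoA acetyltransferase", "", "protein", "taxon:9913",
          "20190101", "UniProt", "", "", sep = "\t"),
    paste("UniProtKB", "P67890", "SDHA", "", "GO:0006099", "PMID:2", "IEA", "",
          "C", "Succinate dehydrogenase", "", "protein", "taxon:9606",
          "20190101", "UniProt", "", "", sep = "\t")
  ), gaf)
  ann <- read_annotations(gaf)
  expect_equal(ann$gene_name, c("ACAT1", "SDHA"))
  expect_equal(ann$namespace, c("BP", "CC"))
  expect_equal(ann$evidence_code, c("IDA", "IEA"))
  expect_equal(ann$taxon, c("9913", "9606"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_name\tterm_id\tterm_label\tnamespace\tevidence_code\ttaxon",
               "ACAT1\tGO:0004813\tthiolase activity\tMF\tIDA\t9913"), tsv)
  ann2 <- read_annotations(tsv)
  expect_equal(ann2$term_label, "thiolase activity")
  expect_equal(ann2$namespace, "MF")
})

test_that("mitochondrial flagging and complex grouping work on the fixture", {
  t1 <- early_milk_proteins()
  loc <- locations_from_protein_names(t1$gene_name, t1$protein_name)
  mito <- flag_subcellular(t1$gene_name, loc, "mitochondrion")
  expect_equal(length(mito), 15L)
  expect_true(all(c("ACAT1", "IVD", "PCK2", "SDHA", "UQCRC1", "C1QBP",
                    "GPAM", "NDUFAB1") %in% mito))
  expect_equal(flag_subcellular(character(), annotation_table(loc[0, ]), "x"), character())
  expect_error(flag_subcellular(t1$gene_name, loc, "nucleus"), "unknown")
  # flagging the flagged set is the identity
  expect_equal(flag_subcellular(mito, loc, "mitochondrion"), mito)

  cpx <- complexes_from_protein_names(t1$gene_name, t1$protein_name)
  groups <- assign_complexes(t1$gene_name, cpx)
  expect_equal(lengths(groups)[["ATP synthase"]], 4L)
  expect_equal(lengths(groups)[["Cytochrome c oxidase"]], 3L)
  expect_equal(lengths(groups)[["60S ribosomal protein"]], 5L)
  expect_equal(sum(lengths(groups)), 12L)
  expect_equal(assign_complexes("ACAT1", annotation_table(loc[0, ])),
               setNames(list(), character()))
})

test_that("complex grouping equals a row-by-row grouping oracle on random tables", {
  set.seed(21)
  genes <- sprintf("G%02d", 1:30)
  df <- tibble::tibble(
    gene_name = sample(genes, 50, replace = TRUE),
    term_id = sample(sprintf("CPX:%d", 1:5), 50, replace = TRUE)
  )
  df$term_label <- sub("CPX:", "complex ", df$term_id)
  df$namespace <- "complex"
  ann <- annotation_table(df)
  got <- assign_complexes(genes, ann)
  dedup <- unique(df[c("gene_name", "term_label")])
  want <- lapply(split(dedup$gene_name, dedup$term_label), function(g) sort(unique(g)))
  expect_identical(got, want[sort(names(want))])
})
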