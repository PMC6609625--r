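small_cfg <- function(...) {
  synthetic_config(n_proteins = 200, categories = c("a", "b", "c"),
                   dimension = "stage_class", n_datasets_per_category = 2,
                   core_size = 20, exclusive_per_category = 15, ...)
}

test_that("simulation is fully reproducible from its seed", {
  s1 <- simulate_detection(small_cfg(seed = 5))
  s2 <- simulate_detection(small_cfg(seed = 5))
  expect_identical(s1$id_lists, s2$id_lists)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_detection(small_cfg(seed = 6))
  expect_false(identical(s1$id_lists, s3$id_lists))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_proteins = 10, core_size = 5,
                                exclusive_per_category = 5,
                                categories = c("a", "b")), "infeasible")
  expect_error(small_cfg(p_detect = 0), "p_detect")
  expect_error(small_cfg(synonym_prob = 0.8, unmapped_prob = 0.5), "sum")
  cfg <- synthetic_config(categories = list(fraction_class = c("x", "y")),
                          core_size = 5, exclusive_per_category = 5,
                          n_proteins = 50)
  expect_equal(cfg$dimension, "fraction_class")
})

test_that("truth sets are disjoint and the degenerate empty design works", {
  sim <- simulate_detection(small_cfg(seed = 2))
  all_planted <- unlist(sim$truth$planted)
  expect_false(anyDuplicated(all_planted) > 0)
  expect_equal(intersect(all_planted, sim$truth$core), character())

  empty <- simulate_detection(synthetic_config(n_proteins = 0, core_size = 0,
                                               exclusive_per_category = 0,
                                               categories = c("a", "b"),
                                               n_datasets_per_category = 1))
  expect_true(all(lengths(empty$id_lists) == 0))
  expect_equal(empty$truth$core, character())
})

test_that("exclusive-set recovery is exact under perfect detection and no ID noise", {
  for (seed in 1:3) {
    sim <- simulate_detection(small_cfg(p_detect = 1, synonym_prob = 0,
                                        unmapped_prob = 0, seed = seed))
    rep <- recovery_report(sim, recover_exclusives(sim))
    expect_true(all(rep$precision == 1), label = paste("seed", seed))
    expect_true(all(rep$recall == 1), label = paste("seed", seed))
    # the all-categories region contains the core
    atlas <- atlas_from_simulation(sim)
    p <- venn_regions(category_union_sets(atlas, "stage_class"))
    all_sig <- paste(sort(sim$config$categories), collapse = "&")
    expect_true(all(sim$truth$core %in% p$regions[[all_sig]]))
  }
})

test_that("mean per-protein recovery tracks the closed-form detection probability", {
  # a truly-exclusive protein is recovered iff detected in >= 1 of its
  # category's D datasets: P = 1 - (1 - p_detect)^D
  p_closed <- 1 - (1 - 0.9)^3
  recalls <- vapply(1:20, function(seed) {
    sim <- simulate_detection(
      synthetic_config(n_proteins = 300, categories = letters[1:5],
                       n_datasets_per_category = 3, core_size = 30,
                       exclusive_per_category = 40, p_detect = 0.9,
                       synonym_prob = 0, unmapped_prob = 0, seed = seed)
    )
    mean(recovery_report(sim, recover_exclusives(sim))$recall)
  }, numeric(1))
  expect_lt(abs(mean(recalls) - p_closed), 0.03)
})

test_that("atlas provenance reconciles exactly with generated unmapped emissions", {
  sim <- simulate_detection(small_cfg(unmapped_prob = 0.2, synonym_prob = 0.1, seed = 9))
  expect_gt(sum(sim$truth$unmapped_counts), 0)
  atlas <- atlas_from_simulation(sim)
  got <- setNames(atlas$provenance$n_unmapped, atlas$provenance$dataset_id)
  expect_equal(got[names(sim$truth$unmapped_counts)], sim$truth$unmapped_counts)
})

test_that("recovery_report conventions: empty denominators count as perfect", {
  truth <- list(exclusives = list(a = character(), b = c("G1", "G2")))
  rep <- recovery_report(truth, list(a = character(), b = "G1"))
  expect_equal(rep$precision, c(1, 1))
  expect_equal(rep$recall, c(1, 0.5))
  expect_error(recovery_report(truth, list(a = character(), z = "G1")), "labels")
})

test_that("synonym identifiers map back to the same gene set", {
  sim_noisy <- simulate_detection(small_cfg(p_detect = 1, synonym_prob = 0.5,
                                            unmapped_prob = 0, seed = 4))
  sim_clean <- simulate_detection(small_cfg(p_detect = 1, synonym_prob = 0,
                                            unmapped_prob = 0, seed = 4))
  expect_identical(unique_proteins(atlas_from_simulation(sim_noisy)),
                   unique_proteins(atlas_from_simulation(sim_clean)))
})
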