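test_that("classify_stage maps DIM and drying-off days to the five stages", {
  expect_equal(classify_stage(dim = 3), "colostrum")
  expect_equal(classify_stage(dim = 5), "colostrum")
  expect_equal(classify_stage(dim = 6), "early")
  expect_equal(classify_stage(dim = 10), "early")
  expect_equal(classify_stage(dim = 21), "early")
  expect_equal(classify_stage(dim = 22), "peak")
  expect_equal(classify_stage(dim = 80), "peak")
  expect_equal(classify_stage(dim = 81), "mid")
  expect_equal(classify_stage(dim = 300), "mid")
  expect_equal(classify_stage(dryoff_day = 3), "drying_off")
  expect_equal(classify_stage(dryoff_day = 8), "drying_off")
})

test_that("classify_stage rejects invalid inputs", {
  expect_error(classify_stage(dim = 5, dryoff_day = 3), "exactly one")
  expect_error(classify_stage(), "exactly one")
  expect_error(classify_stage(dim = -1), "non-negative")
  expect_error(classify_stage(dryoff_day = -2), "non-negative")
})

test_that("every non-negative DIM maps to exactly one stage (totality)", {
  stages <- vapply(0:200, function(d) classify_stage(dim = d), character(1))
  expect_true(all(stages %in% stage_levels()))
  # boundaries partition the axis: class changes exactly at the rule edges
  expect_equal(which(stages[-1] != stages[-length(stages)]), c(6, 22, 81))
})

test_that("stage_rules rejects gappy or overlapping intervals", {
  expect_error(stage_rules(early_range = c(7, 21)), "cover")
  expect_error(stage_rules(peak_range = c(20, 80)), "cover")
  r <- stage_rules(colostrum_max_dim = 3, early_range = c(4, 30),
                   peak_range = c(31, 90), mid_min_dim = 91)
  expect_equal(classify_stage(dim = 4, rules = r), "early")
  expect_equal(classify_stage(dim = 90, rules = r), "peak")
})

test_that("classify_fraction follows technique precedence and the g-force split", {
  expect_equal(
    classify_fraction(isolation_descriptor("centrifugation", 50000, acidification = TRUE)),
    "skimmed"
  )
  expect_equal(classify_fraction(isolation_descriptor("sucrose_gradient")), "exosomes")
  expect_equal(classify_fraction(isolation_descriptor("ultracentrifugation", 150000)), "whey")
  expect_equal(classify_fraction(isolation_descriptor("cream_separation")), "MFGM")
  # threshold itself pellets caseins -> whey; just below -> skimmed
  expect_equal(classify_fraction(isolation_descriptor("centrifugation", 100000)), "whey")
  expect_equal(classify_fraction(isolation_descriptor("centrifugation", 99999)), "skimmed")
  # sucrose gradient wins even though it involves centrifugation
  expect_equal(classify_fraction(isolation_descriptor("sucrose_gradient", 150000)), "exosomes")
  # depletion flags never change the class
  expect_equal(
    classify_fraction(isolation_descriptor("ultracentrifugation", 150000,
                                           acidification = TRUE,
                                           major_protein_depletion = TRUE)),
    "whey"
  )
  expect_error(classify_fraction(isolation_descriptor("centrifugation")), "g-force")
  expect_error(isolation_descriptor("centrifugation", max_g = -5), "> 0")
})

test_that("classification reproduces the curated classes of all 35 datasets", {
  manifest <- milk_dataset_manifest()
  expect_equal(nrow(manifest), 35L)
  reclassified <- classify_manifest(manifest)
  expect_identical(reclassified$stage_class, manifest$stage_class)
  expect_identical(reclassified$fraction_class, manifest$fraction_class)
  # the curated design: 14 skimmed, 13 whey, 4 MFGM, 4 exosome datasets
  expect_mapequal(as.list(table(reclassified$fraction_class)),
                  list(exosomes = 4L, MFGM = 4L, skimmed = 14L, whey = 13L))
  expect_mapequal(as.list(table(reclassified$stage_class)),
                  list(colostrum = 12L, drying_off = 2L, early = 7L, mid = 8L, peak = 6L))
})
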