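toy_bundles <- function() {
  bundle_table(
    region_a = c("r1", "r1", "r3"),
    region_b = c("r2", "r3", "r4"),
    tracts = list(c("t1"), c("t2", "t3"), c("t1", "t3")),
    weight = c(2.0, 5.0, 1.5),
    region_universe = paste0("r", 1:4),
    tract_universe = paste0("t", 1:3)
  )
}

test_that("pattern weight sums bundles inside the pattern exactly once", {
  bt <- toy_bundles()
  # pattern covering exactly bundle 2
  expect_equal(pattern_weight(bt, c("r1", "r3"), c("t2")), 5.0)
  # bundle 3 traverses two pattern tracts but counts once
  expect_equal(pattern_weight(bt, c("r3", "r4"), c("t1", "t3")), 1.5)
  expect_equal(pattern_weight(bt, character(0), c("t1")), 0)
  expect_error(pattern_weight(bt, c("r9"), c("t1")), "r9")
  expect_error(pattern_weight(bt, c("r1"), c("t9")), "t9")
})

test_that("pattern weight matches a brute-force row scan on random tables", {
  out <- generate_bundle_table(n_regions = 12, n_tracts = 6,
                               planted_pattern = list(regions = 1:3, tracts = 1:2),
                               enrichment = 3, seed = 7, n_bundles = 150)
  bt <- out$bundles
  set.seed(8)
  for (i in 1:10) {
    regions <- sample(bt$region_universe, 4)
    tracts <- sample(bt$tract_universe, 2)
    brute <- 0
    for (b in seq_along(bt$weight)) {
      if (bt$region_a[b] %in% regions && bt$region_b[b] %in% regions &&
          any(bt$tracts[[b]] %in% tracts)) {
        brute <- brute + bt$weight[b]
      }
    }
    expect_equal(pattern_weight(bt, regions, tracts), brute, tolerance = 1e-12)
  }
})

test_that("pattern weight is monotone in both label sets", {
  out <- generate_bundle_table(n_regions = 10, n_tracts = 5,
                               planted_pattern = list(regions = 1:2, tracts = 1:2),
                               enrichment = 1, seed = 9, n_bundles = 100)
  bt <- out$bundles
  r_small <- bt$region_universe[1:3]; r_big <- bt$region_universe[1:6]
  t_small <- bt$tract_universe[1:2]; t_big <- bt$tract_universe[1:4]
  expect_lte(pattern_weight(bt, r_small, t_small), pattern_weight(bt, r_big, t_small))
  expect_lte(pattern_weight(bt, r_small, t_small), pattern_weight(bt, r_small, t_big))
})

test_that("monte carlo null converges to the exhaustive null on a small universe", {
  set.seed(10)
  bt <- bundle_table(
    region_a = sample(paste0("r", 1:4), 40, replace = TRUE),
    region_b = sample(paste0("r", 1:4), 40, replace = TRUE),
    tracts = replicate(40, sample(paste0("t", 1:3), sample(1:2, 1)), simplify = FALSE),
    weight = rlnorm(40),
    region_universe = paste0("r", 1:4),
    tract_universe = paste0("t", 1:3)
  )
  pattern <- list(regions = c("r1", "r2"), tracts = "t2")
  ex <- exhaustive_pattern_null(bt, pattern)
  expect_equal(ex$n_patterns, choose(4, 2) * choose(3, 1))
  mc <- random_pattern_null(bt, pattern, B = 10000, seed = 11)
  expect_lt(abs(mc$p - ex$p_exact), 0.02)
})

test_that("p-values respect the counting convention and seed determinism", {
  # a single dominant bundle on a large universe: the chance a random
  # size-matched pattern covers it is ~1e-5, so the observed weight exceeds
  # every null draw and p hits the floor 1/(B+1)
  regions <- sprintf("R%02d", 1:68)
  tracts <- sprintf("T%02d", 1:48)
  bt_enriched <- bundle_table(
    region_a = c("R01", "R05", "R09"), region_b = c("R02", "R06", "R10"),
    tracts = list("T01", "T02", "T03"), weight = c(1e6, 1, 1),
    region_universe = regions, tract_universe = tracts
  )
  res <- random_pattern_null(bt_enriched, list(regions = c("R01", "R02"), tracts = "T01"),
                             B = 500, seed = 12)
  expect_equal(res$p, 1 / 501)
  res2 <- random_pattern_null(bt_enriched, list(regions = c("R01", "R02"), tracts = "T01"),
                              B = 500, seed = 12)
  expect_identical(res$null, res2$null)
  expect_error(
    random_pattern_null(toy_bundles(), list(regions = paste0("r", 1:9), tracts = "t1"), B = 10),
    "larger than")
})

test_that("bundle tables round-trip through TSV", {
  out <- generate_bundle_table(n_regions = 10, n_tracts = 5,
                               planted_pattern = list(regions = 1:2, tracts = 1:2),
                               enrichment = 2, seed = 13, n_bundles = 50)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_bundle_table(out$bundles, tmp)
  back <- read_bundle_table(tmp, region_universe = out$bundles$region_universe,
                            tract_universe = out$bundles$tract_universe)
  expect_equal(back$weight, out$bundles$weight, tolerance = 1e-12)
  expect_identical(back$region_a, out$bundles$region_a)
  expect_identical(back$tracts, out$bundles$tracts)
})

test_that("the shipped atlas label sets have the expected sizes", {
  expect_length(dk_labels(), 68)
  expect_length(jhu_labels(), 48)
  expect_false(anyDuplicated(dk_labels()) > 0)
  expect_false(anyDuplicated(jhu_labels()) > 0)
})
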