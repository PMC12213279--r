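test_that("procrustes alignment of a solution to itself is the identity", {
  model <- fit_mbplsc(assemble_multiblock(toy_dataset(n_per_group = 10, p = 4, q = 3, c = 1, seed = 1)))
  al <- align_to_model(model, model$u, model$v, model$sigma)
  expect_lt(max(abs(al$sigma - model$sigma)), 1e-12)
  expect_lt(max(abs(al$u - model$u)), 1e-10)
  expect_lt(max(abs(al$v - model$v)), 1e-10)
})

test_that("procrustes undoes an artificial rotation of the singular vectors", {
  model <- fit_mbplsc(assemble_multiblock(toy_dataset(n_per_group = 12, p = 5, q = 4, c = 0, seed = 2)))
  k <- model$n_components
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  al <- align_to_model(model, model$u %*% Q, model$v %*% Q, rep(1, k))
  # rotated-back right vectors match the originals
  expect_lt(max(abs(al$v - model$v)), 1e-8)
})

test_that("permutation p-values honor the add-one counting convention", {
  gen <- generate_dataset(small_synth(seed = 4))
  cfg <- analysis_config(n_permutations = 199, seed = 4)
  res <- permutation_test(gen$dataset, cfg)
  expect_equal(res$p_omnibus, 1 / 200)   # planted coupling beats every permutation
  expect_true(all(res$p_components >= 1 / 200 & res$p_components <= 1))
  expect_lte(res$p_components[1], 0.05)
  # reproducible under the same seed
  res2 <- permutation_test(gen$dataset, cfg)
  expect_identical(res$p_omnibus, res2$p_omnibus)
  expect_identical(res$null_inertia, res2$null_inertia)
})

test_that("bootstrap salience CIs separate planted from null loadings", {
  gen <- generate_dataset(small_synth(seed = 5, diff_effect = 0))
  cfg <- analysis_config(n_bootstrap = 300, seed = 5)
  model <- fit_mbplsc(assemble_multiblock(gen$dataset, cfg))
  m <- match_planted(model, gen$truth$gm_saliences$shared, gen$truth$wm_saliences$shared)
  boot <- bootstrap_saliences(gen$dataset, cfg, model, components = m$component)
  expect_false(boot$unreliable)
  tab <- boot$table
  gm_rows <- tab[tab$side == "left" & tab$block == "gm" & tab$group == "HC", ]
  truth <- gen$truth$gm_saliences$shared$HC
  planted <- truth[match(gm_rows$variable, sprintf("gm_%03d", seq_along(truth)))] != 0
  expect_gte(mean(gm_rows$significant[planted]), 0.8)     # sensitivity
  # specificity: 95% CIs leave each null loading a ~5% false-positive
  # chance, so allow a few of the 16 null entries to be flagged
  expect_gte(mean(!gm_rows$significant[!planted]), 0.75)
  # flags consistent with the CI bounds
  expect_identical(tab$significant, tab$lower > 0 | tab$upper < 0)
})

test_that("tiny bootstrap runs are flagged unreliable", {
  ds <- toy_dataset(n_per_group = 8, p = 3, q = 2, c = 0, seed = 6)
  boot <- bootstrap_saliences(ds, analysis_config(n_bootstrap = 2, seed = 6))
  expect_true(boot$unreliable)
  expect_true(all(c("lower", "upper") %in% names(boot$table)))
})

test_that("bootstrap SD tracks the true sampling variability of a salience", {
  # singular-vector point estimates carry an attenuation bias at modest n
  # (component mixing), so percentile CIs need not cover the population
  # value at the nominal rate; the property the bootstrap must deliver is
  # that its SD estimates the sampling SD of the estimator. Disjoint
  # cohorts drawn from one large pool (same planting seed, hence the same
  # population loading vectors) provide independent replications.
  plant_seed <- 314L
  reps <- 25L; n_cohort <- 40L
  pool <- generate_dataset(synth_config(
    n_per_group = reps * n_cohort, p = 10L, q = 8L, seed = plant_seed,
    diff_effect = 0, cognition_link = c(0, 0),
    age_effect = 0, sex_tiv_effect = 0))
  big_model <- fit_mbplsc(assemble_multiblock(pool$dataset))
  m_big <- match_planted(big_model, pool$truth$gm_saliences$shared,
                         pool$truth$wm_saliences$shared)
  ref_u <- big_model$u[, m_big$component]
  target <- which.max(abs(ref_u))

  ests <- numeric(reps); bsds <- numeric(reps)
  for (s in seq_len(reps)) {
    take <- unlist(lapply(levels(pool$dataset$group), function(g) {
      which(pool$dataset$group == g)[((s - 1) * n_cohort + 1):(s * n_cohort)]
    }))
    ds <- subset_participants(pool$dataset, take)
    cfg <- analysis_config(n_bootstrap = 150, seed = 500 + s)
    model <- fit_mbplsc(assemble_multiblock(ds, cfg))
    cong <- vapply(seq_len(model$n_components),
                   function(i) tucker_congruence(ref_u, model$u[, i]), numeric(1))
    comp <- which.max(abs(cong))
    boot <- bootstrap_saliences(ds, cfg, model, components = comp)
    row <- boot$table[boot$table$side == "left", ][target, ]
    ests[s] <- sign(cong[comp]) * row$estimate
    bsds[s] <- row$boot_sd
  }
  # estimates scatter around a common (attenuated) center with the
  # bootstrap SD matching their empirical SD to well within a factor of 2
  ratio <- stats::median(bsds) / stats::sd(ests)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  # and every cohort identifies the planted entry with the right sign
  expect_true(all(ests > 0) || all(ests < 0))
})

test_that("NSSD is zero at equality, antisymmetric, and matches the hand case", {
  expect_equal(nssd_vectors(c(0.6, 0.8), c(0.8, 0.6)), c(-0.2, 0.2), tolerance = 1e-12)
  expect_equal(nssd_vectors(c(0.3, 0.4), c(0.3, 0.4)), c(0, 0))
  v1 <- c(0.1, -0.5, 0.2); v2 <- c(-0.3, 0.2, 0.6)
  expect_equal(nssd_vectors(v1, v2), -nssd_vectors(v2, v1))

  model <- fit_mbplsc(assemble_multiblock(toy_dataset(n_per_group = 10, seed = 7)))
  expect_equal(nssd(model, 1, c("A", "B")), -nssd(model, 1, c("B", "A")))
  expect_error(nssd(model, 1, c("A", "Z")), "unknown group")
})

test_that("salience trajectories vanish for noiseless rank-1 data", {
  ds <- rank1_dataset(n_per_group = 20, p = 4, q = 3, seed = 8)
  cfg <- analysis_config(n_min = 8, n_orderings = 3, seed = 8)
  tr <- convergence_trajectory(ds, cfg, component = 1)
  expect_equal(tr$n_grid, 8:19)
  expect_lt(max(tr$left), 1e-8)
  expect_lt(max(tr$right), 1e-8)
})

test_that("salience trajectories shrink with sample size on planted data", {
  gen <- generate_dataset(synth_config(n_per_group = 45L, p = 12L, q = 8L, seed = 9,
                                       diff_effect = 0, cognition_link = c(0, 0)))
  cfg <- analysis_config(n_min = 10, n_orderings = 4, seed = 9)
  tr <- convergence_trajectory(gen$dataset, cfg, component = 1)
  early <- mean(tr$left[, tr$n_grid <= 14])
  late <- mean(tr$left[, tr$n_grid >= 40])
  expect_lt(late, early)
  expect_true(all(is.finite(tr$left)) && all(is.finite(tr$right)))
})

test_that("monte carlo cross-validation recovers planted generalisability", {
  gen <- generate_dataset(small_synth(seed = 10, diff_effect = 0))
  cfg <- analysis_config(n_splits = 30, train_fraction = 0.75, seed = 10)
  cv <- monte_carlo_cv(gen$dataset, cfg, component = 1)
  expect_equal(nrow(cv$splits), 30 * 2)
  expect_true(all(abs(cv$splits$r) <= 1))
  expect_true(all(cv$summary$mean_r > 0))
  expect_true(all(cv$summary$generalisable))

  # single split: summary equals that split, SD undefined
  cfg1 <- analysis_config(n_splits = 1, train_fraction = 0.75, seed = 11)
  cv1 <- monte_carlo_cv(gen$dataset, cfg1, component = 1)
  expect_equal(cv1$summary$mean_r, cv1$splits$r[match(cv1$summary$group, cv1$splits$group)])
  expect_true(all(is.na(cv1$summary$sd_r)))
})

test_that("out-of-sample projection is exact on the training set and recovers sign", {
  gen <- generate_dataset(small_synth(seed = 12, diff_effect = 0))
  model <- fit_mbplsc(assemble_multiblock(gen$dataset))
  sc_in <- participant_scores(model, gen$dataset, 1)
  proj <- out_of_sample_projection(model, gen$dataset, 1)
  sc_proj <- attr(proj, "scores")
  expect_lt(max(abs(sc_in$gm_score - sc_proj$gm_score)), 1e-12)

  # a fresh cohort from the same process shows the planted positive coupling
  gen2 <- generate_dataset(small_synth(seed = 13, diff_effect = 0))
  proj2 <- out_of_sample_projection(model, gen2$dataset, 1)
  expect_true(all(proj2$r > 0))

  ds_bad <- gen2$dataset
  colnames(ds_bad$wm)[1] <- "other"
  expect_error(out_of_sample_projection(model, ds_bad, 1), "alignment")
})
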