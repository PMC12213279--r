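# in-code fixture builders shared across test files

# unstructured random two-group dataset
toy_dataset <- function(n_per_group = 10, p = 3, q = 2, c = 1, k = 0,
                        seed = 1, groups = c("A", "B")) {
  set.seed(seed)
  N <- 2 * n_per_group
  gm <- matrix(rnorm(N * p), N, p, dimnames = list(NULL, paste0("gm", seq_len(p))))
  wm <- matrix(rnorm(N * q), N, q, dimnames = list(NULL, paste0("wm", seq_len(q))))
  cov <- matrix(rnorm(N * c), N, c, dimnames = list(NULL, if (c > 0) paste0("cov", seq_len(c))))
  cog <- matrix(rnorm(N * k), N, k, dimnames = list(NULL, if (k > 0) paste0("cog", seq_len(k))))
  feature_dataset(
    participant_id = sprintf("p%03d", seq_len(N)),
    group = rep(groups, each = n_per_group),
    gm = gm, wm = wm, covariates = cov, cognition = cog,
    wm_is_fa = FALSE
  )
}

# exactly rank-1 noiseless coupling, no covariates: every gm/wm column is a
# multiple of one latent factor, so all correlation entries are +-1 exactly
rank1_dataset <- function(n_per_group = 20, p = 4, q = 3, seed = 1) {
  set.seed(seed)
  N <- 2 * n_per_group
  t_sh <- rnorm(N)
  w_gm <- sample(c(-1, 1), p, replace = TRUE) / sqrt(p)
  w_wm <- sample(c(-1, 1), q, replace = TRUE) / sqrt(q)
  gm <- tcrossprod(t_sh, w_gm)
  wm <- tcrossprod(t_sh, w_wm)
  colnames(gm) <- paste0("gm", seq_len(p))
  colnames(wm) <- paste0("wm", seq_len(q))
  feature_dataset(sprintf("p%03d", seq_len(N)), rep(c("A", "B"), each = n_per_group),
                  gm, wm, wm_is_fa = FALSE)
}

# reduced-size planted configuration for resampling tests
small_synth <- function(seed = 1, ...) {
  synth_config(n_per_group = 30L, p = 20L, q = 15L, seed = seed, ...)
}

# shared invariant checks applied to every fitted model in the suite
expect_model_invariants <- function(model, tol = 1e-10) {
  M <- model$mb$M
  recon <- model$u %*% diag(model$sigma, model$n_components) %*% t(model$v)
  expect_lt(max(abs(recon - M)), tol)
  expect_true(all(diff(model$sigma) <= 1e-12))
  expect_true(all(model$sigma >= -1e-12))
  expect_equal(sum(model$xi), 100, tolerance = 1e-11)
  expect_lt(max(abs(crossprod(model$u) - diag(model$n_components))), 1e-9)
  expect_lt(max(abs(crossprod(model$v) - diag(model$n_components))), 1e-9)
  nonzero <- model$sigma > 1e-8 * max(model$sigma)
  contrib_sums <- colSums(model$block_contributions[, nonzero, drop = FALSE])
  expect_equal(unname(contrib_sums), rep(100, sum(nonzero)), tolerance = 1e-9)
  invisible(model)
}

# locate the fitted component best matching a planted truth vector (stacked
# per-group gm layout) and return congruences
match_planted <- function(model, truth_gm_by_group, truth_wm,
                          max_components = 6L) {
  groups <- model$mb$groups
  target <- unlist(truth_gm_by_group[groups])
  congs <- vapply(seq_len(min(max_components, model$n_components)), function(i) {
    u_gm <- unlist(lapply(groups, function(g) gm_saliences(model, g, i)[, 1]))
    tucker_congruence(u_gm, target)
  }, numeric(1))
  best <- which.max(abs(congs))
  list(component = best,
       gm_congruence = abs(congs[best]),
       wm_congruence = abs(tucker_congruence(wm_saliences(model, best)[, 1], truth_wm)),
       cross_group = tucker_congruence(gm_saliences(model, groups[1], best)[, 1],
                                       gm_saliences(model, groups[2], best)[, 1]))
}
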