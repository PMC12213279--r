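test_that("correlation_block matches a brute-force per-pair loop", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  Y <- matrix(rnorm(40), 20, 2)
  A <- correlation_block(X, Y)
  brute <- matrix(NA_real_, 3, 2)
  for (i in 1:3) for (j in 1:2) brute[i, j] <- cor(X[, i], Y[, j])
  expect_lt(max(abs(A - brute)), 1e-12)

  # self-correlation diagonal and affine invariance
  expect_equal(diag(correlation_block(X, X)), rep(1, 3))
  Y2 <- cbind(2 * X[, 1] + 5, Y[, 2])
  expect_equal(correlation_block(X, Y2)[1, 1], 1, tolerance = 1e-12)

  # failure contracts
  expect_error(correlation_block(X, Y[1:10, ]), "row mismatch")
  Xz <- X; Xz[, 2] <- 7; colnames(Xz) <- c("a", "b", "c")
  expect_error(correlation_block(Xz, Y), "b")
})

test_that("multiblock assembly has the documented layout and index maps", {
  ds <- toy_dataset(n_per_group = 8, p = 3, q = 2, c = 1, seed = 5)
  mb <- assemble_multiblock(ds)
  expect_equal(dim(mb$M), c(2 * (3 + 1), 2 + 1))
  expect_equal(mb$row_map$block, rep(c(rep("gm", 3), "cov"), 2))
  expect_equal(mb$col_map$block, c("wm", "wm", "cov"))
  expect_true(all(abs(mb$M) <= 1 + 1e-12))

  # each block matches direct recomputation from group-standardized data
  for (g in c("A", "B")) {
    rows <- ds$group == g
    A_direct <- cor(ds$gm[rows, ], ds$wm[rows, ])
    block_rows <- which(mb$row_map$group == g & mb$row_map$block == "gm")
    expect_lt(max(abs(mb$M[block_rows, 1:2] - A_direct)), 1e-12)
  }

  # no covariates: M reduces to stacked GM-WM blocks
  ds0 <- toy_dataset(n_per_group = 8, p = 3, q = 2, c = 0, seed = 5)
  mb0 <- assemble_multiblock(ds0)
  expect_equal(dim(mb0$M), c(6, 2))

  # participant order within group is irrelevant
  perm <- c(sample(1:8), sample(9:16))
  mb_perm <- assemble_multiblock(subset_participants(ds, perm))
  expect_lt(max(abs(mb$M - mb_perm$M)), 1e-12)
})

test_that("rank-1 matrices recover their factors with the sign convention", {
  set.seed(8)
  a <- rnorm(6); a <- a / sqrt(sum(a^2))
  b <- rnorm(4); b <- b / sqrt(sum(b^2))
  mb <- structure(list(
    M = outer(a, b),
    row_map = data.frame(group = "G", variable = paste0("v", 1:6),
                         block = "gm", row = 1:6),
    col_map = data.frame(variable = paste0("w", 1:4), block = "wm", col = 1:4),
    groups = "G", p = 6, q = 4, c = 0,
    gm_names = paste0("v", 1:6), wm_names = paste0("w", 1:4),
    covariate_names = NULL, group_stats = list(),
    cor_method = "pearson", include_cov_cov = TRUE
  ), class = "multiblock_matrix")
  model <- fit_mbplsc(mb)
  expect_equal(model$sigma[1], 1, tolerance = 1e-10)
  expect_lt(max(model$sigma[-1]), 1e-10)
  s <- sign(a[which.max(abs(a))])
  expect_equal(model$u[, 1], s * a, tolerance = 1e-10)
  expect_equal(model$v[, 1], s * b, tolerance = 1e-10)
  expect_gt(model$u[which.max(abs(model$u[, 1])), 1], 0)
})

test_that("explained covariance follows the squared-singular-value formula", {
  # sigma = (2, 1, 1) -> xi = (66.67, 16.67, 16.67)
  M <- diag(c(2, 1, 1))
  mb <- structure(list(
    M = M,
    row_map = data.frame(group = "G", variable = paste0("v", 1:3), block = "gm", row = 1:3),
    col_map = data.frame(variable = paste0("w", 1:3), block = "wm", col = 1:3),
    groups = "G", p = 3, q = 3, c = 0,
    gm_names = paste0("v", 1:3), wm_names = paste0("w", 1:3),
    covariate_names = NULL, group_stats = list(),
    cor_method = "pearson", include_cov_cov = TRUE
  ), class = "multiblock_matrix")
  model <- fit_mbplsc(mb)
  expect_equal(model$xi, 100 * c(4, 1, 1) / 6, tolerance = 1e-9)
})

test_that("one group and no covariates reduce to plain PLS correlation", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30; p <- 8; q <- 5
    gm <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    wm <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("w", 1:q)))
    ds <- feature_dataset(sprintf("p%02d", 1:n), rep("G", n), gm, wm, wm_is_fa = FALSE)
    model <- fit_mbplsc(assemble_multiblock(ds))

    ref <- svd(cor(gm, wm))
    k <- min(p, q)
    for (i in seq_len(k)) {
      j <- which.max(abs(ref$u[, i]))
      if (ref$u[j, i] < 0) { ref$u[, i] <- -ref$u[, i]; ref$v[, i] <- -ref$v[, i] }
    }
    expect_lt(max(abs(model$sigma[1:k] - ref$d[1:k])), 1e-10)
    expect_lt(max(abs(model$u[, 1:k] - ref$u[, 1:k])), 1e-10)
    expect_lt(max(abs(model$v[, 1:k] - ref$v[, 1:k])), 1e-10)
  }
})

test_that("model invariants hold on assorted fitted models", {
  fits <- list(
    fit_mbplsc(assemble_multiblock(toy_dataset(n_per_group = 10, p = 4, q = 3, c = 2, seed = 1))),
    fit_mbplsc(assemble_multiblock(toy_dataset(n_per_group = 12, p = 5, q = 5, c = 0, seed = 2))),
    fit_mbplsc(assemble_multiblock(generate_dataset(small_synth(seed = 3))$dataset))
  )
  for (m in fits) expect_model_invariants(m)
})

test_that("multiplying a raw feature column by a constant changes nothing", {
  ds <- toy_dataset(n_per_group = 10, p = 4, q = 3, c = 1, seed = 6)
  ds2 <- ds
  ds2$gm[, 2] <- 1000 * ds2$gm[, 2]
  ds2$wm[, 1] <- 0.01 * ds2$wm[, 1]
  m1 <- fit_mbplsc(assemble_multiblock(ds))
  m2 <- fit_mbplsc(assemble_multiblock(ds2))
  expect_lt(max(abs(m1$mb$M - m2$mb$M)), 1e-12)
  expect_lt(max(abs(m1$u - m2$u)), 1e-9)
  s1 <- participant_scores(m1, ds, 1)
  s2 <- participant_scores(m2, ds2, 1)
  expect_equal(s1$gm_score, s2$gm_score, tolerance = 1e-9)
})

test_that("participant scores are centered projections excluding covariates", {
  ds <- toy_dataset(n_per_group = 10, p = 4, q = 3, c = 2, seed = 7)
  model <- fit_mbplsc(assemble_multiblock(ds))
  sc <- participant_scores(model, ds, 1:2)
  expect_equal(nrow(sc), 20 * 2)
  # group means of scores are zero (projection of centered data)
  for (g in c("A", "B")) {
    expect_lt(abs(mean(sc$gm_score[sc$group == g & sc$component == 1])), 1e-12)
    expect_lt(abs(mean(sc$wm_score[sc$group == g & sc$component == 1])), 1e-12)
  }
  # a dataset sitting at the group mean scores exactly zero
  at_mean <- ds
  for (g in c("A", "B")) {
    rows <- ds$group == g
    at_mean$gm[rows, ] <- matrix(colMeans(ds$gm[rows, ]), sum(rows), 4, byrow = TRUE)
    at_mean$wm[rows, ] <- matrix(colMeans(ds$wm[rows, ]), sum(rows), 3, byrow = TRUE)
  }
  sc0 <- participant_scores(model, at_mean, 1)
  expect_lt(max(abs(c(sc0$gm_score, sc0$wm_score))), 1e-12)

  # variable-name mismatch is an alignment error
  ds_bad <- ds
  colnames(ds_bad$gm)[1] <- "other"
  expect_error(participant_scores(model, ds_bad), "alignment")
})

test_that("pattern strength is the signed outer product of saliences", {
  expect_equal(pattern_strength(0.5, -0.4), matrix(-0.2, 1, 1))
  g <- c(0.5, 0, -0.3); w <- c(0.2, -0.1)
  ps <- pattern_strength(g, w)
  expect_equal(ps, outer(g, w))
  expect_true(all(ps[2, ] == 0))
})

test_that("in-sample score coupling is positive for a planted component", {
  gen <- generate_dataset(small_synth(seed = 10, diff_effect = 0))
  model <- fit_mbplsc(assemble_multiblock(gen$dataset))
  m <- match_planted(model, gen$truth$gm_saliences$shared, gen$truth$wm_saliences$shared)
  sc <- participant_scores(model, gen$dataset, m$component)
  for (g in c("HC", "ROP")) {
    sg <- sc[sc$group == g, ]
    expect_gt(cor(sg$gm_score, sg$wm_score), 0.3)
  }
})
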