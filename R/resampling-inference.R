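#' Orthogonal Procrustes rotation onto a reference
#'
#' Returns the orthogonal matrix R minimizing ||mat R - ref||_F (Schonemann
#' solution via SVD of mat' ref). Used to resolve the rotation and sign
#' indeterminacy of singular vectors across permutation and bootstrap
#' refits before accumulating null distributions or salience CIs.
#'
#' @param ref reference matrix (columns = components).
#' @param mat matrix to be rotated, same dimensions.
#' @return Orthogonal rotation matrix.
#' @export
procrustes_rotation <- function(ref, mat) {
  stopifnot(all(dim(ref) == dim(mat)))
  s <- svd(crossprod(mat, ref))
  s$u %*% t(s$v)
}

#' Align a resampled SVD solution to a reference model
#'
#' Rotates the resampled left/right singular vectors by the Procrustes
#' rotation of the resampled right singular vectors onto the reference
#' ones, and recomputes component-wise singular values as the column norms
#' of the rotated loading matrix U diag(sigma) R.
#'
#' @param model reference `mbplsc_model`.
#' @param u,v,sigma resampled decomposition (same dimensions as the
#'   reference).
#' @return list with rotated `u`, `v` and aligned `sigma`.
#' @export
align_to_model <- function(model, u, v, sigma) {
  R <- procrustes_rotation(model$v, v)
  L <- (u %*% diag(sigma, length(sigma))) %*% R
  list(u = u %*% R, v = v %*% R, sigma = sqrt(colSums(L^2)))
}

# --- internal fast refitting on pre-standardized blocks ------------------

# Standardize (and rank-transform for spearman) each group's blocks once;
# permutations within group leave marginals unchanged, so correlation
# blocks of permuted data are crossprod(z_x, z_y_perm) / (n - 1).
standardized_blocks <- function(ds, config) {
  out <- list()
  for (g in levels(ds$group)) {
    rows <- which(ds$group == g)
    zb <- list(rows = rows, n = length(rows))
    for (b in c("gm", "wm", "covariates")) {
      m <- ds[[b]][rows, , drop = FALSE]
      if (ncol(m) > 0) {
        if (config$cor_method == "spearman") m <- apply(m, 2, rank)
        m <- scale(m)
        if (any(!is.finite(m))) {
          stop(sprintf("zero-variance column in block '%s', group %s", b, g))
        }
      }
      zb[[b]] <- m
    }
    out[[g]] <- zb
  }
  out
}

stack_from_z <- function(zb_list, include_cov_cov, wm_rows_order = NULL) {
  blocks <- lapply(seq_along(zb_list), function(gi) {
    zb <- zb_list[[gi]]
    n <- zb$n
    wm <- zb$wm
    if (!is.null(wm_rows_order)) wm <- wm[wm_rows_order[[gi]], , drop = FALSE]
    A <- crossprod(zb$gm, wm) / (n - 1)
    if (ncol(zb$covariates) > 0) {
      B <- crossprod(zb$gm, zb$covariates) / (n - 1)
      D <- crossprod(zb$covariates, wm) / (n - 1)
      E <- if (include_cov_cov) crossprod(zb$covariates, zb$covariates) / (n - 1)
           else matrix(0, ncol(zb$covariates), ncol(zb$covariates))
      rbind(cbind(A, B), cbind(D, E))
    } else {
      A
    }
  })
  do.call(rbind, blocks)
}

#' Permutation test for the multiblock decomposition
#'
#' Breaks the grey-white pairing by shuffling participant rows of the
#' white-matter block (default scheme) within each group, refits, and
#' compares: the omnibus statistic is the total inertia (sum of squared
#' singular values of the stacked matrix); per-component statistics are the
#' permuted singular values after Procrustes alignment to the observed
#' solution. P-values use the (1 + k) / (1 + B) convention.
#'
#' @param ds a validated [feature_dataset()].
#' @param config an [analysis_config()]; uses `n_permutations`,
#'   `permutation_scheme`, `seed`, `cor_method`, `include_cov_cov`.
#' @param model optional prefitted `mbplsc_model` for `ds` (refitted if
#'   absent).
#' @return A `permutation_result` list: `p_omnibus`, `p_components`,
#'   `observed_inertia`, `null_inertia`, `null_sigma` (B x k matrix of
#'   aligned singular values), `n_permutations`, `scheme`.
#' @export
permutation_test <- function(ds, config = analysis_config(), model = NULL) {
  B <- config$n_permutations
  if (B < 1) stop("n_permutations must be >= 1")
  if (is.null(model)) model <- fit_mbplsc(assemble_multiblock(ds, config))
  zb <- standardized_blocks(ds, config)
  obs_inertia <- sum(model$sigma^2)
  k <- model$n_components

  set.seed(config$seed)
  null_inertia <- numeric(B)
  null_sigma <- matrix(NA_real_, B, k)
  G <- length(zb)
  for (b in seq_len(B)) {
    perms <- lapply(zb, function(z) sample.int(z$n))
    if (config$permutation_scheme == "permute_gm") {
      # equivalently permute gm rows: swap roles by permuting wm with the
      # inverse ordering applied to gm-aligned rows
      zb_p <- zb
      for (gi in seq_len(G)) {
        zb_p[[gi]]$gm <- zb[[gi]]$gm[perms[[gi]], , drop = FALSE]
        zb_p[[gi]]$covariates <- zb[[gi]]$covariates[perms[[gi]], , drop = FALSE]
      }
      M_p <- stack_from_z(zb_p, config$include_cov_cov)
    } else if (config$permutation_scheme == "both") {
      perms2 <- lapply(zb, function(z) sample.int(z$n))
      zb_p <- zb
      for (gi in seq_len(G)) {
        zb_p[[gi]]$gm <- zb[[gi]]$gm[perms2[[gi]], , drop = FALSE]
        zb_p[[gi]]$covariates <- zb[[gi]]$covariates[perms2[[gi]], , drop = FALSE]
      }
      M_p <- stack_from_z(zb_p, config$include_cov_cov, wm_rows_order = perms)
    } else {
      M_p <- stack_from_z(zb, config$include_cov_cov, wm_rows_order = perms)
    }
    dec <- svd(M_p, nu = nrow(M_p), nv = ncol(M_p))
    sig <- dec$d[seq_len(k)]
    null_inertia[b] <- sum(sig^2)
    al <- align_to_model(model, dec$u[, seq_len(k), drop = FALSE],
                         dec$v[, seq_len(k), drop = FALSE], sig)
    null_sigma[b, ] <- al$sigma
  }
  p_omnibus <- (1 + sum(null_inertia >= obs_inertia)) / (B + 1)
  p_components <- vapply(seq_len(k), function(i) {
    (1 + sum(null_sigma[, i] >= model$sigma[i])) / (B + 1)
  }, numeric(1))
  structure(list(p_omnibus = p_omnibus, p_components = p_components,
                 observed_inertia = obs_inertia, observed_sigma = model$sigma,
                 null_inertia = null_inertia, null_sigma = null_sigma,
                 n_permutations = B, scheme = config$permutation_scheme),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (B = %d, scheme = %s)\n", x$n_permutations, x$scheme))
  cat(sprintf("  omnibus p = %.4g (inertia = %.4f)\n", x$p_omnibus, x$observed_inertia))
  k_show <- min(5L, length(x$p_components))
  cat("  per-component p:", paste(sprintf("LV%d=%.3g", seq_len(k_show),
                                          x$p_components[seq_len(k_show)]), collapse = "  "), "\n")
  invisible(x)
}

resample_within_group <- function(ds, seed_draw = NULL) {
  idx <- unlist(lapply(levels(ds$group), function(g) {
    rows <- which(ds$group == g)
    sample(rows, length(rows), replace = TRUE)
  }))
  feature_dataset(
    participant_id = sprintf("boot_%05d", seq_along(idx)),
    group = ds$group[idx],
    gm = ds$gm[idx, , drop = FALSE],
    wm = ds$wm[idx, , drop = FALSE],
    covariates = ds$covariates[idx, , drop = FALSE],
    cognition = ds$cognition[idx, , drop = FALSE],
    wm_is_fa = ds$wm_is_fa
  )
}

#' Bootstrap confidence intervals for saliences
#'
#' Resamples participants with replacement within each group, refits the
#' multiblock model, Procrustes-aligns each replicate to the original
#' solution (rotation and sign), and accumulates per-entry salience
#' distributions. Percentile 95% CIs and a significance flag (CI excluding
#' zero) are reported per salience entry. Replicates producing a
#' zero-variance column are discarded and counted; if more than 1% are
#' discarded a warning is recorded in the result.
#'
#' @param ds a validated [feature_dataset()].
#' @param config an [analysis_config()]; uses `n_bootstrap`, `seed`.
#' @param model optional prefitted model.
#' @param components components to summarise (default first
#'   `min(5, k)`).
#' @param ci_level confidence level (default 0.95).
#' @return A `bootstrap_result` with a long data frame `table` (side,
#'   group, variable, block, component, estimate, boot_sd, lower, upper,
#'   significant), `n_bootstrap`, `n_discarded`, `unreliable`, `warnings`.
#' @export
bootstrap_saliences <- function(ds, config = analysis_config(), model = NULL,
                                components = NULL, ci_level = 0.95) {
  B <- config$n_bootstrap
  if (is.null(model)) model <- fit_mbplsc(assemble_multiblock(ds, config))
  k <- model$n_components
  if (is.null(components)) components <- seq_len(min(5L, k))
  set.seed(config$seed + 1L)

  n_left <- nrow(model$u); n_right <- nrow(model$v)
  acc_u <- array(NA_real_, c(B, n_left, length(components)))
  acc_v <- array(NA_real_, c(B, n_right, length(components)))
  discarded <- 0L
  for (b in seq_len(B)) {
    rep_ds <- resample_within_group(ds)
    mb <- tryCatch(assemble_multiblock(rep_ds, config), error = function(e) NULL)
    if (is.null(mb)) { discarded <- discarded + 1L; next }
    fit <- fit_mbplsc(mb)
    al <- align_to_model(model, fit$u, fit$v, fit$sigma)
    acc_u[b, , ] <- al$u[, components]
    acc_v[b, , ] <- al$v[, components]
  }
  used <- B - discarded
  warnings <- character(0)
  if (discarded > 0.01 * B) {
    warnings <- c(warnings, sprintf("%d of %d bootstrap replicates discarded (zero-variance column)",
                                    discarded, B))
  }
  unreliable <- used < 100L
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)

  summarise_side <- function(acc, est, meta) {
    rows <- NULL
    for (ci in seq_along(components)) {
      draws <- acc[, , ci, drop = FALSE]
      dim(draws) <- c(B, dim(acc)[2])
      qs <- apply(draws, 2, stats::quantile, probs = probs, na.rm = TRUE)
      sds <- apply(draws, 2, stats::sd, na.rm = TRUE)
      rows <- rbind(rows, data.frame(
        meta,
        component = components[ci],
        estimate = est[, components[ci]],
        boot_sd = sds, lower = qs[1, ], upper = qs[2, ],
        significant = qs[1, ] > 0 | qs[2, ] < 0,
        stringsAsFactors = FALSE, row.names = NULL
      ))
    }
    rows
  }
  left_meta <- data.frame(side = "left", group = model$mb$row_map$group,
                          variable = model$mb$row_map$variable,
                          block = model$mb$row_map$block, stringsAsFactors = FALSE)
  right_meta <- data.frame(side = "right", group = NA_character_,
                           variable = model$mb$col_map$variable,
                           block = model$mb$col_map$block, stringsAsFactors = FALSE)
  tab <- rbind(summarise_side(acc_u, model$u, left_meta),
               summarise_side(acc_v, model$v, right_meta))
  structure(list(table = tab, n_bootstrap = used, n_discarded = discarded,
                 unreliable = unreliable, warnings = warnings,
                 ci_level = ci_level, components = components),
            class = "bootstrap_result")
}

#' Normalised between-group structural salience difference (NSSD)
#'
#' Contrasts the grey-matter salience patterns of two groups for one latent
#' component: each group's grey-matter salience subvector is L2-normalised,
#' then subtracted elementwise. A positive entry means the (normalised)
#' salience is larger in the first group of `group_pair`.
#'
#' @param model an `mbplsc_model`.
#' @param component component index.
#' @param group_pair character vector of two group labels (default: the
#'   model's group order).
#' @return Named numeric vector over grey-matter variables.
#' @export
nssd <- function(model, component = 1L, group_pair = model$mb$groups[1:2]) {
  stopifnot(length(group_pair) == 2)
  for (g in group_pair) {
    if (!g %in% model$mb$groups) stop(sprintf("unknown group label '%s'", g))
  }
  s1 <- gm_saliences(model, group_pair[1], component)[, 1]
  s2 <- gm_saliences(model, group_pair[2], component)[, 1]
  nssd_vectors(s1, s2)
}

#' NSSD from two raw salience vectors
#' @param s1,s2 numeric grey-matter salience vectors for the two groups.
#' @return `s1/||s1|| - s2/||s2||`, named like `s1`.
#' @export
nssd_vectors <- function(s1, s2) {
  stopifnot(length(s1) == length(s2))
  s1 / sqrt(sum(s1^2)) - s2 / sqrt(sum(s2^2))
}

#' Salience convergence trajectories over sample size
#'
#' For each of `n_orderings` random participant orderings, fits the model
#' on the first n participants of each group for n = n_min .. N-1, matches
#' the fitted component to the full-sample component of interest by maximal
#' absolute Tucker congruence (with sign alignment), and records the
#' absolute change in every salience between consecutive sample sizes
#' |salience(n+1) - salience(n)|. Trajectories are averaged over orderings;
#' values shrinking toward zero indicate the salience estimates have
#' stabilised.
#'
#' @param ds a validated [feature_dataset()].
#' @param config an [analysis_config()]; uses `convergence$n_min`,
#'   `convergence$n_orderings`, `seed`.
#' @param component full-sample component to track.
#' @return A `convergence_trajectory` list: `n_grid`, `left` and `right`
#'   matrices (variables x length(n_grid)) of mean absolute differences,
#'   `component`, `n_orderings`.
#' @export
convergence_trajectory <- function(ds, config = analysis_config(), component = 1L) {
  n_min <- config$convergence$n_min
  if (n_min < 5) stop("n_min must be >= 5 for stable correlations")
  counts <- table(ds$group)
  N <- min(counts)
  if (N <= n_min) stop(sprintf("need more than n_min = %d participants per group", n_min))
  full <- fit_mbplsc(assemble_multiblock(ds, config))
  ref_u <- full$u[, component]
  n_grid <- n_min:(N - 1)
  R <- config$convergence$n_orderings

  acc_left <- matrix(0, nrow(full$u), length(n_grid))
  acc_right <- matrix(0, nrow(full$v), length(n_grid))
  set.seed(config$seed + 2L)
  for (r in seq_len(R)) {
    ord <- lapply(levels(ds$group), function(g) sample(which(ds$group == g)))
    prev <- NULL
    for (ni in seq_along(c(n_grid, N))) {
      n <- c(n_grid, N)[ni]
      idx <- unlist(lapply(ord, function(o) o[seq_len(n)]))
      fit <- fit_mbplsc(assemble_multiblock(subset_participants(ds, idx), config))
      cong <- vapply(seq_len(fit$n_components),
                     function(i) tucker_congruence(ref_u, fit$u[, i]), numeric(1))
      best <- which.max(abs(cong))
      s <- sign(cong[best])
      cur <- list(u = s * fit$u[, best], v = s * fit$v[, best])
      if (!is.null(prev)) {
        acc_left[, ni - 1] <- acc_left[, ni - 1] + abs(cur$u - prev$u)
        acc_right[, ni - 1] <- acc_right[, ni - 1] + abs(cur$v - prev$v)
      }
      prev <- cur
    }
  }
  left <- acc_left / R
  right <- acc_right / R
  rownames(left) <- rownames(full$mb$M)
  rownames(right) <- colnames(full$mb$M)
  structure(list(n_grid = n_grid, left = left, right = right,
                 component = component, n_orderings = R),
            class = "convergence_trajectory")
}

match_component <- function(ref_model, fit, component) {
  # match a refitted model's component to a reference component by maximal
  # |Tucker congruence| of the left singular vectors; ties -> lowest index
  cong <- vapply(seq_len(fit$n_components),
                 function(i) tucker_congruence(ref_model$u[, component], fit$u[, i]),
                 numeric(1))
  best <- which.max(abs(cong))
  list(index = best, sign = sign(cong[best]), congruence = cong[best])
}

#' Monte Carlo cross-validation of latent-score coupling
#'
#' Repeatedly splits each group into training and test partitions, fits the
#' model on the training partition, projects test participants with the
#' training solution's component of the requested rank (using
#' training-group standardization statistics), and records the per-group
#' out-of-sample correlation between grey-matter and white-matter latent
#' scores. The component is tracked by rank within each training fit, not
#' by congruence with the full-sample solution: the full-sample model has
#' seen the test participants, so selecting the training component most
#' aligned with it would leak test information and bias the out-of-sample
#' correlation upward under the null. A group's coupling is flagged "generalisable" when the
#' normal-theory 95% interval of the across-split mean correlation excludes
#' zero.
#'
#' @param ds a validated [feature_dataset()].
#' @param config an [analysis_config()]; uses `cv$train_fraction`,
#'   `cv$n_splits`, `seed`.
#' @param component full-sample component to track.
#' @return A `cv_result` with `splits` (data frame: split, group, r, p,
#'   n_test), `summary` (per group: mean_r, sd_r, n_splits, generalisable),
#'   `component`.
#' @export
monte_carlo_cv <- function(ds, config = analysis_config(), component = 1L) {
  frac <- config$cv$train_fraction
  n_splits <- config$cv$n_splits
  counts <- table(ds$group)
  n_train <- floor(frac * counts)
  if (any(n_train < 5) || any(counts - n_train < 5)) {
    stop("split infeasible: need >= 5 participants per group in both partitions")
  }
  set.seed(config$seed + 3L)
  rows_list <- NULL
  for (s in seq_len(n_splits)) {
    train_idx <- unlist(lapply(levels(ds$group), function(g) {
      rows <- which(ds$group == g)
      sample(rows, n_train[[g]])
    }))
    test_idx <- setdiff(seq_along(ds$participant_id), train_idx)
    fit <- fit_mbplsc(assemble_multiblock(subset_participants(ds, train_idx), config))
    sc <- participant_scores(fit, subset_participants(ds, test_idx), component)
    for (g in levels(ds$group)) {
      sg <- sc[sc$group == g, ]
      ct <- stats::cor.test(sg$gm_score, sg$wm_score)
      rows_list <- rbind(rows_list, data.frame(
        split = s, group = g, r = unname(ct$estimate), p = ct$p.value,
        n_test = nrow(sg), stringsAsFactors = FALSE
      ))
    }
  }
  summ <- do.call(rbind, lapply(levels(ds$group), function(g) {
    rg <- rows_list$r[rows_list$group == g]
    mean_r <- mean(rg)
    sd_r <- if (length(rg) > 1) stats::sd(rg) else NA_real_
    gen <- if (is.na(sd_r)) NA else {
      half <- 1.96 * sd_r / sqrt(length(rg))
      (mean_r - half) > 0 || (mean_r + half) < 0
    }
    data.frame(group = g, mean_r = mean_r, sd_r = sd_r,
               n_splits = length(rg), generalisable = gen,
               stringsAsFactors = FALSE)
  }))
  structure(list(splits = rows_list, summary = summ, component = component),
            class = "cv_result")
}

#' Project a held-out cohort onto a fitted model
#'
#' Scores new participants with the trained saliences and training-group
#' standardization statistics, then reports the per-group correlation
#' between grey-matter and white-matter latent scores with its p-value.
#'
#' @param model a fitted `mbplsc_model` (carries training statistics).
#' @param new_ds a [feature_dataset()] with identical gm/wm variable names
#'   and group labels mapping to the trained groups.
#' @param component component to score.
#' @return A data frame with one row per group: `group`, `r`, `p`, `n`,
#'   plus attribute `"scores"` holding the projected score table.
#' @export
out_of_sample_projection <- function(model, new_ds, component = 1L) {
  sc <- participant_scores(model, new_ds, component)
  out <- do.call(rbind, lapply(unique(sc$group), function(g) {
    sg <- sc[sc$group == g, ]
    ct <- stats::cor.test(sg$gm_score, sg$wm_score)
    data.frame(group = g, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(sg), stringsAsFactors = FALSE)
  }))
  attr(out, "scores") <- sc
  out
}
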