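#' Cross-correlation block between two data matrices
#'
#' Entry (i, j) is the correlation of column i of `X` with column j of `Y`.
#'
#' @param X numeric matrix with >= 4 rows.
#' @param Y numeric matrix with the same number of rows as `X`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `ncol(X)` x `ncol(Y)` correlation matrix.
#' @export
correlation_block <- function(X, Y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop(sprintf("row mismatch: X has %d rows, Y has %d", nrow(X), nrow(Y)))
  }
  if (nrow(X) < 4) stop("correlation requires at least 4 rows")
  for (nm in c("X", "Y")) {
    m <- get(nm)
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- colnames(m)[sds == 0] %||% which(sds == 0)
      stop(sprintf("zero-variance column(s) in %s: %s", nm, paste(bad, collapse = ", ")))
    }
  }
  stats::cor(X, Y, method = method)
}

group_standardize <- function(ds) {
  # within-group z-scoring; returns per-group standardized blocks and the
  # group means/sds reused when projecting held-out participants
  out <- list()
  for (g in levels(ds$group)) {
    rows <- ds$group == g
    gs <- list(group = g)
    for (b in c("gm", "wm", "covariates")) {
      m <- ds[[b]][rows, , drop = FALSE]
      if (ncol(m) == 0) {
        gs[[b]] <- m
        gs[[paste0(b, "_center")]] <- numeric(0)
        gs[[paste0(b, "_scale")]] <- numeric(0)
        next
      }
      ctr <- colMeans(m)
      scl <- apply(m, 2, stats::sd)
      gs[[b]] <- sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
      gs[[paste0(b, "_center")]] <- ctr
      gs[[paste0(b, "_scale")]] <- scl
    }
    out[[g]] <- gs
  }
  out
}

#' Assemble the group-stacked multiblock correlation matrix
#'
#' For each group g the data are standardized within group and four
#' correlation blocks are formed: grey-matter x white-matter (A_g, p x q),
#' grey-matter x covariates (B_g, p x c), covariates x white-matter
#' (D_g, c x q) and covariates x covariates (E_g, c x c). The per-group
#' block matrix \[\[A_g, B_g\], \[D_g, E_g\]\] is stacked vertically over
#' groups, giving a G(p+c) x (q+c) matrix whose SVD yields per-group
#' grey-matter saliences and white-matter saliences shared across groups.
#'
#' @param ds a validated [feature_dataset()].
#' @param config an [analysis_config()]; `include_cov_cov` switches the E_g
#'   block on/off (off replaces it with zeros), `cor_method` selects the
#'   correlation coefficient.
#' @return An object of class `multiblock_matrix` with elements `M` (the
#'   stacked matrix), `row_map` and `col_map` (data frames mapping rows to
#'   (group, variable, block) and columns to (variable, block)),
#'   `group_stats` (standardization statistics reused for projection) and
#'   bookkeeping fields.
#' @export
assemble_multiblock <- function(ds, config = analysis_config()) {
  stopifnot(inherits(ds, "feature_dataset"))
  groups <- levels(ds$group)
  p <- ncol(ds$gm); q <- ncol(ds$wm); c_ <- ncol(ds$covariates)
  stats_by_group <- group_standardize(ds)

  blocks <- vector("list", length(groups))
  row_map <- NULL
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gs <- stats_by_group[[g]]
    A <- tryCatch(
      correlation_block(gs$gm, gs$wm, config$cor_method),
      error = function(e) stop(sprintf("group %s: %s", g, conditionMessage(e)))
    )
    if (c_ > 0) {
      B <- correlation_block(gs$gm, gs$covariates, config$cor_method)
      D <- correlation_block(gs$covariates, gs$wm, config$cor_method)
      E <- if (config$include_cov_cov) {
        correlation_block(gs$covariates, gs$covariates, config$cor_method)
      } else {
        matrix(0, c_, c_, dimnames = list(colnames(ds$covariates), colnames(ds$covariates)))
      }
      blocks[[gi]] <- rbind(cbind(A, B), cbind(D, E))
    } else {
      blocks[[gi]] <- A
    }
    row_map <- rbind(row_map, data.frame(
      group = g,
      variable = c(colnames(ds$gm), colnames(ds$covariates)),
      block = c(rep("gm", p), rep("cov", c_)),
      stringsAsFactors = FALSE
    ))
  }
  M <- do.call(rbind, blocks)
  row_map$row <- seq_len(nrow(M))
  col_map <- data.frame(
    variable = c(colnames(ds$wm), colnames(ds$covariates)),
    block = c(rep("wm", q), rep("cov", c_)),
    col = seq_len(q + c_),
    stringsAsFactors = FALSE
  )
  rownames(M) <- paste(row_map$group, row_map$variable, sep = ".")
  colnames(M) <- col_map$variable

  structure(list(M = M, row_map = row_map, col_map = col_map,
                 groups = groups, p = p, q = q, c = c_,
                 gm_names = colnames(ds$gm), wm_names = colnames(ds$wm),
                 covariate_names = colnames(ds$covariates),
                 group_stats = stats_by_group,
                 cor_method = config$cor_method,
                 include_cov_cov = config$include_cov_cov),
            class = "multiblock_matrix")
}

#' Fit the multiblock PLS correlation model
#'
#' Decomposes the stacked multiblock correlation matrix by full singular
#' value decomposition. Each latent component i carries a singular value
#' sigma_i, per-group grey-matter saliences and grey-matter-side covariate
#' saliences (partitioned from the left singular vector by the row map),
#' white-matter saliences and white-matter-side covariate saliences shared
#' across groups (the right singular vector), the percentage of cross-block
#' covariance explained xi_i = 100 sigma_i^2 / sum_j sigma_j^2, and signed
#' block-wise contributions to sigma_i: for block B with rows R and columns
#' C, 100 * u_i\[R\]' M\[R, C\] v_i\[C\] / sigma_i (GM-WM aggregated over
#' groups). SVD signs are fixed so the largest-magnitude entry of each left
#' singular vector is positive.
#'
#' @param mb a `multiblock_matrix` from [assemble_multiblock()].
#' @return An object of class `mbplsc_model`.
#' @export
fit_mbplsc <- function(mb) {
  stopifnot(inherits(mb, "multiblock_matrix"))
  M <- mb$M
  if (!all(is.finite(M))) stop("multiblock matrix contains non-finite entries")
  dec <- svd(M, nu = nrow(M), nv = ncol(M))
  k <- min(dim(M))
  u <- dec$u[, seq_len(k), drop = FALSE]
  v <- dec$v[, seq_len(k), drop = FALSE]
  sigma <- dec$d[seq_len(k)]
  # sign convention: largest-|entry| of each left singular vector positive
  for (i in seq_len(k)) {
    j <- which.max(abs(u[, i]))
    if (u[j, i] < 0) {
      u[, i] <- -u[, i]
      v[, i] <- -v[, i]
    }
  }
  xi <- 100 * sigma^2 / sum(sigma^2)

  contrib <- block_contributions(M, u, v, sigma, mb)

  structure(list(u = u, v = v, sigma = sigma, xi = xi,
                 block_contributions = contrib,
                 mb = mb, n_components = k,
                 sign_convention = "max_abs_left_positive"),
            class = "mbplsc_model")
}

block_contributions <- function(M, u, v, sigma, mb) {
  rm <- mb$row_map; cm <- mb$col_map
  gm_rows <- which(rm$block == "gm")
  cov_rows <- which(rm$block == "cov")
  wm_cols <- which(cm$block == "wm")
  cov_cols <- which(cm$block == "cov")
  blocks <- list(
    `GM-WM` = list(rows = gm_rows, cols = wm_cols),
    `GM-GMcov` = list(rows = gm_rows, cols = cov_cols),
    `WM-WMcov` = list(rows = cov_rows, cols = wm_cols),
    `cov-cov` = list(rows = cov_rows, cols = cov_cols)
  )
  blocks <- Filter(function(b) length(b$rows) > 0 && length(b$cols) > 0, blocks)
  k <- length(sigma)
  out <- matrix(NA_real_, length(blocks), k,
                dimnames = list(names(blocks), paste0("LV", seq_len(k))))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    for (i in seq_len(k)) {
      if (sigma[i] <= .Machine$double.eps * max(sigma) * max(dim(M))) next
      out[bi, i] <- 100 * drop(crossprod(u[b$rows, i], M[b$rows, b$cols, drop = FALSE] %*% v[b$cols, i])) / sigma[i]
    }
  }
  out
}

#' @export
print.mbplsc_model <- function(x, ...) {
  k_show <- min(5L, x$n_components)
  cat(sprintf("mbplsc_model: %d groups, %d GM x %d WM variables, %d covariates, %d components\n",
              length(x$mb$groups), x$mb$p, x$mb$q, x$mb$c, x$n_components))
  df <- data.frame(sigma = round(x$sigma[seq_len(k_show)], 4),
                   xi_pct = round(x$xi[seq_len(k_show)], 2))
  rownames(df) <- paste0("LV", seq_len(k_show))
  print(df)
  invisible(x)
}

#' Extract grey-matter saliences for one group
#' @param model an `mbplsc_model`.
#' @param group group label.
#' @param components integer vector of components (default all).
#' @return p x length(components) matrix of saliences.
#' @export
gm_saliences <- function(model, group, components = seq_len(model$n_components)) {
  rm <- model$mb$row_map
  if (!group %in% model$mb$groups) stop(sprintf("unknown group label '%s'", group))
  rows <- which(rm$group == group & rm$block == "gm")
  out <- model$u[rows, components, drop = FALSE]
  dimnames(out) <- list(model$mb$gm_names, paste0("LV", components))
  out
}

#' Extract shared white-matter saliences
#' @inheritParams gm_saliences
#' @return q x length(components) matrix.
#' @export
wm_saliences <- function(model, components = seq_len(model$n_components)) {
  cols <- which(model$mb$col_map$block == "wm")
  out <- model$v[cols, components, drop = FALSE]
  dimnames(out) <- list(model$mb$wm_names, paste0("LV", components))
  out
}

#' Extract covariate saliences
#' @inheritParams gm_saliences
#' @param side `"gm"` for the per-group grey-matter-side covariate saliences
#'   (from the left singular vectors), `"wm"` for the shared
#'   white-matter-side covariate saliences (right singular vectors).
#' @param group group label, required for `side = "gm"`.
#' @return c x length(components) matrix.
#' @export
covariate_saliences <- function(model, side = c("gm", "wm"), group = NULL,
                                components = seq_len(model$n_components)) {
  side <- match.arg(side)
  if (model$mb$c == 0) stop("model has no covariate block")
  if (side == "gm") {
    if (is.null(group)) stop("group required for gm-side covariate saliences")
    rows <- which(model$mb$row_map$group == group & model$mb$row_map$block == "cov")
    out <- model$u[rows, components, drop = FALSE]
  } else {
    cols <- which(model$mb$col_map$block == "cov")
    out <- model$v[cols, components, drop = FALSE]
  }
  dimnames(out) <- list(model$mb$covariate_names, paste0("LV", components))
  out
}

#' Participant latent-variable scores
#'
#' Projects each participant onto the latent components: the grey-matter
#' score is the group-standardized grey-matter profile times that group's
#' grey-matter salience vector; the white-matter score uses the shared
#' white-matter saliences. Covariate salience entries are excluded.
#' Standardization reuses the group statistics stored in the model (so
#' held-out participants are projected with training-group means/SDs).
#'
#' @param model an `mbplsc_model`.
#' @param ds a [feature_dataset()] with the same gm/wm variable names.
#' @param components integer vector of components to score.
#' @return A data frame with columns `participant_id`, `group`, `component`,
#'   `gm_score`, `wm_score`.
#' @export
participant_scores <- function(model, ds, components = seq_len(model$n_components)) {
  mb <- model$mb
  if (!identical(colnames(ds$gm), mb$gm_names) ||
      !identical(colnames(ds$wm), mb$wm_names)) {
    stop("alignment error: gm/wm variable names do not match the fitted model")
  }
  unknown <- setdiff(levels(ds$group), mb$groups)
  if (length(unknown)) {
    stop(sprintf("unmapped group label(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- NULL
  wm_sal <- wm_saliences(model, components)
  for (g in levels(ds$group)) {
    rows <- which(ds$group == g)
    if (!length(rows)) next
    gs <- mb$group_stats[[g]]
    gm_z <- sweep(sweep(ds$gm[rows, , drop = FALSE], 2, gs$gm_center, "-"), 2, gs$gm_scale, "/")
    wm_z <- sweep(sweep(ds$wm[rows, , drop = FALSE], 2, gs$wm_center, "-"), 2, gs$wm_scale, "/")
    gm_sc <- gm_z %*% gm_saliences(model, g, components)
    wm_sc <- wm_z %*% wm_sal
    for (ci in seq_along(components)) {
      out <- rbind(out, data.frame(
        participant_id = ds$participant_id[rows],
        group = g, component = components[ci],
        gm_score = gm_sc[, ci], wm_score = wm_sc[, ci],
        stringsAsFactors = FALSE, row.names = NULL
      ))
    }
  }
  out
}

#' Strength and direction of a grey-white matter pattern
#'
#' The outer product of a grey-matter salience vector and a white-matter
#' salience vector; the magnitude of entry (i, j) is the strength of the
#' pairing between region i and tract j, and its sign its direction
#' (negative = opposite-direction pairing).
#'
#' @param gm_salience numeric vector (length p).
#' @param wm_salience numeric vector (length q).
#' @return p x q matrix.
#' @export
pattern_strength <- function(gm_salience, wm_salience) {
  stopifnot(is.numeric(gm_salience), is.numeric(wm_salience))
  outer(as.numeric(gm_salience), as.numeric(wm_salience))
}

#' Tucker congruence coefficient between two salience vectors
#'
#' Cosine similarity: sum(x*y) / sqrt(sum(x^2) * sum(y^2)). Used for
#' matching components across groups, subsamples and bootstrap replicates.
#'
#' @param x,y numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
tucker_congruence <- function(x, y) {
  stopifnot(length(x) == length(y))
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Serialise a fitted model to JSON and TSV salience tables
#'
#' @param model an `mbplsc_model`.
#' @param dir output directory (created if absent).
#' @param components components to export (default all with sigma > 0).
#' @return Invisibly, the paths written.
#' @export
write_model <- function(model, dir, components = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(components)) components <- which(model$sigma > 1e-12)
  summary_path <- file.path(dir, "model_summary.json")
  jsonlite::write_json(list(
    n_components = model$n_components,
    sigma = model$sigma,
    xi_percent = model$xi,
    block_contributions_percent = as.data.frame(t(model$block_contributions)),
    groups = model$mb$groups,
    layout = list(include_cov_cov = model$mb$include_cov_cov,
                  cor_method = model$mb$cor_method),
    sign_convention = model$sign_convention
  ), summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  paths <- summary_path
  for (g in model$mb$groups) {
    p <- file.path(dir, sprintf("gm_saliences_%s.tsv", g))
    utils::write.table(
      data.frame(variable = model$mb$gm_names, gm_saliences(model, g, components)),
      p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "wm_saliences.tsv")
  utils::write.table(
    data.frame(variable = model$mb$wm_names, wm_saliences(model, components)),
    p, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}
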