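#' Configuration for the synthetic two-group coupling generator
#'
#' The generator emulates the statistical structure of a two-group
#' grey-white matter coupling study: a shared grey-white coupling component
#' expressed with the same polarity in both groups, a group-differentiating
#' component whose grey-matter loadings flip sign between groups, covariate
#' structure (age lowering cortical thickness; sex/total intracranial volume
#' raising surface area), and a cognition score linked to the differential
#' white-matter latent variable in the patient-like group only.
#'
#' Defaults describe the emulated study conditions: 71 participants per
#' group, 68 grey-matter regions, 48 white-matter tracts, age roughly
#' uniform over 17-28 years, about 70 percent male, and planted effects
#' strong enough that recovery tests are informative (see the methods
#' vignette for the calibration rationale).
#'
#' @param n_per_group participants per group.
#' @param p number of grey-matter regions.
#' @param q number of white-matter tracts.
#' @param k_cognition number of cognition columns (column 1 carries the link).
#' @param group_labels length-2 character vector; first label is the
#'   control-like group.
#' @param gm_measure `"thickness"` or `"surface_area"` (sets output scale).
#' @param shared_effect loading strength of the shared component.
#' @param diff_effect loading strength of the group-differentiating component.
#' @param diff_polarity per-group sign of the differential grey-matter
#'   loadings (default `c(1, -1)`).
#' @param age_effect slope of standardized age on grey matter (negative
#'   mimics age-related cortical thinning).
#' @param sex_tiv_effect slope of the standardized TIV/sex factor on grey
#'   matter (positive mimics the surface-area scaling).
#' @param cognition_link per-group slope of the differential white-matter
#'   latent score on cognition column 1 (default links the second,
#'   patient-like group only).
#' @param noise_sd residual standard deviation on every feature.
#' @param sparsity fraction of nonzero entries in each planted loading
#'   vector.
#' @param seed integer seed; same config + seed gives a bit-identical
#'   dataset.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_group = 71L, p = 68L, q = 48L, k_cognition = 4L,
                         group_labels = c("HC", "ROP"),
                         gm_measure = c("thickness", "surface_area"),
                         shared_effect = 4, diff_effect = 2,
                         diff_polarity = c(1, -1),
                         age_effect = -0.5, sex_tiv_effect = 0.5,
                         cognition_link = c(0, 0.5),
                         noise_sd = 0.5, sparsity = 0.2, seed = 1L) {
  gm_measure <- match.arg(gm_measure)
  stopifnot(length(group_labels) == 2, length(diff_polarity) == 2,
            length(cognition_link) == 2,
            is.finite(shared_effect), is.finite(diff_effect),
            is.finite(age_effect), is.finite(sex_tiv_effect),
            all(is.finite(cognition_link)), noise_sd >= 0,
            sparsity > 0, sparsity <= 1, n_per_group >= 4,
            p >= 2, q >= 2, k_cognition >= 1)
  structure(list(n_per_group = as.integer(n_per_group), p = as.integer(p),
                 q = as.integer(q), k_cognition = as.integer(k_cognition),
                 group_labels = group_labels, gm_measure = gm_measure,
                 shared_effect = shared_effect, diff_effect = diff_effect,
                 diff_polarity = diff_polarity, age_effect = age_effect,
                 sex_tiv_effect = sex_tiv_effect,
                 cognition_link = cognition_link,
                 noise_sd = noise_sd, sparsity = sparsity,
                 seed = as.integer(seed)),
            class = "synth_config")
}

sparse_unit_vector <- function(len, sparsity, idx = NULL) {
  # equal-magnitude random-sign entries: the planted pattern has a crisp
  # nonzero/zero ground truth for significance-mask recovery tests
  k <- max(1L, ceiling(sparsity * len))
  if (is.null(idx)) idx <- sample.int(len, k)
  w <- numeric(len)
  w[idx] <- sample(c(-1, 1), length(idx), replace = TRUE)
  w / sqrt(sum(w^2))
}

orth_standardize <- function(y, X) {
  r <- stats::residuals(stats::lm.fit(cbind(1, X), y))
  (r - mean(r)) / stats::sd(r)
}

disjoint_support_pair <- function(len, sparsity) {
  # shared and differential loading vectors on disjoint supports, so the
  # two planted components are exactly orthogonal and separately
  # identifiable
  k <- max(1L, ceiling(sparsity * len))
  idx <- sample.int(len, min(2L * k, len))
  k1 <- min(k, length(idx) - 1L)
  list(sparse_unit_vector(len, sparsity, idx[seq_len(k1)]),
       sparse_unit_vector(len, sparsity, idx[(k1 + 1L):length(idx)]))
}

#' Generate a synthetic two-group dataset with known latent structure
#'
#' Per participant j in group g, with latent factors t_shared and t_diff
#' drawn standard normal:
#' \deqn{gm_j = s \, w^{gm}_{sh} t_{sh} + d \, \pi(g) \, w^{gm}_{df} t_{df}
#'   + a \, z(age_j) w_{age} + b \, z(tiv_j) w_{tiv} + \epsilon}
#' \deqn{wm_j = s \, w^{wm}_{sh} t_{sh} + d \, w^{wm}_{df} t_{df} + \epsilon}
#' where s, d are the shared/differential effects, \eqn{\pi(g)} the
#' per-group polarity, and the loading vectors are sparse, unit-norm and
#' drawn once per seed. Cognition column 1 is `cognition_link[g]` times the
#' standardized differential white-matter latent score plus noise; remaining
#' cognition columns are pure noise. Outputs are rescaled to plausible
#' units (thickness in mm or area in mm^2, FA around 0.45, cognition around
#' 100 +/- 15); correlations are unaffected by this rescaling.
#'
#' @param config a [synth_config()].
#' @return A list with elements `dataset` (a [feature_dataset()]) and
#'   `truth` (a `ground_truth` list with unit-norm salience vectors per
#'   component and group, participant factor scores, and cognition slopes).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  p <- config$p; q <- config$q; n <- config$n_per_group
  N <- 2L * n
  # planted loading vectors, drawn once per seed; shared/differential pairs
  # occupy disjoint supports (orthogonal, separately identifiable truth)
  w_gm <- disjoint_support_pair(p, config$sparsity)
  w_gm_sh <- w_gm[[1]]; w_gm_df <- w_gm[[2]]
  w_wm <- disjoint_support_pair(q, config$sparsity)
  w_wm_sh <- w_wm[[1]]; w_wm_df <- w_wm[[2]]
  w_age <- sparse_unit_vector(p, config$sparsity)
  w_tiv <- sparse_unit_vector(p, config$sparsity)

  group <- factor(rep(config$group_labels, each = n), levels = config$group_labels)
  age <- stats::runif(N, 17, 28)
  sex <- stats::rbinom(N, 1, 0.7)
  tiv_z <- 0.6 * (sex - mean(sex)) / max(stats::sd(sex), 1e-8) +
    sqrt(1 - 0.36) * stats::rnorm(N)
  tiv <- 1.45e6 + 1.2e5 * tiv_z
  age_z <- (age - mean(age)) / stats::sd(age)

  # factor scores are orthogonalized in-sample against the covariates and
  # each other, so each planted component is separately identifiable and
  # incidental factor-covariate correlations do not scale with effect size
  t_sh <- orth_standardize(stats::rnorm(N), cbind(age_z, tiv_z))
  t_df <- orth_standardize(stats::rnorm(N), cbind(age_z, tiv_z, t_sh))
  pol <- config$diff_polarity[as.integer(group)]

  gm_raw <- config$shared_effect * tcrossprod(t_sh, w_gm_sh) +
    config$diff_effect * tcrossprod(pol * t_df, w_gm_df) +
    config$age_effect * tcrossprod(age_z, w_age) +
    config$sex_tiv_effect * tcrossprod(tiv_z, w_tiv) +
    config$noise_sd * matrix(stats::rnorm(N * p), N, p)
  wm_raw <- config$shared_effect * tcrossprod(t_sh, w_wm_sh) +
    config$diff_effect * tcrossprod(t_df, w_wm_df) +
    config$noise_sd * matrix(stats::rnorm(N * q), N, q)

  # differential WM latent score drives cognition column 1, group-specifically
  wm_lv_df <- drop(wm_raw %*% w_wm_df)
  wm_lv_df_z <- (wm_lv_df - mean(wm_lv_df)) / max(stats::sd(wm_lv_df), 1e-12)
  link <- config$cognition_link[as.integer(group)]
  cog_raw <- matrix(stats::rnorm(N * config$k_cognition), N, config$k_cognition)
  cog_raw[, 1] <- link * wm_lv_df_z + stats::rnorm(N)

  if (config$gm_measure == "thickness") {
    gm <- 2.5 + 0.15 * gm_raw
  } else {
    gm <- 2500 + 250 * gm_raw
  }
  wm <- 0.45 + 0.05 * wm_raw
  cognition <- 100 + 15 * cog_raw

  colnames(gm) <- sprintf("gm_%03d", seq_len(p))
  colnames(wm) <- sprintf("wm_%03d", seq_len(q))
  cognition_names <- c("processing_speed", "working_memory",
                       "episodic_memory", "executive_function",
                       sprintf("cognition_%d", seq_len(config$k_cognition)))
  colnames(cognition) <- cognition_names[seq_len(config$k_cognition)]
  covariates <- cbind(age = age, sex = as.numeric(sex), tiv = tiv)

  ds <- feature_dataset(
    participant_id = sprintf("sub-%04d", seq_len(N)),
    group = group, gm = gm, wm = wm,
    covariates = covariates, cognition = cognition
  )
  truth <- structure(list(
    gm_saliences = list(
      shared = stats::setNames(lapply(1:2, function(i) w_gm_sh), config$group_labels),
      differential = stats::setNames(lapply(1:2, function(i) config$diff_polarity[i] * w_gm_df),
                                     config$group_labels)
    ),
    wm_saliences = list(shared = w_wm_sh, differential = w_wm_df),
    factor_scores = data.frame(participant_id = ds$participant_id,
                               t_shared = t_sh, t_differential = t_df),
    cognition_slopes = stats::setNames(as.list(config$cognition_link), config$group_labels),
    config = config
  ), class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' Generate a null dataset (no coupling, no cognition link)
#'
#' Same marginal structure as [generate_dataset()] but with shared,
#' differential and cognition effects set to zero; used for type-I error
#' calibration of permutation tests, cross-validation and FDR control.
#'
#' @param config a [synth_config()]; its effect fields are overridden to 0.
#' @return A [feature_dataset()].
#' @export
generate_null_dataset <- function(config = synth_config()) {
  config$shared_effect <- 0
  config$diff_effect <- 0
  config$cognition_link <- c(0, 0)
  generate_dataset(config)$dataset
}

#' Write ground truth to JSON
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic streamline-bundle table with a planted pattern
#'
#' Draws random streamline bundles (unordered endpoint region pairs, one to
#' three traversed tracts, log-normal weights). Bundles whose endpoints both
#' lie in the planted region set and that traverse at least one planted
#' tract have their weight multiplied by `enrichment`, planting a
#' connectivity signal detectable by [random_pattern_null()].
#'
#' @param n_regions size of the region label universe.
#' @param n_tracts size of the tract label universe.
#' @param planted_pattern list with integer vectors `regions` and `tracts`
#'   (indices into the universes).
#' @param enrichment weight multiplier for planted bundles (>= 1; 1 = null).
#'   When greater than 1, two percent of the bundles are additionally
#'   redirected into the planted pattern so the signal exists even on
#'   universes where random endpoints rarely co-occur in the pattern.
#' @param seed integer seed.
#' @param n_bundles number of bundles to draw.
#' @param region_labels,tract_labels optional label vectors; defaults are
#'   `region_001`-style labels.
#' @return A list with `bundles` (a `bundle_table`) and `pattern` (the
#'   planted label sets).
#' @export
generate_bundle_table <- function(n_regions = 68L, n_tracts = 48L,
                                  planted_pattern = list(regions = 1:6, tracts = 1:4),
                                  enrichment = 1, seed = 1L, n_bundles = 500L,
                                  region_labels = sprintf("region_%03d", seq_len(n_regions)),
                                  tract_labels = sprintf("tract_%03d", seq_len(n_tracts))) {
  stopifnot(enrichment >= 1, n_bundles >= 1)
  if (any(planted_pattern$regions > n_regions) || any(planted_pattern$tracts > n_tracts) ||
      any(planted_pattern$regions < 1) || any(planted_pattern$tracts < 1)) {
    stop("planted pattern indices out of range")
  }
  set.seed(seed)
  a <- sample.int(n_regions, n_bundles, replace = TRUE)
  b <- sample.int(n_regions, n_bundles, replace = TRUE)
  n_tr <- sample.int(3L, n_bundles, replace = TRUE)
  tracts <- lapply(n_tr, function(k) sort(sample.int(n_tracts, k)))
  weight <- stats::rlnorm(n_bundles, meanlog = 0, sdlog = 1)
  if (enrichment > 1) {
    # on large universes random endpoint pairs rarely both fall in the
    # pattern, so an enrichment-only signal could be planted on zero
    # bundles; redirect a small fixed share of bundles into the pattern
    forced <- seq_len(ceiling(0.02 * n_bundles))
    a[forced] <- sample(rep(planted_pattern$regions, 2L), length(forced), replace = TRUE)
    b[forced] <- sample(rep(planted_pattern$regions, 2L), length(forced), replace = TRUE)
    tracts[forced] <- lapply(tracts[forced], function(tr) {
      sort(unique(c(sample(rep(planted_pattern$tracts, 2L), 1L), tr)))
    })
  }
  in_pattern <- (a %in% planted_pattern$regions) & (b %in% planted_pattern$regions) &
    vapply(tracts, function(tr) any(tr %in% planted_pattern$tracts), logical(1))
  weight[in_pattern] <- weight[in_pattern] * enrichment

  bt <- bundle_table(
    region_a = region_labels[a],
    region_b = region_labels[b],
    tracts = lapply(tracts, function(tr) tract_labels[tr]),
    weight = weight,
    region_universe = region_labels,
    tract_universe = tract_labels
  )
  list(bundles = bt,
       pattern = list(regions = region_labels[planted_pattern$regions],
                      tracts = tract_labels[planted_pattern$tracts]))
}
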