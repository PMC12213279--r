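#' Run the full structural-coupling analysis from a configuration
#'
#' Orchestrates load -> validate -> assemble -> fit -> permutation ->
#' bootstrap -> NSSD -> (optional) convergence -> (optional) Monte Carlo
#' CV -> cognition association -> (optional) pattern connectivity, writing
#' a machine-readable report bundle to the output directory. All stage
#' randomness derives from the single master seed.
#'
#' @param config either a path to a YAML/JSON configuration file or a named
#'   list. Recognised keys: `input` (list with `feature_table`, `schema`,
#'   optionally `bundle_table` and `pattern`), `output_dir`, `seed`,
#'   `n_permutations`, `n_bootstrap`, `alpha`, `fdr_q`, `gm_measure`,
#'   `permutation_scheme`, `include_cov_cov`, `cor_method`, `components`
#'   (indices; default = permutation-significant components, or LV1),
#'   `stages` (logical flags `convergence`, `cv`, `association`,
#'   `connectivity`), `cv` and `convergence` parameter lists.
#' @return A `report_bundle` list (also serialised to `output_dir` when
#'   given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- config
  ac_args <- cfg[intersect(names(cfg), names(formals(analysis_config)))]
  cv_cfg <- cfg$cv %||% list()
  conv_cfg <- cfg$convergence %||% list()
  for (nm in names(cv_cfg)) ac_args[[nm]] <- cv_cfg[[nm]]
  for (nm in names(conv_cfg)) ac_args[[nm]] <- conv_cfg[[nm]]
  ac <- do.call(analysis_config, ac_args)
  stages <- utils::modifyList(
    list(convergence = FALSE, cv = TRUE, association = TRUE, connectivity = FALSE),
    as.list(cfg$stages %||% list())
  )

  ds <- load_feature_table(cfg$input$feature_table, cfg$input$schema)
  report <- list(meta = list(
    package_version = as.character(utils::packageVersion("mbplsc")),
    seed = ac$seed,
    config_hash = config_hash(cfg),
    gm_measure = ac$gm_measure,
    timestamp = NA  # left unset: reports must be byte-reproducible
  ))

  vr <- validate_dataset(ds, ac)
  report$validation <- unclass(vr)
  if (!vr$passes) {
    stop(sprintf("stage 'validate' failed: %s", paste(vr$fatal, collapse = "; ")))
  }

  mb <- assemble_multiblock(ds, ac)
  model <- fit_mbplsc(mb)
  report$model <- list(sigma = model$sigma, xi_percent = model$xi,
                       block_contributions_percent = model$block_contributions,
                       layout = list(include_cov_cov = mb$include_cov_cov,
                                     cor_method = mb$cor_method),
                       sign_convention = model$sign_convention)

  perm <- permutation_test(ds, ac, model)
  report$permutation <- list(p_omnibus = perm$p_omnibus,
                             p_components = perm$p_components,
                             n_permutations = perm$n_permutations,
                             scheme = perm$scheme)

  components <- cfg$components %||% {
    sig <- which(perm$p_components < ac$alpha)
    if (length(sig)) sig else 1L
  }
  components <- as.integer(components)

  boot <- bootstrap_saliences(ds, ac, model, components = components)
  report$bootstrap <- list(n_bootstrap = boot$n_bootstrap,
                           n_discarded = boot$n_discarded,
                           unreliable = boot$unreliable,
                           warnings = boot$warnings)

  report$nssd <- stats::setNames(lapply(components, function(comp) {
    as.list(nssd(model, comp))
  }), paste0("LV", components))

  if (isTRUE(stages$convergence)) {
    report$convergence <- stats::setNames(lapply(components, function(comp) {
      tr <- convergence_trajectory(ds, ac, comp)
      list(n_grid = tr$n_grid,
           mean_left = colMeans(tr$left), mean_right = colMeans(tr$right))
    }), paste0("LV", components))
  }

  scores <- participant_scores(model, ds, components)
  if (isTRUE(stages$cv)) {
    report$cv <- stats::setNames(lapply(components, function(comp) {
      cv <- monte_carlo_cv(ds, ac, comp)
      insample <- do.call(rbind, lapply(levels(ds$group), function(g) {
        sg <- scores[scores$group == g & scores$component == comp, ]
        ct <- stats::cor.test(sg$gm_score, sg$wm_score)
        data.frame(group = g, r = unname(ct$estimate), p = ct$p.value)
      }))
      list(in_sample = insample, summary = cv$summary)
    }), paste0("LV", components))
  }

  if (isTRUE(stages$association) && ncol(ds$cognition) > 0) {
    assoc <- correlate_cognition(scores, ds, components, ac)
    report$association <- as.data.frame(assoc)
  }

  if (isTRUE(stages$connectivity)) {
    if (is.null(cfg$input$bundle_table) || is.null(cfg$input$pattern)) {
      stop("stage 'connectivity' requires input$bundle_table and input$pattern")
    }
    bt <- read_bundle_table(cfg$input$bundle_table,
                            region_universe = cfg$input$region_universe %||% colnames(ds$gm),
                            tract_universe = cfg$input$tract_universe %||% colnames(ds$wm))
    pt <- random_pattern_null(bt, cfg$input$pattern,
                              B = ac$n_permutations, seed = ac$seed + 4L)
    report$connectivity <- list(observed = pt$observed, p = pt$p,
                                B = pt$B, n_regions = pt$n_regions,
                                n_tracts = pt$n_tracts)
  }

  report <- structure(report, class = "report_bundle")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, model, boot, cfg$output_dir)
  }
  report
}

config_hash <- function(cfg) {
  cfg$output_dir <- NULL  # hash the analysis, not where its results land
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_report <- function(report, model, boot, dir) {
  out <- rapply(unclass(report), f = function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  }, how = "replace")
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  utils::write.table(boot$table, file.path(dir, "salience_ci.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_model(model, dir)
  invisible(dir)
}

#' Write a synthetic fixture set to disk
#'
#' Generates a synthetic study (feature table CSV + schema JSON + ground
#' truth JSON + bundle table TSV) under `outdir`, for demos and tests.
#'
#' @param outdir output directory (created if needed).
#' @param preset one of `"null"`, `"shared_only"`,
#'   `"shared_plus_differential"`, `"cognition_linked"`.
#' @param n_per_group participants per group (default 71).
#' @param seed integer seed.
#' @param enrichment weight multiplier for the planted connectivity pattern
#'   in the bundle table.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixture <- function(outdir, preset = c("shared_plus_differential", "null",
                                            "shared_only", "cognition_linked"),
                         n_per_group = 71L, seed = 1L, enrichment = 20) {
  preset <- match.arg(preset)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- switch(preset,
    null = synth_config(n_per_group = n_per_group, seed = seed,
                        shared_effect = 0, diff_effect = 0,
                        cognition_link = c(0, 0)),
    shared_only = synth_config(n_per_group = n_per_group, seed = seed,
                               diff_effect = 0, cognition_link = c(0, 0)),
    shared_plus_differential = synth_config(n_per_group = n_per_group, seed = seed,
                                            cognition_link = c(0, 0)),
    cognition_linked = synth_config(n_per_group = n_per_group, seed = seed)
  )
  gen <- generate_dataset(cfg)
  paths <- list(
    feature_table = file.path(outdir, "feature_table.csv"),
    schema = file.path(outdir, "schema.json"),
    ground_truth = file.path(outdir, "ground_truth.json"),
    bundle_table = file.path(outdir, "bundle_table.tsv")
  )
  write_feature_table(gen$dataset, paths$feature_table, paths$schema)
  write_ground_truth(gen$truth, paths$ground_truth)
  bt <- generate_bundle_table(n_regions = cfg$p, n_tracts = cfg$q,
                              planted_pattern = list(regions = 1:6, tracts = 1:4),
                              enrichment = if (preset == "null") 1 else enrichment,
                              seed = seed,
                              region_labels = colnames(gen$dataset$gm),
                              tract_labels = colnames(gen$dataset$wm))
  write_bundle_table(bt$bundles, paths$bundle_table)
  invisible(paths)
}
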