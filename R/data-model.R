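#' Construct a participant-level feature dataset
#'
#' Bundles grey-matter morphometry, white-matter tract values, covariates and
#' cognition scores for a two-group (or G-group) structural-coupling study
#' into a validated container. Grey-matter columns are regional morphometry
#' (cortical thickness in mm or surface area in mm^2), white-matter columns
#' are tract-wise fractional anisotropy (unitless, in \[0, 1\]), covariates
#' typically age (years), sex (0/1) and total intracranial volume (mm^3).
#'
#' @param participant_id character vector of unique participant identifiers.
#' @param group factor (or coercible) of group labels, one per participant.
#' @param gm numeric matrix, participants x grey-matter regions, with column
#'   names.
#' @param wm numeric matrix, participants x white-matter tracts, with column
#'   names.
#' @param covariates numeric matrix (possibly 0 columns), participants x
#'   covariates, with column names. Sex must already be coded 0/1.
#' @param cognition numeric matrix (possibly 0 columns), participants x
#'   cognitive scores, with column names.
#' @param wm_is_fa logical; if `TRUE` (default) white-matter values are
#'   checked to lie in \[0, 1\] by [validate_dataset()].
#' @return An object of class `feature_dataset`.
#' @export
feature_dataset <- function(participant_id, group, gm, wm,
                            covariates = matrix(numeric(0), nrow = length(participant_id), ncol = 0),
                            cognition = matrix(numeric(0), nrow = length(participant_id), ncol = 0),
                            wm_is_fa = TRUE) {
  participant_id <- as.character(participant_id)
  group <- as.factor(group)
  gm <- as_named_matrix(gm, "gm")
  wm <- as_named_matrix(wm, "wm")
  covariates <- as_named_matrix(covariates, "covariates", allow_empty = TRUE)
  cognition <- as_named_matrix(cognition, "cognition", allow_empty = TRUE)

  n <- length(participant_id)
  for (nm in c("gm", "wm", "covariates", "cognition")) {
    m <- get(nm)
    if (nrow(m) != n) {
      stop(sprintf("block '%s' has %d rows but there are %d participants", nm, nrow(m), n))
    }
  }
  if (length(group) != n) stop("group must have one label per participant")
  if (anyDuplicated(participant_id)) {
    dup <- participant_id[duplicated(participant_id)][1]
    stop(sprintf("duplicate participant_id: '%s'", dup))
  }
  for (nm in c("gm", "wm", "covariates", "cognition")) {
    m <- get(nm)
    if (ncol(m) > 0 && anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value in block '%s' at row %d, column '%s'",
                   nm, idx[1], colnames(m)[idx[2]]))
    }
  }
  structure(list(
    participant_id = participant_id,
    group = droplevels(group),
    gm = gm, wm = wm,
    covariates = covariates, cognition = cognition,
    wm_is_fa = isTRUE(wm_is_fa)
  ), class = "feature_dataset")
}

as_named_matrix <- function(m, what, allow_empty = FALSE) {
  m <- as.matrix(m)
  if (ncol(m) == 0) {
    if (!allow_empty) stop(sprintf("block '%s' must have at least one column", what))
    storage.mode(m) <- "double"
    return(m)
  }
  if (!is.numeric(m)) stop(sprintf("block '%s' must be numeric", what))
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0(what, seq_len(ncol(m)))
  m
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("feature_dataset: %d participants, %d groups (%s)\n",
              length(x$participant_id), nlevels(x$group),
              paste(levels(x$group), collapse = "/")))
  cat(sprintf("  gm: %d  wm: %d  covariates: %d  cognition: %d columns\n",
              ncol(x$gm), ncol(x$wm), ncol(x$covariates), ncol(x$cognition)))
  invisible(x)
}

#' @export
dim.feature_dataset <- function(x) {
  c(length(x$participant_id),
    ncol(x$gm) + ncol(x$wm) + ncol(x$covariates) + ncol(x$cognition))
}

#' Analysis configuration
#'
#' Collects tunable parameters for the full multiblock analysis. Resampling
#' sizes default to 10,000 draws; tests and examples use smaller profiles.
#'
#' @param gm_measure `"thickness"` or `"surface_area"`; recorded in outputs,
#'   it does not change the algebra.
#' @param n_permutations number of permutations for significance testing.
#' @param n_bootstrap number of bootstrap resamples for salience CIs.
#' @param alpha two-sided significance level for permutation tests.
#' @param fdr_q Benjamini-Hochberg false discovery rate for cognition tests.
#' @param seed integer master seed; all stage seeds derive from it.
#' @param permutation_scheme which block's participant rows are shuffled
#'   within group: `"permute_wm"` (default), `"permute_gm"` or `"both"`.
#' @param include_cov_cov include the covariate-covariate correlation block
#'   in the stacked matrix (default `TRUE`).
#' @param cor_method correlation used inside the multiblock matrix
#'   (`"pearson"` default, `"spearman"` available).
#' @param train_fraction fraction of each group used for training in Monte
#'   Carlo cross-validation.
#' @param n_splits number of Monte Carlo cross-validation splits.
#' @param n_min smallest per-group sample size for convergence trajectories.
#' @param n_orderings number of random participant orderings averaged in the
#'   convergence trajectory.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(gm_measure = c("thickness", "surface_area"),
                            n_permutations = 10000L,
                            n_bootstrap = 10000L,
                            alpha = 0.05, fdr_q = 0.05,
                            seed = 1L,
                            permutation_scheme = c("permute_wm", "permute_gm", "both"),
                            include_cov_cov = TRUE,
                            cor_method = c("pearson", "spearman"),
                            train_fraction = 0.8, n_splits = 100L,
                            n_min = 10L, n_orderings = 10L) {
  gm_measure <- match.arg(gm_measure)
  permutation_scheme <- match.arg(permutation_scheme)
  cor_method <- match.arg(cor_method)
  stopifnot(n_permutations >= 1, n_bootstrap >= 1,
            alpha > 0, alpha < 1, fdr_q > 0, fdr_q < 1,
            train_fraction > 0, train_fraction < 1,
            n_min >= 5, n_orderings >= 1, n_splits >= 1)
  structure(list(
    gm_measure = gm_measure,
    n_permutations = as.integer(n_permutations),
    n_bootstrap = as.integer(n_bootstrap),
    alpha = alpha, fdr_q = fdr_q, seed = as.integer(seed),
    permutation_scheme = permutation_scheme,
    include_cov_cov = isTRUE(include_cov_cov),
    cor_method = cor_method,
    cv = list(train_fraction = train_fraction, n_splits = as.integer(n_splits)),
    convergence = list(n_min = as.integer(n_min), n_orderings = as.integer(n_orderings))
  ), class = "analysis_config")
}

#' Load a participant feature table from delimited text
#'
#' Reads a CSV or TSV file with a header row and maps every column to a role
#' via `schema`. Sex-like categorical covariate columns with two string
#' levels are encoded 0/1 by lexicographic label order so the sign of the
#' resulting saliences is interpretable.
#'
#' @param path path to a comma- or tab-delimited text file with header.
#' @param schema either a path to a YAML/JSON schema file or a named list
#'   with elements `id`, `group`, and character vectors `gm`, `wm`,
#'   `covariate`, `cognition` (and optionally `ignore`) naming columns.
#' @return A [feature_dataset()]. Column order within each block follows the
#'   schema's order.
#' @export
load_feature_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1) schema <- read_schema(schema)
  schema <- normalize_schema(schema)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  mapped <- unlist(schema[c("id", "group")], use.names = FALSE)
  mapped <- c(mapped, schema$gm, schema$wm, schema$covariate, schema$cognition)
  missing_cols <- setdiff(mapped, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: mapped column(s) not in file: %s",
                 paste(missing_cols, collapse = ", ")))
  }

  num_block <- function(cols, what) {
    if (!length(cols)) {
      return(matrix(numeric(0), nrow = nrow(df), ncol = 0))
    }
    out <- matrix(NA_real_, nrow(df), length(cols), dimnames = list(NULL, cols))
    for (j in seq_along(cols)) {
      raw <- df[[cols[j]]]
      if (what == "covariate" && !all(grepl("^\\s*-?[0-9.eE+]+\\s*$", raw))) {
        lev <- sort(unique(raw))
        if (length(lev) != 2) {
          stop(sprintf("covariate column '%s' is non-numeric with %d levels; only binary categorical covariates are supported",
                       cols[j], length(lev)))
        }
        out[, j] <- as.numeric(match(raw, lev) - 1L)  # lexicographic 0/1
        next
      }
      v <- suppressWarnings(as.numeric(raw))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                     raw[bad], bad, cols[j]))
      }
      out[, j] <- v
    }
    out
  }

  feature_dataset(
    participant_id = df[[schema$id]],
    group = df[[schema$group]],
    gm = num_block(schema$gm, "gm"),
    wm = num_block(schema$wm, "wm"),
    covariates = num_block(schema$covariate, "covariate"),
    cognition = num_block(schema$cognition, "cognition")
  )
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_schema <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

normalize_schema <- function(schema) {
  req <- c("id", "group")
  for (r in req) {
    if (is.null(schema[[r]])) stop(sprintf("schema error: missing '%s' role", r))
  }
  for (r in c("gm", "wm", "covariate", "cognition")) {
    schema[[r]] <- as.character(schema[[r]] %||% character(0))
  }
  if (!length(schema$gm) || !length(schema$wm)) {
    stop("schema error: gm and wm roles must each map at least one column")
  }
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature dataset and its schema to delimited text
#'
#' Inverse of [load_feature_table()]: writes a CSV with an `id` and `group`
#' column followed by covariate, grey-matter, white-matter and cognition
#' columns, plus a JSON schema mapping each column to its role.
#'
#' @param ds a [feature_dataset()].
#' @param path output CSV path.
#' @param schema_path optional output path for the JSON schema.
#' @return Invisibly, the schema list.
#' @export
write_feature_table <- function(ds, path, schema_path = NULL) {
  df <- data.frame(id = ds$participant_id, group = as.character(ds$group),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (b in c("covariates", "gm", "wm", "cognition")) {
    if (ncol(ds[[b]]) > 0) df <- cbind(df, as.data.frame(ds[[b]], check.names = FALSE))
  }
  # full-precision formatting so write -> load round trips are exact
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  schema <- list(id = "id", group = "group",
                 covariate = colnames(ds$covariates),
                 gm = colnames(ds$gm), wm = colnames(ds$wm),
                 cognition = colnames(ds$cognition))
  if (!is.null(schema_path)) {
    jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(schema)
}

#' Validate a feature dataset against analysis preconditions
#'
#' Checks per-group sample sizes (correlation needs at least 4 participants
#' per group), zero-variance columns (fatal: correlations undefined) and,
#' when the white-matter block is declared as fractional anisotropy,
#' out-of-range values. Validation never modifies the dataset.
#'
#' @param ds a [feature_dataset()].
#' @param config an [analysis_config()]; currently only recorded.
#' @return A `validation_report` list with `per_group_n`, `fatal` (character
#'   vector of findings), `warnings`, and `passes` (`TRUE` iff no fatal
#'   finding).
#' @export
validate_dataset <- function(ds, config = analysis_config()) {
  stopifnot(inherits(ds, "feature_dataset"))
  fatal <- character(0)
  warn <- character(0)
  per_group_n <- table(ds$group)
  small <- names(per_group_n)[per_group_n < 4]
  if (length(small)) {
    fatal <- c(fatal, sprintf("group too small (n < 4): %s", paste(small, collapse = ", ")))
  }
  for (b in c("gm", "wm", "covariates")) {
    m <- ds[[b]]
    if (ncol(m) == 0) next
    for (g in levels(ds$group)) {
      rows <- ds$group == g
      if (sum(rows) < 2) next
      sds <- apply(m[rows, , drop = FALSE], 2, stats::sd)
      zv <- colnames(m)[sds == 0]
      if (length(zv)) {
        fatal <- c(fatal, sprintf("zero-variance %s column(s) in group %s: %s",
                                  b, g, paste(zv, collapse = ", ")))
      }
    }
  }
  if (isTRUE(ds$wm_is_fa) && ncol(ds$wm) > 0) {
    bad <- which(ds$wm < 0 | ds$wm > 1, arr.ind = TRUE)
    if (nrow(bad)) {
      warn <- c(warn, sprintf("%d white-matter value(s) outside [0, 1] (declared FA), e.g. row %d column '%s'",
                              nrow(bad), bad[1, 1], colnames(ds$wm)[bad[1, 2]]))
    }
  }
  structure(list(per_group_n = as.list(per_group_n),
                 fatal = fatal, warnings = warn,
                 passes = length(fatal) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", if (x$passes) "PASS" else "FAIL", "\n")
  cat("  per-group n:", paste(sprintf("%s=%d", names(x$per_group_n),
                                      unlist(x$per_group_n)), collapse = ", "), "\n")
  if (length(x$fatal)) cat("  fatal:\n", paste("   -", x$fatal, collapse = "\n"), "\n")
  if (length(x$warnings)) cat("  warnings:\n", paste("   -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialise a validation report to JSON
#' @param report a `validation_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Subset a feature dataset by participant index
#' @param ds a [feature_dataset()].
#' @param idx integer or logical row index.
#' @return A [feature_dataset()] restricted to the selected participants.
#' @export
subset_participants <- function(ds, idx) {
  feature_dataset(
    participant_id = ds$participant_id[idx],
    group = ds$group[idx],
    gm = ds$gm[idx, , drop = FALSE],
    wm = ds$wm[idx, , drop = FALSE],
    covariates = ds$covariates[idx, , drop = FALSE],
    cognition = ds$cognition[idx, , drop = FALSE],
    wm_is_fa = ds$wm_is_fa
  )
}
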