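#' Streamline bundle summary table
#'
#' Represents tractography output reduced to bundle summaries: each row is
#' a bundle of streamlines with an unordered endpoint region pair, the set
#' of white-matter tract labels it traverses, and a non-negative total
#' weight (SIFT2-like units). Label universes (default: 68 cortical
#' regions, 48 tracts) bound the random-pattern null.
#'
#' @param region_a,region_b character vectors of endpoint region labels.
#' @param tracts list of character vectors of traversed tract labels.
#' @param weight non-negative numeric bundle weights.
#' @param region_universe,tract_universe full label sets.
#' @return An object of class `bundle_table`.
#' @export
bundle_table <- function(region_a, region_b, tracts, weight,
                         region_universe, tract_universe) {
  n <- length(region_a)
  if (n == 0) stop("empty bundle table: no bundles supplied")
  stopifnot(length(region_b) == n, length(tracts) == n, length(weight) == n)
  if (any(weight < 0)) stop("bundle weights must be non-negative")
  bad_r <- setdiff(c(region_a, region_b), region_universe)
  if (length(bad_r)) stop(sprintf("unknown region label(s): %s", paste(utils::head(bad_r, 3), collapse = ", ")))
  bad_t <- setdiff(unlist(tracts), tract_universe)
  if (length(bad_t)) stop(sprintf("unknown tract label(s): %s", paste(utils::head(bad_t, 3), collapse = ", ")))
  structure(list(region_a = as.character(region_a),
                 region_b = as.character(region_b),
                 tracts = tracts, weight = as.numeric(weight),
                 region_universe = region_universe,
                 tract_universe = tract_universe),
            class = "bundle_table")
}

#' @export
print.bundle_table <- function(x, ...) {
  cat(sprintf("bundle_table: %d bundles over %d regions x %d tracts, total weight %.2f\n",
              length(x$weight), length(x$region_universe),
              length(x$tract_universe), sum(x$weight)))
  invisible(x)
}

#' Read a bundle table from TSV
#'
#' Expected columns: `region_a`, `region_b`, `tracts` (semicolon-delimited
#' labels), `weight`.
#'
#' @param path TSV file path.
#' @param region_universe,tract_universe label universes; default to the
#'   shipped Desikan-Killiany and JHU atlas label lists.
#' @return A [bundle_table()].
#' @export
read_bundle_table <- function(path,
                              region_universe = dk_labels(),
                              tract_universe = jhu_labels()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  bundle_table(df$region_a, df$region_b,
               strsplit(df$tracts, ";", fixed = TRUE),
               df$weight, region_universe, tract_universe)
}

#' Write a bundle table to TSV
#' @param bundles a [bundle_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bundle_table <- function(bundles, path) {
  df <- data.frame(region_a = bundles$region_a, region_b = bundles$region_b,
                   tracts = vapply(bundles$tracts, paste, "", collapse = ";"),
                   weight = bundles$weight, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shipped Desikan-Killiany cortical label set (68 regions)
#' @return Character vector of 68 region labels.
#' @export
dk_labels <- function() {
  readLines(system.file("extdata", "dk_cortical_labels.txt", package = "mbplsc"))
}

#' Shipped JHU white-matter tract label set (48 tracts)
#' @return Character vector of 48 tract labels.
#' @export
jhu_labels <- function() {
  readLines(system.file("extdata", "jhu_tract_labels.txt", package = "mbplsc"))
}

#' Total streamline weight captured by a grey-white pattern
#'
#' Sums the weights of bundles whose both endpoints lie in `regions` and
#' that traverse at least one tract in `tracts`. Each bundle is counted
#' once regardless of how many pattern tracts it traverses.
#'
#' @param bundles a [bundle_table()].
#' @param regions character set of region labels.
#' @param tracts character set of tract labels.
#' @return Scalar total weight.
#' @export
pattern_weight <- function(bundles, regions, tracts) {
  bad_r <- setdiff(regions, bundles$region_universe)
  if (length(bad_r)) stop(sprintf("unknown region label '%s'", bad_r[1]))
  bad_t <- setdiff(tracts, bundles$tract_universe)
  if (length(bad_t)) stop(sprintf("unknown tract label '%s'", bad_t[1]))
  if (!length(regions) || !length(tracts)) return(0)
  hit <- (bundles$region_a %in% regions) & (bundles$region_b %in% regions) &
    vapply(bundles$tracts, function(tr) any(tr %in% tracts), logical(1))
  sum(bundles$weight[hit])
}

#' Size-matched random-pattern null for pattern connectivity
#'
#' Compares the observed pattern weight against `B` random patterns, each
#' drawing (uniformly, without replacement) the same number of regions and
#' tracts from the label universes. The one-sided p-value
#' (1 + #\{null >= observed\}) / (B + 1) asks whether the observed pattern
#' captures unusually much direct connectivity for its size.
#'
#' @param bundles a [bundle_table()].
#' @param pattern list with character vectors `regions` and `tracts`.
#' @param B number of random patterns (default 10000).
#' @param seed integer seed.
#' @return A `pattern_test_result`: `observed`, `null` (length-B vector),
#'   `p`, `n_regions`, `n_tracts`, `B`, `seed`.
#' @export
random_pattern_null <- function(bundles, pattern, B = 10000L, seed = 1L) {
  stopifnot(B >= 1)
  nr <- length(pattern$regions); nt <- length(pattern$tracts)
  if (nr > length(bundles$region_universe) || nt > length(bundles$tract_universe)) {
    stop("pattern larger than its label universe")
  }
  observed <- pattern_weight(bundles, pattern$regions, pattern$tracts)
  set.seed(seed)
  null <- vapply(seq_len(B), function(b) {
    r <- sample(bundles$region_universe, nr)
    tr <- sample(bundles$tract_universe, nt)
    pattern_weight(bundles, r, tr)
  }, numeric(1))
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null >= observed)) / (B + 1),
                 n_regions = nr, n_tracts = nt, B = B, seed = seed),
            class = "pattern_test_result")
}

#' @export
print.pattern_test_result <- function(x, ...) {
  cat(sprintf("pattern_test_result: observed weight %.3f, p = %.4g (B = %d, %d regions x %d tracts)\n",
              x$observed, x$p, x$B, x$n_regions, x$n_tracts))
  invisible(x)
}

#' Exhaustive pattern null over all size-matched patterns
#'
#' Enumerates every size-matched (region set, tract set) pair on small
#' universes and returns the exact one-sided exceedance probability,
#' p = #\{pattern weight >= observed\} / #patterns. Intended as an oracle
#' for validating the Monte Carlo null on toy problems.
#'
#' @inheritParams random_pattern_null
#' @return list with `observed`, `p_exact`, `n_patterns`, `weights`.
#' @export
exhaustive_pattern_null <- function(bundles, pattern) {
  nr <- length(pattern$regions); nt <- length(pattern$tracts)
  rc <- utils::combn(bundles$region_universe, nr, simplify = FALSE)
  tc <- utils::combn(bundles$tract_universe, nt, simplify = FALSE)
  observed <- pattern_weight(bundles, pattern$regions, pattern$tracts)
  weights <- unlist(lapply(rc, function(r) {
    vapply(tc, function(tr) pattern_weight(bundles, r, tr), numeric(1))
  }))
  list(observed = observed,
       p_exact = mean(weights >= observed),
       n_patterns = length(weights), weights = weights)
}
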