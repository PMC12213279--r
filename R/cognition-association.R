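#' Choose Pearson or Spearman correlation from normality
#'
#' Applies Shapiro-Wilk to both vectors; Pearson is used only when neither
#' test rejects normality at `alpha_norm`, otherwise Spearman.
#'
#' @param x,y numeric vectors, n >= 4, non-constant.
#' @param alpha_norm significance level of the normality gate (default
#'   0.05).
#' @return `"pearson"` or `"spearman"`, with attribute `"shapiro_p"` giving
#'   the two test p-values.
#' @export
choose_method <- function(x, y, alpha_norm = 0.05) {
  if (length(x) < 4 || length(y) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  method <- if (px > alpha_norm && py > alpha_norm) "pearson" else "spearman"
  structure(method, shapiro_p = c(x = px, y = py))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (monotone, capped at 1), controlling the false
#' discovery rate over the supplied family.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Fisher z comparison of two independent correlations
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), with a two-sided
#' p-value from the standard normal. Used to compare a brain-cognition
#' correlation between groups.
#'
#' @param r1,r2 correlations, |r| < 1.
#' @param n1,n2 sample sizes, >= 4.
#' @return list with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1 (atanh undefined at 1)")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

correlate_pair <- function(x, y, alpha_norm = 0.05, exact_perm_n = 20L) {
  method <- choose_method(x, y, alpha_norm)
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson")
    list(method = "pearson", r = unname(ct$estimate), p = ct$p.value)
  } else if (length(x) < exact_perm_n) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = TRUE))
    list(method = "spearman", r = unname(ct$estimate), p = ct$p.value)
  } else {
    # large-sample t approximation for the Spearman coefficient
    rs <- stats::cor(x, y, method = "spearman")
    n <- length(x)
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    list(method = "spearman", r = rs, p = 2 * stats::pt(-abs(tstat), df = n - 2))
  }
}

#' Cognition vs latent-variable association table
#'
#' For each group and each selected component, correlates every cognition
#' column with both the grey-matter and white-matter latent scores. The
#' correlation coefficient (Pearson or Spearman) is chosen per pair by the
#' Shapiro-Wilk normality gate. Benjamini-Hochberg adjustment is applied
#' within each (group, component) family of size
#' k_cognition x 2 score blocks, matching the study's
#' (4 cognitive abilities) x (GM or WM latent variable) family.
#'
#' @param scores score table from [participant_scores()].
#' @param ds the [feature_dataset()] providing cognition columns (aligned
#'   by participant id).
#' @param components integer vector of components to test.
#' @param config an [analysis_config()]; uses `fdr_q`.
#' @param alpha_norm normality-gate level for [choose_method()].
#' @return An `association_table` data frame with columns `group`,
#'   `component`, `cognition`, `score_block`, `method`, `r`, `p`,
#'   `p_adjusted`, `significant`, and attribute `"family_size"`.
#' @export
correlate_cognition <- function(scores, ds, components = 1L,
                                config = analysis_config(), alpha_norm = 0.05) {
  if (ncol(ds$cognition) == 0) stop("dataset has no cognition columns")
  out <- NULL
  for (g in levels(ds$group)) {
    for (comp in components) {
      sc <- scores[scores$group == g & scores$component == comp, ]
      idx <- match(sc$participant_id, ds$participant_id)
      if (anyNA(idx)) stop("score table and dataset participants do not align")
      cog <- ds$cognition[idx, , drop = FALSE]
      fam <- NULL
      for (cn in colnames(cog)) {
        for (blk in c("gm", "wm")) {
          y <- if (blk == "gm") sc$gm_score else sc$wm_score
          res <- correlate_pair(cog[, cn], y, alpha_norm)
          fam <- rbind(fam, data.frame(
            group = g, component = comp, cognition = cn,
            score_block = blk, method = res$method, r = res$r, p = res$p,
            stringsAsFactors = FALSE
          ))
        }
      }
      fam$p_adjusted <- bh_adjust(fam$p)
      fam$significant <- fam$p_adjusted < config$fdr_q
      out <- rbind(out, fam)
    }
  }
  structure(out, family_size = 2L * ncol(ds$cognition), class = c("association_table", "data.frame"))
}

#' Compare a cognition-latent correlation between two groups
#'
#' Convenience wrapper extracting one (cognition, score block, component)
#' pair from an [correlate_cognition()] table for two groups and applying
#' [fisher_z_compare()] with the per-group sample sizes.
#'
#' @param assoc an `association_table`.
#' @param scores the score table used to build it (for group sizes).
#' @param cognition cognition column name.
#' @param score_block `"gm"` or `"wm"`.
#' @param component component index.
#' @param group_pair two group labels.
#' @return list with `z`, `p`, and the two per-group correlations.
#' @export
compare_group_correlation <- function(assoc, scores, cognition, score_block,
                                      component, group_pair) {
  pick <- function(g) {
    row <- assoc[assoc$group == g & assoc$cognition == cognition &
                   assoc$score_block == score_block & assoc$component == component, ]
    if (nrow(row) != 1) stop("association row not found or not unique")
    row$r
  }
  n_of <- function(g) sum(scores$group == g & scores$component == component)
  r1 <- pick(group_pair[1]); r2 <- pick(group_pair[2])
  fz <- fisher_z_compare(r1, n_of(group_pair[1]), r2, n_of(group_pair[2]))
  c(fz, list(r = stats::setNames(c(r1, r2), group_pair)))
}
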