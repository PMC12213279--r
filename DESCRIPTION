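Package: mbplsc
Title: Multiblock Partial Least Squares Correlation for Grey-White Matter Structural Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Group-stacked multiblock partial least squares correlation (MB-PLS-C)
    for studying coupling between grey-matter morphometry and white-matter
    microstructure in two-group neuroimaging designs. Builds per-group
    cross-correlation blocks between grey-matter, white-matter and covariate
    variables, stacks them vertically and decomposes the stacked matrix by
    singular value decomposition into latent components with saliences,
    explained cross-block covariance and block-wise contributions. Provides
    permutation tests with Procrustes alignment, bootstrap confidence
    intervals for saliences, normalised between-group salience differences,
    salience convergence trajectories, Monte Carlo cross-validation and
    out-of-sample projection, cognition-latent-variable association with
    Benjamini-Hochberg control and Fisher z group comparison, a streamline
    bundle connectivity statistic with a size-matched random-pattern null,
    and a synthetic two-group data generator with planted shared and
    group-differentiating latent couplings for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
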