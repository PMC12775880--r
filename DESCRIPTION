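Package: statpilot
Title: Guided, Assumption-Driven Statistical Workflows for Grouped Laboratory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless statistical copilot for long-format group/value data
    from laboratory experiments (assays, qPCR, viability measurements).
    Screens outliers (Grubbs, modified Z-score), checks normality
    (Shapiro-Wilk, per group and on model residuals) and homoscedasticity
    (Brown-Forsythe), guides log10/Box-Cox/arcsine-square-root
    transformations with maximum-likelihood estimation of the Box-Cox
    exponent, then routes every dataset through the only statistically valid
    parametric or non-parametric test, runs branch-appropriate post-hoc
    comparisons (Tukey HSD, Dunnett, Dunn, Sidak pairs) with Cohen's d
    effect sizes and compact letter displays, and exports a fully traceable
    multi-sheet results workbook including a rendered decision tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    readxl,
    zip,
    mvtnorm,
    car,
    ggplot2,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    multcomp,
    xml2,
    jsonlite
Config/testthat/edition: 3
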