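# Seeded dataset generators with the statistical structure of the two
# validation scenarios, plus null datasets for operating-characteristic
# studies.
#
# "three_group_clean" emulates a well-behaved genotype comparison
# (WT/KO/KI): normal, homoscedastic, group means separated by >= 5 sigma,
# so both assumption checks pass and every pairwise contrast is large.
#
# "viability_dirty" emulates a cell-viability assay (ctrl/A/B/C/D,
# n drawn uniformly from 8..12 per group) engineered to defeat parametric
# analysis: opposite skews in different arms (right-skewed lognormal noise
# in one, a ceiling effect -- values pressed against an upper plateau --
# in another), two bimodal responder/non-responder arms, and strongly
# group-dependent variance. No single monotone transform can normalize
# opposite skews and bimodality at once, so per-group normality fails,
# Brown-Forsythe fails, and residual normality still fails after log10 or
# pooled-exponent Box-Cox.
#
# "null_k_groups" is i.i.d. N(0, 1) in every group.

#' Generate a synthetic benchmark dataset
#'
#' @param kind `"three_group_clean"`, `"viability_dirty"`, or
#'   `"null_k_groups"`.
#' @param seed Integer seed; identical `(kind, parameters, seed)` give an
#'   identical dataset. The caller's RNG state is untouched.
#' @param n Per-group size for `three_group_clean` and `null_k_groups`.
#' @param k Number of groups for `null_k_groups`.
#' @param n_range Inclusive range the per-group sizes of
#'   `viability_dirty` are drawn from.
#' @return An `sp_dataset`.
#' @export
generate_fixture <- function(kind = c("three_group_clean", "viability_dirty",
                                      "null_k_groups"),
                             seed = 1, n = 8, k = 3, n_range = c(8, 12)) {
  kind <- match.arg(kind)
  if (n < 2 || k < 2) stop_statpilot("fixture needs n >= 2 and k >= 2")
  if (length(n_range) != 2 || n_range[1] > n_range[2] || n_range[1] < 3)
    stop_statpilot("n_range must be an increasing pair with minimum >= 3")
  with_private_seed(seed, {
    df <- switch(kind,
      three_group_clean = {
        groups <- c("WT", "KO", "KI")
        means <- c(WT = 10, KO = 15, KI = 20)   # sigma = 1: >= 5 sigma apart
        tibble::tibble(
          group = rep(groups, each = n),
          value = rnorm(3 * n, mean = rep(means, each = n), sd = 1))
      },
      viability_dirty = {
        ns <- sample(seq(n_range[1], n_range[2]), 5, replace = TRUE)
        vals <- c(
          100 * exp(rnorm(ns[1], 0, 0.015)),              # ctrl: tight, ~N(100, 1.5)
          pmin(60 + 3 * exp(rnorm(ns[2], 0, 1)), 105),    # A: right-skewed, ceiling at 105
          pmax(100 - 3 * exp(rnorm(ns[3], 0, 1)), 2),     # B: ceiling effect (left skew)
          40 + 60 * (runif(ns[4]) < 0.5) + rnorm(ns[4], 0, 1.5),  # C: bimodal responder/non-responder
          15 + 50 * (runif(ns[5]) < 0.5) + rnorm(ns[5], 0, 2))    # D: bimodal, offset modes
        tibble::tibble(
          group = rep(c("ctrl", "A", "B", "C", "D"), times = ns),
          value = vals)
      },
      null_k_groups = tibble::tibble(
        group = rep(paste0("G", seq_len(k)), each = n),
        value = rnorm(k * n)))
    order0 <- unique(df$group)
    new_dataset(df, group_order = order0,
                source = list(path = NA_character_, sheet = NULL,
                              mapping = list(generator = kind, seed = seed)))
  })
}
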