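test_that("Tukey HSD matches the studentized-range reference and TukeyHSD", {
  set.seed(15)
  gv <- list(a = rnorm(8), b = rnorm(10, 1), c = rnorm(9, 0.5))
  tk <- tukey_hsd(gv)
  ref <- TukeyHSD(aov(unlist(gv) ~ factor(rep(names(gv), lengths(gv)))))[[1]]
  # rows b-a, c-a, c-b correspond to pairs (a,b), (a,c), (b,c)
  expect_equal(tk$p_adj, unname(ref[c("b-a", "c-a", "c-b"), "p adj"]),
               tolerance = 1e-6)
  # direct studentized-range evaluation
  mw <- statpilot:::msw_oneway(gv)
  q12 <- abs(mean(gv$a) - mean(gv$b)) / sqrt(mw$msw / 2 * (1 / 8 + 1 / 10))
  expect_equal(tk$p_raw[1], ptukey(q12, 3, mw$df, lower.tail = FALSE),
               tolerance = 1e-12)
  # two identical groups among k: q = 0, p = 1
  gv2 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 10, 11))
  tk2 <- tukey_hsd(gv2)
  expect_equal(tk2$statistic[1], 0)
  expect_equal(tk2$p_adj[1], 1)
})

test_that("Tukey at k = 2 collapses to the pooled t-test (q = sqrt(2) |t|)", {
  set.seed(25)
  x <- rnorm(9); y <- rnorm(7, 0.8)
  mw <- statpilot:::msw_oneway(list(x, y))
  q <- abs(mean(x) - mean(y)) / sqrt(mw$msw / 2 * (1 / 9 + 1 / 7))
  p_q <- ptukey(q, 2, mw$df, lower.tail = FALSE)
  p_t <- t_test_2g(x, y, "student")$p
  expect_equal(p_q, p_t, tolerance = 1e-10)
})

test_that("Dunnett adjustment brackets between raw and Bonferroni and matches multcomp", {
  set.seed(35)
  gv <- list(ctrl = rnorm(8), t1 = rnorm(8, 0.7), t2 = rnorm(8, 1.2))
  dn <- dunnett_test(gv, control = "ctrl")
  expect_true(all(dn$p_adj >= dn$p_raw - 1e-9))
  expect_true(all(dn$p_adj <= pmin(2 * dn$p_raw, 1) + 1e-3))
  fit <- aov(unlist(gv) ~ factor(rep(names(gv), lengths(gv)),
                                 levels = names(gv)))
  ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(
    `factor(rep(names(gv), lengths(gv)), levels = names(gv))` = "Dunnett")))
  expect_equal(as.numeric(dn$p_adj), as.numeric(ref$test$pvalues),
               tolerance = 2e-3)
  # control identical to treatments: p ~ 1
  g <- rnorm(6)
  dn0 <- dunnett_test(list(ctrl = g, a = g, b = g), control = "ctrl")
  expect_true(all(dn0$p_adj > 0.999))
  expect_error(dunnett_test(gv, control = "nope"), "control group not found")
})

test_that("Dunnett integration is deterministic run to run", {
  set.seed(45)
  gv <- list(ctrl = rnorm(9), a = rnorm(9, 0.5), b = rnorm(9, 1))
  p1 <- dunnett_test(gv, "ctrl")$p_adj
  p2 <- dunnett_test(gv, "ctrl")$p_adj
  expect_identical(p1, p2)
})

test_that("Sidak pair adjustment follows its closed form and bounds", {
  gv <- list(a = c(1.1, 2, 3.4), b = c(2.2, 3, 4.1), c = c(8, 9, 10.5))
  r1 <- sidak_pairs(gv, list(c("a", "b")), "parametric")
  expect_equal(r1$p_adj, r1$p_raw, tolerance = 1e-12)    # m = 1
  r3 <- sidak_pairs(gv, list(c("a", "b"), c("a", "c"), c("b", "c")), "parametric")
  expect_equal(r3$p_adj, 1 - (1 - r3$p_raw)^3, tolerance = 1e-12)
  expect_true(all(r3$p_adj >= r3$p_raw & r3$p_adj <= 1))
  # the documented arithmetic example
  expect_equal(1 - (1 - 0.01)^3, 0.029701, tolerance = 1e-9)
  expect_error(sidak_pairs(gv, list(c("a", "b"), c("b", "a")), "parametric"),
               "duplicate")
  expect_error(sidak_pairs(gv, list(c("a", "z")), "parametric"), "unknown group")
  # nonparametric branch uses the Mann-Whitney U statistic
  rn <- sidak_pairs(gv, list(c("a", "c")), "nonparametric")
  expect_equal(unname(rn$statistic), unname(mann_whitney_u(gv$a, gv$c)$statistic))
})

test_that("Dunn's test matches the rank formula with and without ties", {
  gv <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  d <- dunn_test(gv, adjust = "none")
  # mean ranks 2, 5, 8; no ties
  N <- 9
  se <- sqrt(N * (N + 1) / 12 * (2 / 3))
  z13 <- (2 - 8) / se
  row13 <- d[d$group_a == "g1" & d$group_b == "g3", ]
  expect_equal(row13$statistic, z13, tolerance = 1e-12)
  expect_equal(row13$p_raw, 2 * pnorm(abs(z13), lower.tail = FALSE),
               tolerance = 1e-12)
  # equal mean ranks -> z = 0, p = 1
  gv0 <- list(a = c(1, 4), b = c(2, 3), c = c(2.5, 2.5))
  d0 <- dunn_test(gv0, adjust = "none")
  expect_equal(d0$statistic[1], 0, tolerance = 1e-12)
  expect_equal(d0$p_raw[1], 1)
  # tie correction shrinks the variance term
  gv_t <- list(a = c(1, 2, 2), b = c(2, 3, 4), c = c(5, 6, 7))
  v_untied <- 9 * 10 / 12
  tie_tab <- table(unlist(gv_t))
  v_tied <- v_untied - sum(tie_tab^3 - tie_tab) / (12 * 8)
  expect_lt(v_tied, v_untied)
  # Sidak default: p_adj = 1 - (1 - p_raw)^m over all pairs
  ds <- dunn_test(gv, adjust = "sidak")
  expect_equal(ds$p_adj, pmax(1 - (1 - ds$p_raw)^3, ds$p_raw), tolerance = 1e-12)
})

test_that("compact letters satisfy the sharing-iff-nonsignificant invariant", {
  # no significant pairs: everything shares one letter
  prs <- tibble::tibble(group_a = c("A", "A", "B"), group_b = c("B", "C", "C"),
                        significant = FALSE)
  la <- compact_letters(prs, c("A", "B", "C"))
  expect_true(all(la$letters == "a"))
  # all pairs significant: k distinct letters
  prs$significant <- TRUE
  la2 <- compact_letters(prs, c("A", "B", "C"))
  expect_equal(n_letters(la2), 3)
  expect_equal(anyDuplicated(la2$letters), 0)
  # the worked three-group case: only A-C significant
  prs$significant <- c(FALSE, TRUE, FALSE)
  la3 <- compact_letters(prs, c("A", "B", "C"))
  expect_equal(la3$letters, c("a", "ab", "b"))
  # contradictory duplicate listing errors
  bad <- tibble::tibble(group_a = c("A", "A"), group_b = c("B", "B"),
                        significant = c(TRUE, FALSE))
  expect_error(compact_letters(bad, c("A", "B")), "contradictory")
})

test_that("letter assignment is minimal against the exhaustive clique-cover oracle", {
  # random sample of significance graphs at k = 4 and k = 5 (the full
  # exhaustive sweep runs in the acceptance suite)
  set.seed(77)
  for (i in 1:30) {
    k <- sample(4:5, 1)
    prs_idx <- t(combn(k, 2))
    sig <- runif(nrow(prs_idx)) < 0.4
    prs <- tibble::tibble(group_a = as.character(prs_idx[, 1]),
                          group_b = as.character(prs_idx[, 2]),
                          significant = sig)
    la <- compact_letters(prs, as.character(seq_len(k)))
    adj <- matrix(FALSE, k, k)
    for (j in seq_len(nrow(prs_idx))) if (sig[j]) {
      adj[prs_idx[j, 1], prs_idx[j, 2]] <- TRUE
      adj[prs_idx[j, 2], prs_idx[j, 1]] <- TRUE
    }
    expect_equal(n_letters(la), oracle_min_letters(k, adj))
  }
})
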