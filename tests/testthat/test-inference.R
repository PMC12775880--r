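test_that("two-sample t-test matches direct arithmetic and carries pooled-sd d", {
  r0 <- t_test_2g(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$effect$value, 0)

  r <- t_test_2g(c(0, 1, 2), c(1, 2, 3))
  expect_equal(r$effect$denominator, 1)       # pooled sd
  expect_equal(r$effect$value, -1)            # first minus second

  # equal n, equal sample variance: Student and Welch coincide
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14)
  s <- t_test_2g(x, y, "student"); w <- t_test_2g(x, y, "welch")
  expect_equal(s$statistic, w$statistic, tolerance = 1e-12)
  expect_equal(s$df, w$df, tolerance = 1e-12)

  expect_error(t_test_2g(c(1, 1, 1), c(2, 2)), "zero variance")
  expect_error(t_test_2g(1, c(1, 2)), "n >= 2")
})

test_that("paired t-test uses differences and is antisymmetric", {
  x <- c(10.9, 12.1, 11.0, 13.0); y <- c(10.0, 11.0, 10.0, 12.0)
  r <- paired_t_test(x, y)
  d <- x - y   # 0.9 1.1 1.0 1.0
  expect_equal(r$effect$value, mean(d) / sd(d), tolerance = 1e-12)
  r_swap <- paired_t_test(y, x)
  expect_equal(r_swap$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r_swap$effect$value, -r$effect$value, tolerance = 1e-12)
  expect_error(paired_t_test(x, x + 2), "degenerate paired design")
})

test_that("one-way ANOVA matches direct sums of squares; F = t^2 at k = 2", {
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  # SSB = 1.5, SSW = 4 -> F = 1.5 / (4/4) = 1.5
  expect_equal(r$statistic, 1.5, tolerance = 1e-12)

  set.seed(88)
  for (i in 1:20) {
    gs <- lapply(1:sample(2:5, 1), function(j) rnorm(sample(3:9, 1)))
    ref <- oracle_anova_f(gs)
    r2 <- one_way_anova(gs)
    expect_equal(r2$statistic, ref$f, tolerance = 1e-10)
    expect_equal(r2$p, ref$p, tolerance = 1e-10)
    if (length(gs) == 2) {
      tt <- t_test_2g(gs[[1]], gs[[2]], "student")
      expect_equal(r2$statistic, tt$statistic^2, tolerance = 1e-10)
    }
  }
  # identical groups: no between-group variance
  g <- rnorm(5)
  expect_equal(one_way_anova(list(g, g, g))$statistic, 0, tolerance = 1e-12)
  expect_error(one_way_anova(list(rep(1, 3), rep(1, 3))), "identical")
})

test_that("Welch ANOVA matches the heteroscedastic reference", {
  set.seed(17)
  gs <- lapply(1:3, function(j) rnorm(6 + j, sd = j))
  r <- one_way_anova(gs, "welch")
  ref <- oneway.test(unlist(gs) ~ factor(rep(1:3, lengths(gs))), var.equal = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches the rank formula, with tie handling", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  # permuting group labels of identical groups changes nothing
  g <- c(1.5, 2.5, 3.5)
  expect_equal(kruskal_wallis(list(g, g, g))$statistic,
               kruskal_wallis(list(g, g, g)[c(2, 3, 1)])$statistic)
  # all tied: defined fallback
  rt <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p, 1)
  # H = z^2 of the untied uncorrected MWU normal approximation at k = 2
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9)
    H <- kruskal_wallis(list(x, y))$statistic
    u <- mann_whitney_u(x, y)$statistic
    n1 <- 7; n2 <- 9
    z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    expect_equal(H, z^2, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U: exact enumeration for small untied samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)   # 2/20 arrangements as extreme
  expect_match(r$note, "exact")
  # identical samples: U = n1 n2 / 2 (mid-ranks)
  x <- c(1, 2, 3, 4)
  expect_equal(unname(mann_whitney_u(x, x)$statistic), 8)
  # complementarity
  set.seed(5)
  a <- rnorm(6); b <- rnorm(8)
  expect_equal(unname(mann_whitney_u(a, b)$statistic) +
               unname(mann_whitney_u(b, a)$statistic), 48)
})

test_that("Mann-Whitney and signed-rank exact p equal enumeration oracles", {
  set.seed(61)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney_u(x, y)$p, oracle_mwu_exact(x, y),
                 tolerance = 1e-10)
    d <- rnorm(sample(4:8, 1))
    xs <- d; ys <- rep(0, length(d))
    expect_equal(wilcoxon_signed_rank(xs, ys)$p, oracle_wilcoxon_exact(d),
                 tolerance = 1e-10)
  }
})

test_that("signed-rank handles zero differences and sign antisymmetry", {
  x <- c(1, 2, 3, 4, 5); y <- c(0, 0, 0, 0, 0)
  r <- wilcoxon_signed_rank(x, y)
  expect_equal(unname(r$statistic), 15)       # all positive ranks
  expect_equal(r$p, 2 / 32, tolerance = 1e-12)  # two-sided exact
  # negation maps V to n(n+1)/2 - V
  r_neg <- wilcoxon_signed_rank(y, x)
  expect_equal(unname(r_neg$statistic), 0)
  expect_error(wilcoxon_signed_rank(x, x), "all differences zero")
  # zero differences dropped with a note
  r_z <- wilcoxon_signed_rank(c(1, 2, 3, 0), c(0, 0, 0, 0))
  expect_match(r_z$note, "1 zero difference")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(41)
  x <- runif(8, 1, 5); y <- runif(6, 1, 5); z <- runif(7, 1, 5)
  f <- function(v) exp(v) + v^3
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(f(x), f(y))$p,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(x, y, z))$statistic,
               kruskal_wallis(list(f(x), f(y), f(z)))$statistic,
               tolerance = 1e-12)
})

test_that("Cohen's d is scale-invariant and sign-flips on swap", {
  set.seed(51)
  x <- rnorm(10, 1); y <- rnorm(12)
  d0 <- t_test_2g(x, y)$effect$value
  expect_equal(t_test_2g(3 * x, 3 * y)$effect$value, d0, tolerance = 1e-10)
  expect_equal(t_test_2g(y, x)$effect$value, -d0, tolerance = 1e-10)
})

test_that("repeated-measures ANOVA equals the two-way decomposition oracle", {
  # flat within-subject profiles with subject offsets -> F = 0
  df <- expand.grid(subject = paste0("s", 1:4), group = c("c1", "c2", "c3"))
  df$value <- rep(c(5, 7, 9, 11), 3)
  ds <- statpilot:::new_dataset(df[, c("group", "value", "subject")])
  expect_equal(rm_anova(ds)$statistic, 0, tolerance = 1e-12)

  set.seed(71)
  df$value <- rnorm(12) + rep(c(0, 1, 2), each = 4) + rep(rnorm(4), 3)
  ds2 <- statpilot:::new_dataset(df[, c("group", "value", "subject")])
  mine <- rm_anova(ds2)
  a <- summary(aov(value ~ group + Error(subject/group), data = df))
  ref <- a[["Error: subject:group"]][[1]]
  expect_equal(mine$statistic, ref["group", "F value"], tolerance = 1e-10)
  expect_equal(mine$p, ref["group", "Pr(>F)"], tolerance = 1e-10)
  expect_match(mine$note, "sphericity not assessed")

  # one missing cell names the culprit
  df3 <- df[-5, ]
  ds3 <- statpilot:::new_dataset(df3[, c("group", "value", "subject")])
  expect_error(rm_anova(ds3), "missing cells: \\(s1, c2\\)")
})

test_that("two-way ANOVA: cell-means oracle, additivity, Type-II on balance", {
  # additive noise-free cell means -> interaction F = 0
  grid <- expand.grid(g = c("A", "B"), f = c("lo", "hi"), r = 1:3)
  grid$value <- ifelse(grid$g == "B", 2, 0) + ifelse(grid$f == "hi", 5, 0)
  grid$value <- grid$value + rep(c(-0.1, 0, 0.1), each = 4)[seq_len(nrow(grid))]
  ds <- statpilot:::new_dataset(
    data.frame(group = grid$g, value = grid$value, factor2 = grid$f))
  r <- two_way_anova(ds)
  # balanced 2x2: compare against the classical lm/anova decomposition
  fit <- anova(lm(value ~ g * f, data = grid))
  expect_equal(r$factor_a$statistic, fit["g", "F value"], tolerance = 1e-10)
  expect_equal(r$factor_b$statistic, fit["f", "F value"], tolerance = 1e-10)
  expect_equal(r$interaction$statistic, fit["g:f", "F value"], tolerance = 1e-10)

  # Type-II on a balanced design equals the classical decomposition
  set.seed(81)
  grid$value <- rnorm(nrow(grid))
  ds2 <- statpilot:::new_dataset(
    data.frame(group = grid$g, value = grid$value, factor2 = grid$f))
  r2 <- two_way_anova(ds2)
  fit2c <- anova(lm(value ~ g * f, data = grid))
  fit2t <- car::Anova(lm(value ~ g * f, data = grid), type = 2)
  expect_equal(fit2c["g", "F value"], fit2t["g", "F value"], tolerance = 1e-10)
  expect_equal(r2$factor_a$statistic, fit2c["g", "F value"], tolerance = 1e-10)

  # empty cell is an error
  bad <- grid[!(grid$g == "A" & grid$f == "hi"), ]
  ds3 <- statpilot:::new_dataset(
    data.frame(group = bad$g, value = bad$value, factor2 = bad$f))
  expect_error(two_way_anova(ds3), "empty cell")
})

test_that("mixed ANOVA equals the split-plot oracle and its aggregation identity", {
  set.seed(91)
  df <- expand.grid(subject = paste0("s", 1:8), w = c("t1", "t2", "t3"))
  df$group <- ifelse(as.integer(sub("s", "", df$subject)) <= 4, "ctrl", "trt")
  df$value <- rnorm(24) + ifelse(df$group == "trt", 1.5, 0) +
    rep(c(0, 0.5, 1), each = 8)
  ds <- statpilot:::new_dataset(
    data.frame(group = df$group, value = df$value, subject = df$subject,
               factor2 = df$w))
  mine <- mixed_anova(ds)
  a <- summary(aov(value ~ group * w + Error(subject), data = df))
  refb <- a[["Error: subject"]][[1]]
  refw <- a[["Error: Within"]][[1]]
  expect_equal(mine$between$statistic, refb["group", "F value"], tolerance = 1e-10)
  expect_equal(mine$within$statistic, refw["w", "F value"], tolerance = 1e-10)
  expect_equal(mine$interaction$statistic, refw["group:w", "F value"],
               tolerance = 1e-10)

  # collapsing the within factor to subject means reproduces the between F
  subj_means <- tapply(df$value, df$subject, mean)
  subj_grp <- tapply(df$group, df$subject, `[`, 1)
  ow <- one_way_anova(split(unname(subj_means), subj_grp))
  expect_equal(mine$between$statistic, ow$statistic, tolerance = 1e-10)

  # null design: all effects ~ 0 F for flat data
  df$value <- 3
  dsn <- statpilot:::new_dataset(
    data.frame(group = df$group, value = df$value, subject = df$subject,
               factor2 = df$w))
  mn <- mixed_anova(dsn)
  expect_equal(mn$between$statistic, 0)
  expect_equal(mn$within$statistic, 0)

  # incomplete within-subject data is an error
  ds_bad <- statpilot:::new_dataset(
    data.frame(group = df$group, value = rnorm(24), subject = df$subject,
               factor2 = df$w)[-1, ])
  expect_error(mixed_anova(ds_bad), "incomplete within-subject")
})
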