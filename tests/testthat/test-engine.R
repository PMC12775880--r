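test_that("planning follows the test-selection matrix", {
  p3 <- plan_analysis(generate_fixture("three_group_clean", seed = 1))
  expect_equal(p3$design, "independent")
  expect_true(all(c("One-Way ANOVA", "Kruskal-Wallis") %in% p3$candidate_tests))

  ds2 <- make_ds(list(a = c(1, 2, 3), b = c(2, 3, 4)),
                 subject = rep(c("s1", "s2", "s3"), 2))
  p2 <- plan_analysis(ds2)
  expect_equal(p2$design, "dependent")
  expect_setequal(p2$candidate_tests, c("paired t-test", "Wilcoxon signed-rank"))

  ds4 <- make_ds(list(a = 1:2, b = 3:4, c = 5:6, d = 7:8),
                 subject = rep(c("s1", "s2"), 4))
  p4 <- plan_analysis(ds4)
  expect_equal(p4$candidate_tests, "Repeated-Measures ANOVA")
})

test_that("branch selection implements the documented rules exhaustively", {
  mk_rep <- function(norm, homo, stage = "raw") {
    structure(list(stage = stage, alpha = 0.05, normality_pass = norm,
                   homoscedasticity_pass = homo, notes = character()),
              class = "sp_assumption_report")
  }
  expect_equal(select_branch(mk_rep(TRUE, TRUE)), "parametric")
  expect_equal(select_branch(mk_rep(TRUE, FALSE)), "parametric_welch")
  expect_equal(select_branch(mk_rep(FALSE, TRUE)), "needs_transform")
  expect_equal(select_branch(mk_rep(FALSE, FALSE)), "needs_transform")
  # with a post-transform report, only that report governs
  for (rn in c(TRUE, FALSE)) for (rh in c(TRUE, FALSE))
    for (pn in c(TRUE, FALSE)) for (ph in c(TRUE, FALSE)) {
      b <- select_branch(mk_rep(rn, rh), mk_rep(pn, ph, "post_transform"))
      expected <- if (pn && ph) "parametric"
                  else if (pn) "parametric_welch" else "nonparametric"
      expect_equal(b, expected)
    }
})

test_that("no path reaches a parametric omnibus with failing governing normality", {
  # exhaustive over report combinations (model check of the state machine)
  mk_rep <- function(norm, homo, stage = "raw") {
    structure(list(stage = stage, alpha = 0.05, normality_pass = norm,
                   homoscedasticity_pass = homo, notes = character()),
              class = "sp_assumption_report")
  }
  for (rn in c(TRUE, FALSE)) for (rh in c(TRUE, FALSE)) {
    b <- select_branch(mk_rep(rn, rh))
    if (b %in% c("parametric", "parametric_welch")) expect_true(rn)
    for (pn in c(TRUE, FALSE)) for (ph in c(TRUE, FALSE)) {
      b2 <- select_branch(mk_rep(rn, rh), mk_rep(pn, ph, "post_transform"))
      if (b2 %in% c("parametric", "parametric_welch")) expect_true(pn)
    }
  }
})

test_that("clean data flow straight to ANOVA and Tukey with no transform node", {
  # a seed on the majority path (raw checks pass)
  ds <- generate_fixture("three_group_clean", seed = 2)
  r <- run_workflow(ds, workflow_config(), list(posthoc = "tukey"))
  expect_equal(r$status, "completed")
  expect_true(r$assumptions$raw$normality_pass)
  expect_null(r$assumptions$post)
  expect_equal(r$transform$name, "none")
  expect_equal(r$omnibus$test, "One-Way ANOVA")
  expect_true(r$omnibus$significant)
  expect_equal(nrow(r$pairwise), 3)
  expect_true(all(r$pairwise$significant))
  tree <- render_decision_tree(r, "text")
  expect_false(any(grepl("^\\[x\\] transformation", tree)))
  expect_true(any(grepl("^\\[x\\] omnibus", tree)))
})

test_that("dirty data fail both stages and end on the Kruskal-Wallis branch", {
  ds <- generate_fixture("viability_dirty", seed = 1)
  r <- run_workflow(ds, workflow_config(), list(transform = "log10"))
  expect_equal(r$status, "completed")
  expect_false(r$assumptions$raw$normality_pass)
  expect_false(r$assumptions$post$normality_pass)
  expect_equal(r$omnibus$test, "Kruskal-Wallis")
  expect_equal(r$omnibus$branch, "nonparametric")
  # non-parametric branch gates the post-hoc menu
  expect_true(all(r$pairwise$method %in% c("dunn", "sidak_pairs")))
})

test_that("post-hoc menus are branch-gated", {
  ds <- generate_fixture("viability_dirty", seed = 1)
  r <- run_workflow(ds, workflow_config(posthoc = "tukey"),
                    list(transform = "log10"))
  expect_equal(r$status, "refused")
  expect_match(r$refusal_reason, "not offered on the nonparametric branch")
})

test_that("dependent designs with more than two groups can never go non-parametric", {
  set.seed(19)
  # strongly bimodal within-condition data that no transform rescues
  vals <- as.vector(t(replicate(8, c(1, 1, 1, 1) + rep(c(0, 30), 2) *
                                   (runif(4) < 0.5) + runif(4, 0, 0.3))))
  df <- data.frame(group = rep(c("c1", "c2", "c3", "c4"), times = 8),
                   value = vals + 1,
                   subject = rep(paste0("s", 1:8), each = 4))
  ds <- statpilot:::new_dataset(df)
  r <- run_workflow(ds, workflow_config(), list(transform = "log10"))
  expect_equal(r$status, "refused")
  expect_match(r$refusal_reason, "repeated-measures designs")
  # the trace records the refusal terminal
  ids <- vapply(r$trace$nodes, function(n) n$id, "")
  expect_true("refusal" %in% ids)
  expect_false(any(grepl("Kruskal|Mann-Whitney|signed-rank",
                         vapply(r$trace$nodes, function(n) n$label, ""))))
})

test_that("a blocked run with no transformation choice is a refusal", {
  ds <- generate_fixture("viability_dirty", seed = 2)
  r <- run_workflow(ds, workflow_config(), list())
  expect_equal(r$status, "refused")
  expect_match(r$refusal_reason, "no transformation choice")
})

test_that("heteroscedastic but normal data route to the Welch variant", {
  set.seed(12)
  # find a seed with normal-looking groups of very different spread
  for (s in 1:50) {
    set.seed(s)
    gv <- list(a = rnorm(12, 0, 0.5), b = rnorm(12, 0.3, 4), c = rnorm(12, 0, 8))
    ds <- make_ds(gv)
    rep_raw <- assess_assumptions(ds, "raw")
    if (rep_raw$normality_pass && !rep_raw$homoscedasticity_pass) {
      r <- run_workflow(ds, workflow_config())
      expect_equal(r$omnibus$test, "Welch's ANOVA")
      break
    }
  }
  expect_true(exists("r"))
})

test_that("non-significant omnibus ends without post-hoc", {
  set.seed(100)
  for (s in 1:60) {
    ds <- generate_fixture("null_k_groups", seed = s, n = 10, k = 3)
    r <- run_workflow(ds, workflow_config(), list(transform = "boxcox"))
    if (r$status == "completed" && !is.null(r$omnibus) && !r$omnibus$significant) {
      expect_null(r$pairwise)
      tree <- render_decision_tree(r, "text")
      expect_true(any(grepl("skipped: omnibus not significant",
                            vapply(r$trace$nodes, function(n) n$outcome, ""))))
      break
    }
  }
})

test_that("identical inputs and choices give identical traces and renders", {
  ds <- generate_fixture("viability_dirty", seed = 6)
  r1 <- run_workflow(ds, workflow_config(), list(transform = "boxcox"))
  r2 <- run_workflow(ds, workflow_config(), list(transform = "boxcox"))
  t1 <- render_decision_tree(r1, "text")
  t2 <- render_decision_tree(r2, "text")
  expect_identical(t1, t2)
  # node sequences identical apart from wall-clock stamps
  strip <- function(r) lapply(r$trace$nodes, function(n) n[setdiff(names(n), "time")])
  expect_identical(strip(r1), strip(r2))
})

test_that("outlier opt-in removal is recorded and flag-only is the default", {
  gv <- list(a = c(10, 11, 12, 10.5, 11.5, 60), b = c(20, 21, 22, 20.5, 21.5, 23),
             c = c(30, 31, 32, 30.5, 31.5, 33))
  ds <- make_ds(gv)
  r_flag <- run_workflow(ds, workflow_config(outlier_method = "grubbs"),
                         list(transform = "log10"))
  expect_equal(nrow(r_flag$dataset$data), 18)  # nothing removed
  expect_equal(sum(vapply(r_flag$outliers, function(x) x$n_flagged, 0L)), 1L)

  r_drop <- run_workflow(ds, workflow_config(outlier_method = "grubbs",
                                             drop_outliers = TRUE),
                         list(transform = "log10"))
  expect_equal(nrow(r_drop$dataset$data), 17)
  msgs <- vapply(r_drop$trace$log, function(e) e$message, "")
  expect_true(any(grepl("outlier\\(s\\) removed on explicit request", msgs)))
})

test_that("the SVG tree render marks the executed path", {
  ds <- generate_fixture("three_group_clean", seed = 2)
  r <- run_workflow(ds, workflow_config(), list(posthoc = "tukey"))
  svg <- render_decision_tree(r, "svg")
  expect_match(svg, "^<\\?xml")
  expect_true(grepl("#cfe8cf", svg))   # at least one executed node highlighted
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
})
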