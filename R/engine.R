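# The decision engine: routes a dataset through the only statistically
# valid analysis path and records every decision in a replayable trace.
#
# Routing (one-factor designs):
#   raw per-group normality + Brown-Forsythe
#     both pass                -> parametric
#     normality pass, BF fail  -> Welch variant
#     normality fail           -> transformation (user choice), then
#       residual normality + BF on transformed data
#         both pass            -> parametric on transformed values
#         normality pass only  -> Welch on transformed values
#         normality fail       -> non-parametric on the original values
#   Dependent designs with > 2 groups, two-way, and mixed designs have no
#   non-parametric fallback: a normality failure that survives the
#   transformation attempt is a refusal, never a silently wrong test.

#' Workflow configuration
#'
#' @param alpha Global significance level for assumption checks and tests.
#' @param outlier_method `"none"`, `"grubbs"`, or `"modified_z"`.
#' @param outlier_alpha Grubbs significance level.
#' @param modz_threshold Modified Z-score cutoff.
#' @param drop_outliers Remove flagged points before analysis (opt-in;
#'   flagging alone never removes data).
#' @param percent Treat arcsine-square-root input as percentages.
#' @param posthoc Post-hoc policy: `"auto"` (Tukey on the parametric
#'   branch, Dunn otherwise), `"tukey"`, `"dunnett"`, `"sidak"`, `"dunn"`.
#' @param control Control-group label (Dunnett).
#' @param pairs List of length-2 character vectors (Sidak pairs).
#' @param force_posthoc Run the post-hoc even when the omnibus is not
#'   significant (recorded as a warning in the trace).
#' @param retry_transform Allow a second transformation attempt.
#' @param p_display_floor Display floor for printed p-values.
#' @param seed Integer seed recorded in the trace (the workflow itself is
#'   deterministic given the data and choices).
#' @param center Centering of the homoscedasticity test, `"median"` or
#'   `"mean"`.
#' @param conf_level Confidence level for descriptive intervals.
#' @return A config list used by [run_workflow()].
#' @export
workflow_config <- function(alpha = 0.05, outlier_method = "none",
                            outlier_alpha = 0.05, modz_threshold = 3.5,
                            drop_outliers = FALSE, percent = FALSE,
                            posthoc = "auto", control = NULL, pairs = NULL,
                            force_posthoc = FALSE, retry_transform = FALSE,
                            p_display_floor = 0.001, seed = 1L,
                            center = "median", conf_level = 0.95) {
  if (alpha <= 0 || alpha >= 1) stop_statpilot("alpha must be in (0, 1)")
  if (p_display_floor <= 0 || p_display_floor >= 1)
    stop_statpilot("p_display_floor must be in (0, 1)")
  list(alpha = alpha, outlier_method = outlier_method,
       outlier_alpha = outlier_alpha, modz_threshold = modz_threshold,
       drop_outliers = drop_outliers, percent = percent, posthoc = posthoc,
       control = control, pairs = pairs, force_posthoc = force_posthoc,
       retry_transform = retry_transform, p_display_floor = p_display_floor,
       seed = as.integer(seed), center = center, conf_level = conf_level)
}

# ---- decision trace ---------------------------------------------------

trace_new <- function(cfg) {
  tr <- new.env(parent = emptyenv())
  tr$nodes <- list()
  tr$log <- list()
  tr$config <- cfg
  tr
}

trace_node <- function(tr, id, label, evidence = "", outcome = "",
                       chosen = TRUE) {
  seq_no <- length(tr$nodes) + 1L
  tr$nodes[[seq_no]] <- list(id = id, label = label, evidence = evidence,
                             outcome = outcome, chosen = chosen,
                             seq = seq_no, time = Sys.time())
  trace_log(tr, "decision", sprintf("%s: %s%s", label, outcome,
            if (nzchar(evidence)) paste0(" [", evidence, "]") else ""))
  invisible(tr)
}

trace_log <- function(tr, level, message) {
  tr$log[[length(tr$log) + 1L]] <-
    list(seq = length(tr$log) + 1L, level = level, message = message,
         time = Sys.time())
  invisible(tr)
}

trace_freeze <- function(tr) {
  list(nodes = tr$nodes, log = tr$log, config = tr$config)
}

# ---- planning and branch selection ------------------------------------

#' Plan the analysis for a dataset
#'
#' Determines the design (independent vs dependent from subject labels),
#' the number of groups and factors, and the candidate tests of the
#' selection matrix that apply.
#'
#' @param ds An `sp_dataset`.
#' @return An `sp_plan` list: `design`, `k_groups`, `factors`,
#'   `candidate_tests`.
#' @export
plan_analysis <- function(ds) {
  stopifnot(inherits(ds, "sp_dataset"))
  design <- if (has_subjects(ds)) "dependent" else "independent"
  k <- length(ds$group_order)
  factors <- 1L + has_factor2(ds)
  cand <- if (factors == 2L) {
    if (design == "dependent") c("Mixed ANOVA") else c("Two-Way ANOVA")
  } else if (design == "independent") {
    if (k == 2) c("t-test", "Welch's t-test", "Mann-Whitney U")
    else c("One-Way ANOVA", "Welch's ANOVA", "Kruskal-Wallis")
  } else {
    if (k == 2) c("paired t-test", "Wilcoxon signed-rank")
    else c("Repeated-Measures ANOVA")   # no non-parametric fallback
  }
  structure(list(design = design, k_groups = k, factors = factors,
                 candidate_tests = cand),
            class = "sp_plan")
}

#' Select the analysis branch from assumption reports
#'
#' @param raw Raw-stage assumption report.
#' @param post Optional post-transform report (present iff a transform was
#'   applied).
#' @return `"parametric"`, `"parametric_welch"`, `"needs_transform"` (raw
#'   normality failed and no transform has been tried yet), or
#'   `"nonparametric"`.
#' @export
select_branch <- function(raw, post = NULL) {
  stopifnot(inherits(raw, "sp_assumption_report"))
  pick <- function(rep_) {
    if (rep_$normality_pass && rep_$homoscedasticity_pass) "parametric"
    else if (rep_$normality_pass) "parametric_welch"
    else "nonparametric"
  }
  if (is.null(post)) {
    b <- pick(raw)
    if (b == "nonparametric") "needs_transform" else b
  } else {
    stopifnot(inherits(post, "sp_assumption_report"))
    pick(post)
  }
}

# ---- the workflow ------------------------------------------------------

#' Run the full guided workflow
#'
#' Executes, in order: planning, optional outlier screen, raw assumption
#' checks, branch selection (with a guided transformation attempt when
#' per-group normality fails), the omnibus test of the valid branch,
#' branch-gated post-hoc comparisons when the omnibus is significant, and
#' effect sizes for parametric comparisons -- all recorded in a decision
#' trace. The caller intervenes at most twice, through `choices`.
#'
#' @param ds An `sp_dataset`.
#' @param cfg A [workflow_config()].
#' @param choices List with elements `transform` (`"log10"`, `"boxcox"`,
#'   `"arcsine_sqrt"`; a vector of two when `retry_transform` is set) and
#'   `posthoc` (overrides `cfg$posthoc`). Consulted only when the workflow
#'   reaches the corresponding decision.
#' @return An `sp_analysis_result`: plan, trace, assumption reports,
#'   transform record, omnibus result(s), pairwise comparisons, letters,
#'   descriptives, and status (`"completed"` or `"refused"`). Statistically
#'   unsupported paths (a dependent >2-group, two-way, or mixed design that
#'   needs the non-parametric branch; a blocked run with no transformation
#'   choice) yield a refusal result, not an R error.
#' @export
run_workflow <- function(ds, cfg = workflow_config(), choices = list()) {
  stopifnot(inherits(ds, "sp_dataset"))
  tr <- trace_new(cfg)
  res <- list(dataset = ds, config = cfg, plan = NULL,
              assumptions = list(raw = NULL, post = NULL),
              transform = list(name = "none", lambda = NULL,
                               input_domain_note = "", applied = FALSE),
              omnibus = NULL, pairwise = NULL, letters = NULL,
              descriptives = NULL, outliers = NULL,
              status = "completed", refusal_reason = NULL)
  class(res) <- "sp_analysis_result"

  tr$partial <- res
  out <- tryCatch({
    run_workflow_impl(ds, cfg, choices, tr, res)
  }, statpilot_refusal = function(e) {
    trace_node(tr, "refusal", "terminal: refusal", outcome = conditionMessage(e))
    trace_log(tr, "error", conditionMessage(e))
    partial <- tr$partial
    partial$status <- "refused"
    partial$refusal_reason <- conditionMessage(e)
    partial
  })
  out$trace <- trace_freeze(tr)
  # late fields set inside impl need carrying over
  out
}

run_workflow_impl <- function(ds, cfg, choices, tr, res) {
  plan <- plan_analysis(ds)
  res$plan <- plan
  tr$partial <- res
  trace_node(tr, "design", "design check",
             evidence = sprintf("k = %d, %s, %d factor(s)", plan$k_groups,
                                plan$design, plan$factors),
             outcome = paste("candidates:", paste(plan$candidate_tests, collapse = " / ")))

  # -- outlier screen (flag-only unless drop_outliers) --
  if (cfg$outlier_method != "none") {
    scr <- screen_outliers(ds, cfg$outlier_method,
                           alpha = cfg$outlier_alpha,
                           threshold = cfg$modz_threshold)
    res$outliers <- scr
    nflag <- sum(vapply(scr, function(r) r$n_flagged, 0L))
    trace_node(tr, "outlier_screen",
               sprintf("outlier screen (%s, per group)", cfg$outlier_method),
               evidence = sprintf("%d point(s) flagged", nflag),
               outcome = if (cfg$drop_outliers && nflag > 0)
                 "flagged points removed before analysis (explicit opt-in)"
               else "flagged points highlighted only")
    if (cfg$drop_outliers && nflag > 0) {
      keep <- rep(TRUE, nrow(ds$data))
      for (g in names(scr)) {
        idx <- which(ds$data$group == g)
        keep[idx[scr[[g]]$per_point$flagged]] <- FALSE
      }
      ds$data <- ds$data[keep, ]
      ds <- new_dataset(ds$data, ds$group_order, ds$source, ds$validation)
      res$dataset <- ds
      trace_log(tr, "warning", sprintf("%d outlier(s) removed on explicit request", nflag))
    }
  }

  res$descriptives <- describe_groups(ds, conf_level = cfg$conf_level)
  tr$partial <- res

  if (plan$factors == 2L)
    return(run_two_factor(ds, cfg, choices, tr, res, plan))

  # -- raw assumption checks --
  raw <- assess_assumptions(ds, "raw", alpha = cfg$alpha, center = cfg$center)
  res$assumptions$raw <- raw
  tr$partial <- res
  trace_assumptions(tr, raw, "raw")
  branch <- select_branch(raw)
  analysis_ds <- ds

  if (branch == "needs_transform") {
    tf_choices <- choices$transform
    if (is.null(tf_choices))
      refuse("assumption-blocked: per-group normality failed and no transformation choice was supplied")
    max_tries <- if (isTRUE(cfg$retry_transform)) 2L else 1L
    tf_choices <- head(tf_choices, max_tries)
    post <- NULL
    for (tf in tf_choices) {
      applied <- tryCatch(apply_transform(ds, tf, percent_scale = cfg$percent),
                          statpilot_error = function(e) e)
      if (inherits(applied, "error")) {
        trace_node(tr, "transform", sprintf("transformation (%s)", tf),
                   outcome = sprintf("not applicable: %s", conditionMessage(applied)))
        res$transform <- list(name = tf, lambda = NULL,
                              input_domain_note = conditionMessage(applied),
                              applied = FALSE)
        next
      }
      res$transform <- applied$record
      trace_node(tr, "transform", sprintf("transformation (%s)", tf),
                 outcome = applied$record$input_domain_note)
      post <- assess_assumptions(applied$dataset, "post_transform",
                                 alpha = cfg$alpha, center = cfg$center)
      res$assumptions$post <- post
      tr$partial <- res
      trace_assumptions(tr, post, "post_transform")
      branch <- select_branch(raw, post)
      if (branch != "nonparametric") {
        analysis_ds <- applied$dataset
        break
      }
    }
    if (is.null(post) && res$transform$applied == FALSE) {
      branch <- "nonparametric"
      trace_log(tr, "warning",
                "chosen transformation could not be applied; continuing on the non-parametric branch")
    }
    if (branch == "nonparametric") analysis_ds <- ds  # rank tests on original values
  }

  trace_node(tr, "branch", "branch decision",
             evidence = if (is.null(res$assumptions$post)) "raw-stage report"
                        else "post-transform report",
             outcome = branch)

  run_one_factor(analysis_ds, ds, cfg, choices, tr, res, plan, branch)
}

trace_assumptions <- function(tr, rep_, stage) {
  if (stage == "raw") {
    ps <- vapply(rep_$per_group_normality, function(x) x$p, 0)
    ev <- sprintf("min per-group Shapiro-Wilk p = %s",
                  if (anyNA(ps)) "not testable" else format(signif(min(ps), 4)))
    lab <- "normality check (raw, per group)"
  } else {
    ev <- sprintf("residual Shapiro-Wilk p = %s",
                  if (is.na(rep_$residual_normality$p)) "not testable"
                  else format(signif(rep_$residual_normality$p, 4)))
    lab <- "normality check (post-transform, model residuals)"
  }
  trace_node(tr, paste0("normality_", stage), lab, evidence = ev,
             outcome = if (rep_$normality_pass) "pass" else "fail")
  trace_node(tr, paste0("variance_", stage),
             sprintf("homoscedasticity check (%s, Brown-Forsythe)", stage),
             evidence = sprintf("p = %s", format(signif(rep_$homoscedasticity$p, 4))),
             outcome = if (rep_$homoscedasticity_pass) "pass" else "fail")
}

run_one_factor <- function(analysis_ds, orig_ds, cfg, choices, tr, res, plan,
                           branch) {
  gv <- group_values(analysis_ds)
  k <- plan$k_groups
  alpha <- cfg$alpha

  omni <-
    if (plan$design == "independent") {
      if (branch == "nonparametric") {
        if (k == 2) mann_whitney_u(gv[[1]], gv[[2]], alpha)
        else kruskal_wallis(gv, alpha)
      } else {
        variant <- if (branch == "parametric_welch") "welch" else "classic"
        if (k == 2) t_test_2g(gv[[1]], gv[[2]],
                              if (variant == "welch") "welch" else "student", alpha)
        else one_way_anova(gv, variant, alpha)
      }
    } else {
      if (k == 2) {
        pairs2 <- paired_vectors(analysis_ds)
        if (branch == "nonparametric")
          wilcoxon_signed_rank(pairs2$x, pairs2$y, alpha)
        else {
          if (branch == "parametric_welch")
            trace_log(tr, "note", "Welch variant not applicable to paired designs; paired t-test used")
          paired_t_test(pairs2$x, pairs2$y, alpha)
        }
      } else {
        if (branch == "nonparametric")
          refuse("non-parametric alternatives for repeated-measures designs with > 2 groups are not available; the analysis cannot proceed validly")
        if (branch == "parametric_welch")
          trace_log(tr, "note", "heteroscedasticity flagged; no Welch variant exists for repeated-measures ANOVA")
        rm_anova(analysis_ds, alpha)
      }
    }
  res$omnibus <- omni
  tr$partial <- res
  trace_node(tr, "omnibus", sprintf("omnibus test: %s", omni$test),
             evidence = sprintf("%s = %s, %s", omni$statistic_name,
                                format(signif(omni$statistic, 6)),
                                format_p(omni$p, cfg$p_display_floor)),
             outcome = if (omni$significant) "significant" else "not significant")

  if (k > 2 && (omni$significant || isTRUE(cfg$force_posthoc))) {
    if (!omni$significant)
      trace_log(tr, "warning", "post-hoc forced despite non-significant omnibus")
    res <- run_posthoc(gv, cfg, choices, tr, res, omni$branch,
                       analysis_ds$group_order)
  } else if (k > 2) {
    trace_node(tr, "posthoc", "post-hoc comparisons",
               outcome = "skipped: omnibus not significant", chosen = FALSE)
  }
  res
}

posthoc_menu <- function(branch) {
  if (branch == "parametric") c("tukey", "dunnett", "sidak")
  else c("dunn", "sidak")
}

run_posthoc <- function(gv, cfg, choices, tr, res, branch, group_order) {
  choice <- choices$posthoc %||% cfg$posthoc
  menu <- posthoc_menu(branch)
  if (identical(choice, "auto")) choice <- menu[1]
  if (!choice %in% menu)
    refuse(sprintf("post-hoc '%s' is not offered on the %s branch (menu: %s)",
                   choice, branch, paste(menu, collapse = ", ")))
  pw <- switch(choice,
    tukey = tukey_hsd(gv, alpha = cfg$alpha),
    dunnett = {
      ctrl <- cfg$control %||% group_order[1]
      dunnett_test(gv, control = ctrl, alpha = cfg$alpha)
    },
    sidak = {
      prs <- cfg$pairs %||% utils::combn(group_order, 2, simplify = FALSE)
      sidak_pairs(gv, prs,
                  branch = if (branch == "parametric") "parametric" else "nonparametric",
                  alpha = cfg$alpha)
    },
    dunn = dunn_test(gv, alpha = cfg$alpha))
  res$pairwise <- pw
  trace_node(tr, "posthoc", sprintf("post-hoc comparisons (%s)", choice),
             evidence = sprintf("%d comparison(s)", nrow(pw)),
             outcome = sprintf("%d significant at alpha = %g",
                               sum(pw$significant), cfg$alpha))
  covers_all <- nrow(pw) == choose(length(group_order), 2)
  if (covers_all) {
    res$letters <- compact_letters(pw, group_order)
    trace_log(tr, "note", sprintf("significance letters: %s",
      paste(sprintf("%s=%s", res$letters$group, res$letters$letters), collapse = " ")))
  } else {
    trace_log(tr, "note",
              "letters not assigned: the comparison set does not cover all pairs")
  }
  res
}

# Paired (x, y) vectors from a dependent 2-group dataset, aligned by subject.
paired_vectors <- function(ds) {
  m <- rm_cell_matrix(ds)
  if (ncol(m) != 2) stop_statpilot("paired extraction needs exactly 2 groups")
  list(x = m[, 1], y = m[, 2])
}

run_two_factor <- function(ds, cfg, choices, tr, res, plan) {
  # Assumption checks run on the design cells (group x second factor).
  cell_ds <- ds
  cell_ds$data$group <- paste(ds$data$group, ds$data$factor2, sep = ":")
  cell_ds <- new_dataset(cell_ds$data[, c("group", "value")],
                         source = ds$source)
  raw <- assess_assumptions(cell_ds, "raw", alpha = cfg$alpha, center = cfg$center)
  res$assumptions$raw <- raw
  tr$partial <- res
  trace_assumptions(tr, raw, "raw")
  branch <- select_branch(raw)
  analysis_ds <- ds

  if (branch == "needs_transform") {
    tf <- choices$transform
    if (is.null(tf))
      refuse("assumption-blocked: per-cell normality failed and no transformation choice was supplied")
    tf <- tf[1]
    applied <- tryCatch(apply_transform(ds, tf, percent_scale = cfg$percent),
                        statpilot_error = function(e) e)
    if (inherits(applied, "error")) {
      trace_node(tr, "transform", sprintf("transformation (%s)", tf),
                 outcome = sprintf("not applicable: %s", conditionMessage(applied)))
      refuse(paste0("non-parametric alternatives for two-way and mixed designs are not available, ",
                    "and the chosen transformation could not be applied"))
    }
    res$transform <- applied$record
    trace_node(tr, "transform", sprintf("transformation (%s)", tf),
               outcome = applied$record$input_domain_note)
    cell_post <- applied$dataset
    cell_post$data$group <- paste(cell_post$data$group, cell_post$data$factor2, sep = ":")
    cell_post <- new_dataset(cell_post$data[, c("group", "value")],
                             source = ds$source)
    post <- assess_assumptions(cell_post, "post_transform",
                               alpha = cfg$alpha, center = cfg$center)
    res$assumptions$post <- post
    tr$partial <- res
    trace_assumptions(tr, post, "post_transform")
    branch <- select_branch(raw, post)
    if (branch == "nonparametric")
      refuse("non-parametric alternatives for two-way and mixed designs are not available; assumptions still fail after transformation")
    analysis_ds <- applied$dataset
  }
  if (branch == "parametric_welch")
    trace_log(tr, "note",
              "heteroscedasticity flagged; no Welch variant exists for factorial designs (classical decomposition used)")
  trace_node(tr, "branch", "branch decision",
             evidence = if (is.null(res$assumptions$post)) "raw-stage report"
                        else "post-transform report",
             outcome = "parametric (factorial designs have no non-parametric fallback)")

  omni <- if (plan$design == "dependent") mixed_anova(analysis_ds, cfg$alpha)
          else two_way_anova(analysis_ds, cfg$alpha)
  res$omnibus <- omni
  for (nm in names(omni)) {
    o <- omni[[nm]]
    if (inherits(o, "sp_omnibus"))
      trace_node(tr, paste0("omnibus_", nm), sprintf("omnibus test: %s", o$test),
                 evidence = sprintf("F = %s, %s", format(signif(o$statistic, 6)),
                                    format_p(o$p, cfg$p_display_floor)),
                 outcome = if (o$significant) "significant" else "not significant")
  }
  res
}

#' @export
print.sp_analysis_result <- function(x, ...) {
  cat(sprintf("<sp_analysis_result> status: %s\n", x$status))
  if (!is.null(x$refusal_reason)) cat("  refusal:", x$refusal_reason, "\n")
  if (!is.null(x$plan))
    cat(sprintf("  design: %s, %d groups, %d factor(s)\n", x$plan$design,
                x$plan$k_groups, x$plan$factors))
  omni <- x$omnibus
  if (inherits(omni, "sp_omnibus")) omni <- list(omni)
  for (o in omni) if (inherits(o, "sp_omnibus"))
    cat(sprintf("  %s: %s = %s, %s\n", o$test, o$statistic_name,
                format(signif(o$statistic, 6)),
                format_p(o$p, x$config$p_display_floor)))
  if (!is.null(x$pairwise))
    cat(sprintf("  pairwise: %d comparison(s), %d significant\n",
                nrow(x$pairwise), sum(x$pairwise$significant)))
  invisible(x)
}
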