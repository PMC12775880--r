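# Branch-constrained pairwise comparisons and significance letters.
#
# Parametric branch offers Tukey HSD, Dunnett, and Sidak-adjusted selected
# pairs; the non-parametric branch offers Dunn's test and Sidak-adjusted
# pairwise Mann-Whitney tests. Methods outside the active branch are never
# run: that gating is enforced by the decision engine.

pairwise_tbl <- function(group_a, group_b, estimate, statistic, p_raw, p_adj,
                         method, alpha, effect = NA_real_) {
  tibble::tibble(group_a = group_a, group_b = group_b, estimate = estimate,
                 statistic = statistic, p_raw = p_raw,
                 p_adj = pmin(pmax(p_adj, p_raw), 1), method = method,
                 cohens_d = effect, significant = pmin(pmax(p_adj, p_raw), 1) < alpha)
}

msw_oneway <- function(groups) {
  n <- lengths(groups)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  list(msw = ssw / (sum(n) - length(groups)), df = sum(n) - length(groups))
}

#' Tukey's honestly-significant-difference test
#'
#' All `k(k-1)/2` pairs; `q = |m_a - m_b| / sqrt(MSW/2 (1/n_a + 1/n_b))`
#' (the Tukey-Kramer statistic for unequal n) with p from the studentized
#' range distribution with parameters `(k, N - k)`. Tukey p-values are
#' already family-adjusted, so `p_adj = p_raw`.
#'
#' @param groups Named list of numeric vectors (k >= 3, each n >= 2).
#' @param alpha Family-wise significance level.
#' @return Tibble of pairwise comparisons with pooled-sd Cohen's d per pair.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3, !is.null(names(groups)))
  lapply(groups, assert_numeric_vec)
  if (any(lengths(groups) < 2)) stop_statpilot("Tukey HSD needs n >= 2 per group")
  mw <- msw_oneway(groups)
  if (mw$msw <= 0) stop_statpilot("Tukey HSD undefined: zero within-group mean square")
  k <- length(groups)
  labs <- names(groups)
  pairs <- utils::combn(labs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- mean(groups[[a]]) - mean(groups[[b]])
    se <- sqrt(mw$msw / 2 * (1 / length(groups[[a]]) + 1 / length(groups[[b]])))
    q <- abs(est) / se
    p <- ptukey(q, nmeans = k, df = mw$df, lower.tail = FALSE)
    d <- tryCatch(cohens_d_pooled(groups[[a]], groups[[b]])$value,
                  error = function(e) NA_real_)
    pairwise_tbl(a, b, est, q, p, p, "tukey", alpha, d)
  })
  do.call(rbind, res)
}

#' Dunnett's many-to-one comparisons against a control
#'
#' `t_i = (m_i - m_c) / sqrt(MSW (1/n_i + 1/n_c))` with the pooled one-way
#' MSW; the two-sided family-adjusted p-value for each comparison is
#' `1 - P(max_j |T_j| < |t_i|)` under the `(k-1)`-variate t distribution
#' with the correlation structure implied by the sample sizes,
#' `rho_ij = sqrt(n_i n_j / ((n_i + n_c)(n_j + n_c)))`, evaluated by
#' deterministic seeded Genz-Bretz integration (>= 10^4 nodes, absolute
#' tolerance 5e-4), so repeated exports are identical.
#'
#' @param groups Named list of numeric vectors (k >= 3, each n >= 2).
#' @param control Name of the control group.
#' @param alpha Family-wise significance level.
#' @return Tibble of `k - 1` treatment-vs-control comparisons
#'   (`group_b` is the control) with raw and Dunnett-adjusted p.
#' @export
dunnett_test <- function(groups, control, alpha = 0.05) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (!control %in% names(groups))
    stop_statpilot(sprintf("control group not found: %s", control))
  if (length(groups) < 3) stop_statpilot("Dunnett's test needs k >= 3 groups")
  lapply(groups, assert_numeric_vec)
  if (any(lengths(groups) < 2)) stop_statpilot("Dunnett's test needs n >= 2 per group")
  mw <- msw_oneway(groups)
  if (mw$msw <= 0) stop_statpilot("Dunnett's test undefined: zero within-group mean square")
  trt <- setdiff(names(groups), control)
  n <- lengths(groups)
  nc <- n[[control]]
  tstat <- vapply(trt, function(g) {
    (mean(groups[[g]]) - mean(groups[[control]])) /
      sqrt(mw$msw * (1 / n[[g]] + 1 / nc))
  }, 0)
  m <- length(trt)
  corr <- diag(m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    corr[i, j] <- sqrt(n[[trt[i]]] * n[[trt[j]]] /
                       ((n[[trt[i]]] + nc) * (n[[trt[j]]] + nc)))
  p_adj <- with_private_seed(20240101, vapply(tstat, function(t0) {
    if (!is.finite(t0)) return(0)
    1 - mvtnorm::pmvt(lower = rep(-abs(t0), m), upper = rep(abs(t0), m),
                      df = mw$df, corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 5e-4,
                                                     maxpts = 50000))[1]
  }, 0))
  p_raw <- 2 * pt(abs(tstat), df = mw$df, lower.tail = FALSE)
  est <- vapply(trt, function(g) mean(groups[[g]]) - mean(groups[[control]]), 0)
  d <- vapply(trt, function(g)
    tryCatch(cohens_d_pooled(groups[[g]], groups[[control]])$value,
             error = function(e) NA_real_), 0)
  pairwise_tbl(trt, rep(control, m), est, tstat, p_raw, p_adj,
               "dunnett", alpha, d)
}

#' Sidak-adjusted comparisons of user-selected pairs
#'
#' Each selected pair is tested with the active branch's two-group test
#' (Student t or Mann-Whitney U) and the raw p-values receive the Sidak
#' adjustment `p_adj = 1 - (1 - p_raw)^m` for the `m` selected pairs.
#'
#' @param groups Named list of numeric vectors.
#' @param pairs List of length-2 character vectors naming the pairs.
#' @param branch `"parametric"` or `"nonparametric"`.
#' @param alpha Significance level after adjustment.
#' @return Tibble of comparisons (Cohen's d on the parametric branch only).
#' @export
sidak_pairs <- function(groups, pairs, branch = c("parametric", "nonparametric"),
                        alpha = 0.05) {
  branch <- match.arg(branch)
  stopifnot(is.list(groups), !is.null(names(groups)), is.list(pairs))
  if (length(pairs) < 1) stop_statpilot("select at least one pair")
  key <- vapply(pairs, function(p) paste(sort(p), collapse = "\r"), "")
  if (anyDuplicated(key)) stop_statpilot("duplicate pairs selected")
  for (p in pairs) {
    if (length(p) != 2) stop_statpilot("each pair must name exactly two groups")
    unknown <- setdiff(p, names(groups))
    if (length(unknown))
      stop_statpilot(sprintf("unknown group in pair: %s", paste(unknown, collapse = ", ")))
  }
  m <- length(pairs)
  res <- lapply(pairs, function(p) {
    x <- groups[[p[1]]]; y <- groups[[p[2]]]
    if (branch == "parametric") {
      tt <- t_test_2g(x, y, "student", alpha)
      praw <- tt$p; stat <- tt$statistic; eff <- tt$effect$value
    } else {
      mu <- mann_whitney_u(x, y, alpha)
      praw <- mu$p; stat <- mu$statistic; eff <- NA_real_
    }
    pairwise_tbl(p[1], p[2], mean(x) - mean(y), stat, praw,
                 1 - (1 - praw)^m, "sidak_pairs", alpha, eff)
  })
  do.call(rbind, res)
}

#' Dunn's test of multiple comparisons using rank sums
#'
#' On the pooled mid-ranks,
#' `z_ab = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_a + 1/n_b))`
#' with two-sided normal p-values, Sidak-adjusted over all pairs by default.
#'
#' @param groups Named list of numeric vectors (k >= 3, each non-empty).
#' @param adjust `"sidak"` (default) or `"none"`.
#' @param alpha Significance level after adjustment.
#' @return Tibble of all pairwise comparisons; `estimate` is the mean-rank
#'   difference.
#' @export
dunn_test <- function(groups, adjust = c("sidak", "none"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 3, !is.null(names(groups)))
  lapply(groups, assert_numeric_vec)
  if (any(lengths(groups) < 1)) stop_statpilot("Dunn's test needs non-empty groups")
  allv <- unlist(groups, use.names = FALSE)
  N <- length(allv)
  r <- rank(allv)
  g <- rep(names(groups), lengths(groups))
  rbar <- tapply(r, factor(g, levels = names(groups)), mean)
  tie_tab <- table(allv)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  n <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    praw <- if (se > 0) 2 * stats::pnorm(abs(z), lower.tail = FALSE) else 1
    padj <- if (adjust == "sidak") 1 - (1 - praw)^m else praw
    pairwise_tbl(a, b, rbar[[a]] - rbar[[b]], z, praw, padj, "dunn", alpha)
  })
  do.call(rbind, res)
}

#' Compact letter display
#'
#' Insert-and-absorb over the non-significance graph: start with one letter
#' covering all groups; for every significant pair, split each letter
#' containing both members into two letters (one without each member);
#' absorb letters whose group set is contained in another's. Groups share a
#' letter iff their comparison is non-significant.
#'
#' @param pairs Tibble of pairwise comparisons (needs `group_a`, `group_b`,
#'   `significant`); the same pair listed twice with conflicting
#'   significance is an error.
#' @param group_order Character vector of all groups, in display order.
#' @return Tibble with `group` and `letters` (e.g. `"a"`, `"ab"`), letters
#'   assigned in `group_order`.
#' @export
compact_letters <- function(pairs, group_order) {
  stopifnot(all(c("group_a", "group_b", "significant") %in% names(pairs)))
  key <- apply(cbind(pmin(pairs$group_a, pairs$group_b),
                     pmax(pairs$group_a, pairs$group_b)), 1, paste, collapse = "\r")
  agg <- tapply(pairs$significant, key, unique)
  if (any(lengths(agg) > 1))
    stop_statpilot("contradictory input: a pair is listed with conflicting significance")
  covered <- unique(c(pairs$group_a, pairs$group_b))
  if (!all(covered %in% group_order))
    stop_statpilot("pairs mention groups missing from group_order")

  sig <- pairs[pairs$significant, c("group_a", "group_b")]
  sig <- sig[!duplicated(paste(pmin(sig$group_a, sig$group_b),
                               pmax(sig$group_a, sig$group_b))), ]
  cols <- list(group_order)            # letter "columns": sets of groups
  if (nrow(sig) > 0) for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    newcols <- list()
    for (cl in cols) {
      if (a %in% cl && b %in% cl) {
        newcols <- c(newcols, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else newcols <- c(newcols, list(cl))
    }
    # absorb: drop duplicates and columns properly contained in another
    newcols <- newcols[!duplicated(lapply(newcols, sort))]
    keep <- rep(TRUE, length(newcols))
    for (p in seq_along(newcols)) for (q in seq_along(newcols))
      if (p != q && length(newcols[[p]]) < length(newcols[[q]]) &&
          all(newcols[[p]] %in% newcols[[q]]))
        keep[p] <- FALSE
    cols <- newcols[keep]
  }
  cols <- cols[lengths(cols) > 0]
  # exact minimization: the insert-absorb heuristic can occasionally use one
  # letter more than necessary; for realistic group counts, search covers
  # built from maximal cliques of the non-significance graph
  if (length(group_order) <= 8) {
    sig_pairs <- if (nrow(sig) > 0)
      lapply(seq_len(nrow(sig)), function(i) c(sig$group_a[i], sig$group_b[i]))
    else list()
    better <- minimal_letter_cover(group_order, sig_pairs, length(cols))
    if (!is.null(better)) cols <- better
  }
  # order letters by first member in group_order for stable output
  first_idx <- vapply(cols, function(cl) min(match(cl, group_order)), 0)
  cols <- cols[order(first_idx)]
  letts <- vapply(group_order, function(g)
    paste(letters[which(vapply(cols, function(cl) g %in% cl, TRUE))],
          collapse = ""), "")
  out <- tibble::tibble(group = group_order, letters = unname(letts))
  # verify the defining invariant before returning
  for (i in seq_len(nrow(pairs))) {
    la <- out$letters[out$group == pairs$group_a[i]]
    lb <- out$letters[out$group == pairs$group_b[i]]
    share <- length(intersect(strsplit(la, "")[[1]], strsplit(lb, "")[[1]])) > 0
    if (share == pairs$significant[i])
      stop_statpilot("letter assignment failed its defining invariant")
  }
  out
}

# Exact search for a letter cover smaller than `limit`: choose among the
# maximal cliques of the non-significance graph a minimum family that
# covers every group and every non-significant pair. Returns NULL when no
# smaller cover exists.
minimal_letter_cover <- function(groups, sig_pairs, limit) {
  k <- length(groups)
  nonsig <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  diag(nonsig) <- FALSE
  for (p in sig_pairs) {
    nonsig[p[1], p[2]] <- FALSE
    nonsig[p[2], p[1]] <- FALSE
  }
  # all cliques by subset enumeration (k <= 8: at most 255 subsets)
  subsets <- lapply(seq_len(2^k - 1), function(m) groups[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  is_clique <- vapply(subsets, function(s) {
    if (length(s) <= 1) return(TRUE)
    idx <- match(s, groups)
    all(nonsig[t(utils::combn(idx, 2))])
  }, TRUE)
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i)
    !any(vapply(seq_along(cliques), function(j)
      j != i && length(cliques[[i]]) < length(cliques[[j]]) &&
        all(cliques[[i]] %in% cliques[[j]]), TRUE)), TRUE)]
  edges <- which(upper.tri(nonsig) & nonsig, arr.ind = TRUE)
  covers <- function(family) {
    if (!all(groups %in% unlist(family))) return(FALSE)
    if (nrow(edges) == 0) return(TRUE)
    all(apply(edges, 1, function(e) any(vapply(family, function(cl)
      all(groups[e] %in% cl), TRUE))))
  }
  for (sz in seq_len(min(limit - 1, length(maximal)))) {
    for (cc in utils::combn(length(maximal), sz, simplify = FALSE)) {
      if (covers(maximal[cc])) return(maximal[cc])
    }
  }
  NULL
}
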