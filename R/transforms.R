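# Guided variance-stabilizing transformations.
#
# All three transforms are strictly monotone on their domains, so ranks --
# and with them every rank-based test downstream -- are unchanged. Domain
# violations are hard errors: silently shifting or clipping data would
# change the inference invisibly.

#' Log10 transformation
#'
#' @param values Strictly positive numeric vector.
#' @return Elementwise `log10(values)`.
#' @export
log10_transform <- function(values) {
  assert_numeric_vec(values)
  bad <- sum(values <= 0)
  if (bad > 0)
    stop_statpilot(sprintf(
      "log10 transform: %d non-positive value%s; shift or rescale the data explicitly if that is defensible",
      bad, if (bad == 1) "" else "s"))
  log10(values)
}

#' Maximum-likelihood Box-Cox exponent
#'
#' Maximizes the profile log-likelihood
#' `LL(lambda) = -(n/2) log sigma2(lambda) + (lambda - 1) sum(log x)`,
#' where `sigma2(lambda)` is the ML variance of the transformed sample,
#' over `lambda` in `[-5, 5]` by golden-section/parabolic search
#' (tolerance 1e-5). The exponent is meant to be estimated once on the
#' pooled values of all selected groups and applied identically to every
#' group, so group means stay comparable.
#'
#' @param values Strictly positive numeric vector, n >= 3, nonzero variance.
#' @param interval Search interval, default `c(-5, 5)`.
#' @return The estimated exponent (numeric scalar).
#' @export
boxcox_mle_lambda <- function(values, interval = c(-5, 5)) {
  assert_numeric_vec(values)
  if (any(values <= 0)) stop_statpilot("Box-Cox requires strictly positive values")
  n <- length(values)
  if (n < 3) stop_statpilot("Box-Cox exponent estimation needs n >= 3")
  if (sd(values) == 0) stop_statpilot("Box-Cox exponent undefined for constant data")
  slog <- sum(log(values))
  ll <- function(lambda) {
    y <- boxcox_transform(values, lambda)
    s2 <- mean((y - mean(y))^2)
    -(n / 2) * log(s2) + (lambda - 1) * slog
  }
  opt <- optimize(ll, interval = interval, maximum = TRUE, tol = 1e-5)
  opt$maximum
}

#' Box-Cox power transformation
#'
#' `(x^lambda - 1) / lambda` for `lambda != 0`; `log(x)` at `lambda = 0`
#' (the switch triggers at `|lambda| < 1e-10`, where the two branches agree
#' to floating-point accuracy).
#'
#' @param values Strictly positive numeric vector.
#' @param lambda Exponent.
#' @return Transformed values.
#' @export
boxcox_transform <- function(values, lambda) {
  assert_numeric_vec(values)
  if (any(values <= 0)) stop_statpilot("Box-Cox requires strictly positive values")
  if (abs(lambda) < 1e-10) log(values) else (values^lambda - 1) / lambda
}

#' Arcsine square-root transformation for proportions
#'
#' @param values Numeric vector in `[0, 1]`, or in `[0, 100]` with
#'   `percent_scale = TRUE` (divided by 100 first). Values outside the
#'   admissible interval are an error; nothing is clipped.
#' @param percent_scale Interpret input as percentages.
#' @return Elementwise `asin(sqrt(x))`, in `[0, pi/2]`.
#' @export
arcsine_sqrt_transform <- function(values, percent_scale = FALSE) {
  assert_numeric_vec(values)
  if (percent_scale) {
    if (any(values < 0 | values > 100))
      stop_statpilot("arcsine square root (percent scale) requires values in [0, 100]")
    values <- values / 100
  }
  if (any(values < 0 | values > 1))
    stop_statpilot("arcsine square root requires proportions in [0, 1]")
  asin(sqrt(values))
}

#' Apply a named transformation to a dataset
#'
#' Applies the transform to every value (a single pooled Box-Cox exponent,
#' estimated on all selected groups together, when `name = "boxcox"`).
#'
#' @param ds An `sp_dataset`.
#' @param name `"log10"`, `"boxcox"`, `"arcsine_sqrt"`, or `"none"`.
#' @param percent_scale Passed to [arcsine_sqrt_transform()].
#' @return List with `dataset` (transformed copy) and `record` (name,
#'   estimated lambda if Box-Cox, domain note, applied flag).
#' @export
apply_transform <- function(ds, name = c("none", "log10", "boxcox", "arcsine_sqrt"),
                            percent_scale = FALSE) {
  stopifnot(inherits(ds, "sp_dataset"))
  name <- match.arg(name)
  lambda <- NULL
  v <- ds$data$value
  newv <- switch(name,
    none = v,
    log10 = log10_transform(v),
    boxcox = {
      lambda <- boxcox_mle_lambda(v)
      boxcox_transform(v, lambda)
    },
    arcsine_sqrt = arcsine_sqrt_transform(v, percent_scale = percent_scale))
  out <- ds
  out$data$value <- newv
  note <- switch(name,
    none = "no transformation applied",
    log10 = "log10 on strictly positive values",
    boxcox = sprintf("pooled ML exponent lambda = %.5f on [-5, 5]", lambda),
    arcsine_sqrt = if (percent_scale) "percentages divided by 100, then asin(sqrt(x))"
                   else "asin(sqrt(x)) on proportions")
  list(dataset = out,
       record = list(name = name, lambda = lambda,
                     input_domain_note = note, applied = name != "none"))
}
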