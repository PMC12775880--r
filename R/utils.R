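`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Format a p-value for display
#'
#' Values below the display floor are printed as `"p < <floor>"`; all stored
#' numeric p-values remain exact. This mirrors the reporting convention of
#' mainstream statistics packages.
#'
#' @param p Numeric p-value (may be `NA`).
#' @param floor Display floor, default 0.001.
#' @return A character scalar such as `"p = 0.0534"` or `"p < 0.001"`.
#' @export
format_p <- function(p, floor = 0.001) {
  if (is.null(p) || length(p) == 0 || is.na(p)) return("p = NA")
  if (p < floor) sprintf("p < %s", format(floor)) else sprintf("p = %.4f", p)
}

stop_statpilot <- function(msg, class = "statpilot_error", ...) {
  stop(structure(class = c(class, "statpilot_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# Refusals are "valid" hard stops: statistically unsupported paths, not bugs.
refuse <- function(msg) stop_statpilot(msg, class = "statpilot_refusal")

is_refusal <- function(x) inherits(x, "statpilot_refusal")

assert_numeric_vec <- function(x, what = "values") {
  if (!is.numeric(x) || length(x) == 0)
    stop_statpilot(sprintf("%s must be a non-empty numeric vector", what))
  if (any(!is.finite(x)))
    stop_statpilot(sprintf("%s contains non-finite entries", what))
  invisible(x)
}
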