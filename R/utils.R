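#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Abort helpers: "input" errors are user-facing argument problems, "config"
# errors malformed configurations, "computation" errors numerically undefined
# results. All carry a class so callers (and the CLI) can map them to exit
# codes.
stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("ds_input_error", "ds_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("ds_config_error", "ds_error")))
}

stop_computation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("ds_computation_error", "ds_error")))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_input("`%s` must be > %g (got %g)", name, lower, x)
  }
  if (!strict_lower && (x < lower || x > upper)) {
    stop_input("`%s` must be in [%g, %g] (got %g)", name, lower, upper, x)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower) {
    stop_input("`%s` must be an integer >= %d", name, lower)
  }
  invisible(as.integer(x))
}

assert_sample <- function(x, name, min_n = 1L, positive = FALSE) {
  if (!is.numeric(x) || length(x) < min_n || anyNA(x)) {
    stop_input("`%s` must be a numeric sample of at least %d non-missing values", name, min_n)
  }
  if (positive && any(x <= 0)) {
    stop_input("`%s` must be strictly positive", name)
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input("%s is missing required column(s): %s", what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Draw from a generator, resampling any non-positive values. The mass below
# zero is negligible at the package defaults, so this converges immediately in
# practice; the iteration cap guards pathological configurations.
rpositive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50L)) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop_computation("could not draw strictly positive values from Normal(%g, %g)", mean, sd)
}
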