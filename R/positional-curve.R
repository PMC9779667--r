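#' Positional smoothing curve along cell files
#'
#' Pools (cell index, value) points across roots and fits a local polynomial
#' regression (loess: tricube-weighted local fitting) of the chosen cell
#' variable against cell number from the quiescent centre, evaluated on the
#' integer index grid. The confidence band comes from a seeded bootstrap
#' over roots (resampling whole files, refitting, and taking pointwise
#' quantiles), which respects the within-root correlation of consecutive
#' cells. Slope diagnostics (the maximum fitted per-cell slope and the index
#' where it occurs) summarize the steepness of the elongation ramp and the
#' position of the kink where elongation initiates.
#'
#' @param cell_files Long-format tibble (`root_id`, `cell_index`,
#'   `length_um`, `width_um`); filter to one condition before calling.
#' @param variable `"length"`, `"width"` or `"anisotropy"` (length/width).
#' @param span Loess span in (0, 1]; widened automatically (with a warning)
#'   when the local sample is too small for the polynomial degree.
#' @param degree Local polynomial degree, 1 or 2.
#' @param ci Confidence level of the bootstrap band.
#' @param n_boot Bootstrap resamples over roots.
#' @param seed Integer seed for the bootstrap.
#' @return A `positional_curve` tibble: `cell_index`, `fit`, `lower`,
#'   `upper`, with attributes `max_slope`, `max_slope_index`, `variable`,
#'   `span`, `degree`.
#' @export
#' @examples
#' files <- generate_cell_files(default_cell_file_specs()["dark"], 4, seed = 1)
#' pc <- positional_curve(files, "length", n_boot = 20, seed = 1)
positional_curve <- function(cell_files, variable = c("length", "width", "anisotropy"),
                             span = 0.75, degree = 2L, ci = 0.95,
                             n_boot = 200L, seed = 1L) {
  variable <- match.arg(variable)
  assert_columns(cell_files, c("root_id", "cell_index", "length_um", "width_um"),
                 "cell files")
  assert_number(span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  if (!degree %in% c(1L, 2L)) stop_input("`degree` must be 1 or 2")
  assert_number(ci, "ci", lower = 0, upper = 1)
  n_boot <- assert_count(n_boot, "n_boot", lower = 0L)
  seed <- assert_count(seed, "seed", lower = 0L)
  roots <- unique(cell_files$root_id)
  if (length(roots) < 2L) stop_input("at least 2 cell files are required")

  value_of <- function(df) {
    switch(variable,
           length = df$length_um,
           width = df$width_um,
           anisotropy = anisotropy(df$length_um, df$width_um))
  }
  grid <- seq(min(cell_files$cell_index), max(cell_files$cell_index))

  fit_once <- function(df, span_now) {
    df <- tibble(x = df$cell_index, y = value_of(df))
    # a loess neighbourhood needs more points than the local polynomial has
    # coefficients; widen the span (once per shortfall) rather than fail
    repeat {
      fit <- tryCatch(
        suppressWarnings(stats::loess(y ~ x, data = df, span = span_now,
                                      degree = degree,
                                      control = stats::loess.control(surface = "direct"))),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        pred <- tryCatch(stats::predict(fit, newdata = data.frame(x = grid)),
                         error = function(e) NULL)
        if (!is.null(pred)) return(list(pred = unname(pred), span = span_now))
      }
      if (span_now >= 1) {
        stop_computation("loess fit failed even at span = 1")
      }
      span_now <- min(1, span_now * 1.5)
      warning(sprintf("loess span widened to %.2f (insufficient local points)",
                      span_now))
    }
  }

  main <- fit_once(cell_files, span)
  boot <- NULL
  if (n_boot > 0L) {
    by_root <- split(cell_files, cell_files$root_id)
    boot <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- sample(roots, length(roots), replace = TRUE)
        df <- dplyr::bind_rows(by_root[take])
        suppressWarnings(fit_once(df, main$span)$pred)
      }, numeric(length(grid)))
    })
  }
  alpha <- (1 - ci) / 2
  lower <- if (is.null(boot)) rep(NA_real_, length(grid)) else
    apply(boot, 1L, stats::quantile, probs = alpha, na.rm = TRUE)
  upper <- if (is.null(boot)) rep(NA_real_, length(grid)) else
    apply(boot, 1L, stats::quantile, probs = 1 - alpha, na.rm = TRUE)

  slopes <- diff(main$pred)
  out <- tibble(cell_index = grid, fit = main$pred, lower = lower, upper = upper)
  attr(out, "max_slope") <- if (length(slopes)) max(slopes, na.rm = TRUE) else NA_real_
  attr(out, "max_slope_index") <- if (length(slopes))
    grid[which.max(slopes)] else NA_integer_
  attr(out, "variable") <- variable
  attr(out, "span") <- main$span
  attr(out, "degree") <- degree
  class(out) <- c("positional_curve", class(out))
  out
}

#' Plot a positional curve
#'
#' @param x A [positional_curve()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot.positional_curve <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x), ggplot2::aes(x = .data$cell_index, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cell number from the QC",
                  y = attr(x, "variable")) +
    ggplot2::theme_minimal()
}
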