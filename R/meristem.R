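#' Fit a two-component Gaussian mixture to cell lengths by EM
#'
#' Separates short meristematic cells from long elongating cells. The E step
#' computes per-cell posterior responsibilities under the two Gaussians; the
#' M step updates the weighted means, variances and mixing weight.
#' Initialization splits the sample at its median (each half seeding one
#' component), which is deterministic and robust for well-separated zones;
#' seeded random restarts are available via `init = "random"`. Components
#' are labelled by mean order: the smaller-mean component is "short".
#'
#' @param lengths Cell lengths (um), >= 10 values, at least 2 distinct.
#' @param tol Convergence threshold on the relative log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Variance floor (um^2); hitting it flags a degenerate
#'   fit.
#' @param init `"median"` (deterministic median split) or `"random"`
#'   (seeded random responsibilities).
#' @param n_restarts Number of restarts when `init = "random"`; the best
#'   log-likelihood wins.
#' @param seed Seed for random initialization (ignored for `"median"`).
#' @return A `gmm_fit` object: `mu_short`, `mu_long`, `sigma_short`,
#'   `sigma_long`, `weight_short`, `posterior_short` (per input cell),
#'   `log_likelihood_trace`, `converged`, `degenerate`, `n_iterations`.
#' @export
#' @examples
#' x <- c(rnorm(50, 8, 1.5), rnorm(30, 60, 15))
#' fit <- fit_two_gaussian_em(x)
#' c(fit$mu_short, fit$mu_long)
fit_two_gaussian_em <- function(lengths, tol = 1e-8, max_iter = 500L,
                                var_floor = 1e-6,
                                init = c("median", "random"),
                                n_restarts = 5L, seed = 1L) {
  assert_sample(lengths, "lengths", min_n = 10L)
  if (length(unique(lengths)) < 2L) {
    stop_input("`lengths` must contain at least 2 distinct values")
  }
  init <- match.arg(init)
  assert_number(tol, "tol", lower = 0, strict_lower = TRUE)
  max_iter <- assert_count(max_iter, "max_iter")

  run_em <- function(gamma0) {
    x <- lengths
    n <- length(x)
    gamma <- gamma0  # responsibility of component 1 per observation
    mu <- c(0, 0); sigma2 <- c(1, 1); w1 <- 0.5
    ll_trace <- numeric(0)
    degenerate <- FALSE
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      # M step
      n1 <- sum(gamma); n2 <- n - n1
      if (n1 < 1e-10 || n2 < 1e-10) { degenerate <- TRUE; break }
      mu[1] <- sum(gamma * x) / n1
      mu[2] <- sum((1 - gamma) * x) / n2
      sigma2[1] <- sum(gamma * (x - mu[1])^2) / n1
      sigma2[2] <- sum((1 - gamma) * (x - mu[2])^2) / n2
      if (any(sigma2 < var_floor)) {
        sigma2 <- pmax(sigma2, var_floor)
        degenerate <- TRUE
      }
      w1 <- n1 / n
      # E step + log-likelihood
      d1 <- w1 * stats::dnorm(x, mu[1], sqrt(sigma2[1]))
      d2 <- (1 - w1) * stats::dnorm(x, mu[2], sqrt(sigma2[2]))
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      gamma <- d1 / tot
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      if (it > 1L) {
        rel <- abs(ll - ll_trace[it - 1L]) / (abs(ll_trace[it - 1L]) + tol)
        if (rel < tol) { converged <- TRUE; break }
      }
      if (it >= max_iter) break
    }
    list(mu = mu, sigma2 = sigma2, w1 = w1, gamma = gamma,
         ll_trace = ll_trace, converged = converged,
         degenerate = degenerate, n_iterations = it)
  }

  if (init == "median") {
    fits <- list(run_em(as.numeric(lengths <= stats::median(lengths))))
  } else {
    n_restarts <- assert_count(n_restarts, "n_restarts")
    fits <- withr::with_seed(seed, {
      lapply(seq_len(n_restarts), function(i) run_em(stats::runif(length(lengths))))
    })
  }
  best <- fits[[which.max(vapply(fits, function(f) max(f$ll_trace), numeric(1)))]]

  if (best$degenerate) {
    warning("degenerate mixture fit (vanishing component or floored variance)")
  }
  short <- which.min(best$mu)
  long <- 3L - short
  posterior_short <- if (short == 1L) best$gamma else 1 - best$gamma
  structure(
    list(
      mu_short = best$mu[short], mu_long = best$mu[long],
      sigma_short = sqrt(best$sigma2[short]), sigma_long = sqrt(best$sigma2[long]),
      weight_short = if (short == 1L) best$w1 else 1 - best$w1,
      posterior_short = posterior_short,
      log_likelihood_trace = best$ll_trace,
      converged = best$converged,
      degenerate = best$degenerate,
      n_iterations = best$n_iterations
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "Two-Gaussian mixture fit (%d cells, %d iterations, %s)\n",
    length(x$posterior_short), x$n_iterations,
    if (x$converged) "converged" else "not converged"
  ))
  cat(sprintf("  short: mu = %.2f um, sigma = %.2f, weight = %.2f\n",
              x$mu_short, x$sigma_short, x$weight_short))
  cat(sprintf("  long:  mu = %.2f um, sigma = %.2f\n", x$mu_long, x$sigma_long))
  invisible(x)
}

#' Classify cells as meristematic from a mixture fit
#'
#' A cell is meristematic when its posterior probability of belonging to the
#' short-length component strictly exceeds the threshold (default 0.8).
#' Cells below the threshold are elongating.
#'
#' @param fit A [fit_two_gaussian_em()] result.
#' @param threshold Posterior cutoff in (0, 1); strict inequality.
#' @return Logical vector, one element per cell in the fitted sample.
#' @export
classify_meristematic <- function(fit, threshold = 0.8) {
  if (!inherits(fit, "gmm_fit")) stop_input("`fit` must be a gmm_fit")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop_input("`threshold` must lie strictly within (0, 1)")
  }
  fit$posterior_short > threshold
}

#' Count isodiametric cells from the quiescent centre
#'
#' Counts the initial contiguous run of cells (from the QC) that are not
#' longer than wide (length <= width); the run stops at the first cell
#' longer than wide. `contiguous = FALSE` counts isodiametric cells over
#' the whole file instead.
#'
#' @param lengths,widths Ordered per-cell measurements (um), index 1 at the
#'   QC.
#' @param contiguous Stop at the first non-isodiametric cell (default).
#' @return Integer count.
#' @export
#' @examples
#' count_isodiametric(c(5, 6, 7, 5), c(6, 6, 6, 6))  # 2
count_isodiametric <- function(lengths, widths, contiguous = TRUE) {
  assert_sample(lengths, "lengths", min_n = 1L, positive = TRUE)
  assert_sample(widths, "widths", min_n = 1L, positive = TRUE)
  if (length(lengths) != length(widths)) {
    stop_input("`lengths` and `widths` must have equal length")
  }
  iso <- lengths <= widths
  if (!contiguous) return(sum(iso))
  first_long <- match(FALSE, iso)
  if (is.na(first_long)) length(iso) else first_long - 1L
}

#' Count transition cells
#'
#' The transition zone runs from the first cell longer than wide up to the
#' last cell whose length is under `factor` (default 150%) of its
#' predecessor's; the scan stops at the first cell whose length is at least
#' `factor` times the previous cell's. Returns 0 when no cell is longer
#' than wide.
#'
#' @inheritParams count_isodiametric
#' @param factor Per-cell growth ratio that ends the transition zone.
#' @return Integer count.
#' @export
#' @examples
#' count_transition(c(5, 5, 7, 9, 14, 30), rep(6, 6))  # 2
count_transition <- function(lengths, widths, factor = 1.5) {
  assert_sample(lengths, "lengths", min_n = 1L, positive = TRUE)
  assert_sample(widths, "widths", min_n = 1L, positive = TRUE)
  if (length(lengths) != length(widths)) {
    stop_input("`lengths` and `widths` must have equal length")
  }
  assert_number(factor, "factor", lower = 1, strict_lower = TRUE)
  start <- match(TRUE, lengths > widths)
  if (is.na(start)) return(0L)
  count <- 1L
  i <- start + 1L
  while (i <= length(lengths) && lengths[i] < factor * lengths[i - 1L]) {
    count <- count + 1L
    i <- i + 1L
  }
  count
}

#' Mature cell length
#'
#' Mean length of the `k` most elongated cells (default 10), pooled per
#' condition.
#'
#' @param lengths Cell lengths (um).
#' @param k Number of longest cells to average over.
#' @return Mean length (um).
#' @export
#' @examples
#' mature_cell_length(1:20)  # 15.5
mature_cell_length <- function(lengths, k = 10L) {
  k <- assert_count(k, "k")
  assert_sample(lengths, "lengths", min_n = k)
  mean(sort(lengths, decreasing = TRUE)[seq_len(k)])
}

#' Length of the first elongated cell
#'
#' Length of the lowest-index cell labelled elongating (non-meristematic).
#' Returns `NA` with a warning when every cell is meristematic.
#'
#' @param lengths Ordered cell lengths (um), index 1 at the QC.
#' @param meristematic Logical vector of per-cell meristem labels (as from
#'   [classify_meristematic()]).
#' @return Length (um), or `NA` if no cell is elongating.
#' @export
#' @examples
#' first_elongated_length(c(8, 9, 22, 40), c(TRUE, TRUE, FALSE, FALSE))  # 22
first_elongated_length <- function(lengths, meristematic) {
  assert_sample(lengths, "lengths", min_n = 1L)
  if (!is.logical(meristematic) || length(meristematic) != length(lengths)) {
    stop_input("`meristematic` must be a logical vector matching `lengths`")
  }
  idx <- match(FALSE, meristematic)
  if (is.na(idx)) {
    warning("all cells are meristematic; no elongated cell found")
    return(NA_real_)
  }
  lengths[idx]
}

#' Summarize mitotic-marker counts per condition
#'
#' Per-condition mean counts plus pairwise fold changes
#' (mean A / mean B) with Mann-Whitney U p-values and Benjamini-Hochberg
#' correction across the requested pairs.
#'
#' @param counts Tibble with columns `condition` and `count` (as from
#'   [generate_mitotic_counts()]).
#' @param pairs List of length-2 character vectors `c(numerator,
#'   denominator)`; default: all ordered pairs.
#' @return List with `means` (tibble: condition, mean_count, n_roots) and
#'   `fold_changes` (tibble: numerator, denominator, fold_change, p_value,
#'   p_adjusted).
#' @export
#' @examples
#' ct <- generate_mitotic_counts(c(dark = 1, darkW = 8), 30, seed = 1)
#' mitotic_summary(ct, pairs = list(c("darkW", "dark")))
mitotic_summary <- function(counts, pairs = NULL) {
  assert_columns(counts, c("condition", "count"), "mitotic counts")
  if (!nrow(counts)) stop_input("`counts` must be non-empty")
  if (any(counts$count < 0)) stop_input("counts must be non-negative")
  means <- dplyr::summarise(
    dplyr::group_by(counts, .data$condition),
    mean_count = mean(.data$count),
    n_roots = dplyr::n(),
    .groups = "drop"
  )
  conds <- means$condition
  if (is.null(pairs)) {
    pairs <- list()
    for (a in conds) for (b in conds) if (a != b) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  fc_rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% conds)) stop_input("pair (%s) includes an absent condition",
                                        paste(pr, collapse = ", "))
    ca <- counts$count[counts$condition == pr[1]]
    cb <- counts$count[counts$condition == pr[2]]
    fc <- if (mean(cb) == 0) NA_real_ else mean(ca) / mean(cb)
    p <- suppressWarnings(stats::wilcox.test(ca, cb))$p.value
    tibble(numerator = pr[1], denominator = pr[2], fold_change = fc, p_value = p)
  })
  fcs <- dplyr::bind_rows(fc_rows)
  if (nrow(fcs)) fcs$p_adjusted <- bh_adjust(fcs$p_value)
  list(means = means, fold_changes = fcs)
}

#' Zonation analysis of cell files
#'
#' Pools cell lengths per condition, fits the two-Gaussian mixture
#' ([fit_two_gaussian_em()]), labels meristematic cells (posterior >
#' `threshold`), and derives per-root and per-condition zonation metrics:
#' GMM meristem cell count (total labelled cells, plus the contiguous run
#' from the QC), isodiametric and transition counts, and the first
#' elongated cell's length. Mature cell length is pooled per condition.
#' `per_root = TRUE` fits the mixture separately for each root instead.
#'
#' @param cell_files Long-format tibble (`root_id`, `condition`,
#'   `cell_index`, `length_um`, `width_um`), as from
#'   [generate_cell_files()] or [read_measurements()].
#' @param threshold Posterior cutoff for the meristematic label.
#' @param transition_factor Growth ratio ending the transition zone.
#' @param k_mature Number of longest cells for mature cell length.
#' @param per_root Fit the mixture per root rather than pooled per
#'   condition.
#' @param ... Passed on to [fit_two_gaussian_em()].
#' @return List: `fits` (per condition), `per_root` (tibble: one row per
#'   root), `per_condition` (tibble with means over roots plus
#'   `mature_cell_length`), `labels` (input tibble plus `meristematic`).
#' @export
zonation_summary <- function(cell_files, threshold = 0.8,
                             transition_factor = 1.5, k_mature = 10L,
                             per_root = FALSE, ...) {
  assert_columns(cell_files,
                 c("root_id", "condition", "cell_index", "length_um", "width_um"),
                 "cell files")
  cell_files <- dplyr::arrange(cell_files, .data$condition, .data$root_id,
                               .data$cell_index)
  fits <- list()
  cell_files$meristematic <- NA
  for (cond in unique(cell_files$condition)) {
    sel <- cell_files$condition == cond
    if (per_root) {
      for (rid in unique(cell_files$root_id[sel])) {
        rsel <- sel & cell_files$root_id == rid
        fit <- fit_two_gaussian_em(cell_files$length_um[rsel], ...)
        fits[[rid]] <- fit
        cell_files$meristematic[rsel] <- classify_meristematic(fit, threshold)
      }
    } else {
      fit <- fit_two_gaussian_em(cell_files$length_um[sel], ...)
      fits[[cond]] <- fit
      cell_files$meristematic[sel] <- classify_meristematic(fit, threshold)
    }
  }

  per_root_tbl <- dplyr::bind_rows(lapply(
    split(cell_files, cell_files$root_id), function(fl) {
      fl <- fl[order(fl$cell_index), , drop = FALSE]
      first_elong_idx <- match(FALSE, fl$meristematic)
      run_from_qc <- if (is.na(first_elong_idx)) nrow(fl) else first_elong_idx - 1L
      tibble(
        root_id = fl$root_id[1],
        condition = fl$condition[1],
        n_cells = nrow(fl),
        meristem_cell_count_gmm = sum(fl$meristematic),
        meristem_run_from_qc = run_from_qc,
        isodiametric_count = count_isodiametric(fl$length_um, fl$width_um),
        transition_count = count_transition(fl$length_um, fl$width_um,
                                            transition_factor),
        first_elongated_length = suppressWarnings(
          first_elongated_length(fl$length_um, fl$meristematic)
        )
      )
    }))

  per_condition <- dplyr::summarise(
    dplyr::group_by(per_root_tbl, .data$condition),
    dplyr::across(c("meristem_cell_count_gmm", "meristem_run_from_qc",
                    "isodiametric_count", "transition_count",
                    "first_elongated_length"), ~ mean(.x, na.rm = TRUE)),
    n_roots = dplyr::n(),
    .groups = "drop"
  )
  per_condition$mature_cell_length <- vapply(
    per_condition$condition,
    function(cond) mature_cell_length(
      cell_files$length_um[cell_files$condition == cond], k_mature
    ),
    numeric(1)
  )
  list(fits = fits, per_root = per_root_tbl, per_condition = per_condition,
       labels = cell_files)
}
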