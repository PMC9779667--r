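#' Classify a response quotient
#'
#' Responses are attenuated for RQ < 0.8, normal in the 0.8-1.2 range
#' (boundaries inclusive), and exaggerated for RQ > 1.2.
#'
#' @param rq Response quotient(s), > 0. Vectorized.
#' @param lower,upper Class boundaries.
#' @return Character vector: `"attenuated"`, `"normal"` or `"exaggerated"`.
#' @export
#' @examples
#' classify_rq(c(0.57, 0.8, 1.21))
classify_rq <- function(rq, lower = 0.8, upper = 1.2) {
  if (!is.numeric(rq) || anyNA(rq) || any(rq <= 0)) {
    stop_input("`rq` must be strictly positive")
  }
  if (lower > upper) stop_input("`lower` must not exceed `upper`")
  ifelse(rq < lower, "attenuated", ifelse(rq > upper, "exaggerated", "normal"))
}

#' Classify a response p-value
#'
#' Responses are insignificant for p >= 0.05, of attenuated significance for
#' 0.00001 <= p < 0.05, and significant for p < 0.00001. Wild types
#' invariably fall in the significant class (p below 1e-10 in practice), so
#' the upper two classes mark weakened responses.
#'
#' @param p Probability value(s) in \[0, 1\]. Vectorized.
#' @param alpha Insignificance boundary (default 0.05).
#' @param alpha_strong Strong-significance boundary (default 1e-5).
#' @return Character vector: `"significant"`, `"attenuated_significance"` or
#'   `"insignificant"`.
#' @export
#' @examples
#' classify_p(c(0.19, 0.003, 1e-11))
classify_p <- function(p, alpha = 0.05, alpha_strong = 1e-5) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_input("`p` must be in [0, 1]")
  }
  ifelse(p >= alpha, "insignificant",
         ifelse(p >= alpha_strong, "attenuated_significance", "significant"))
}

#' Volcano-plot coordinates for a genotype
#'
#' x = mean RQ of the chosen readout, y = -log10(median p) of that readout.
#' Zero p-values are clipped to `p_floor` with a warning.
#'
#' @param summary One-row genotype summary from [aggregate_genotype()], or a
#'   list with `mean_rq_<readout>` and `median_p_<readout>`.
#' @param readout `"ratio"` (default), `"hypocotyl"` or `"root"`.
#' @param p_floor Smallest representable p-value.
#' @return Named list `x`, `y`.
#' @export
#' @examples
#' volcano_coords(list(mean_rq_ratio = 0.39, median_p_ratio = 0.19))
volcano_coords <- function(summary, readout = "ratio", p_floor = 1e-300) {
  rq <- summary[[paste0("mean_rq_", readout)]]
  p <- summary[[paste0("median_p_", readout)]]
  if (is.null(rq) || is.null(p)) {
    stop_input("summary lacks the '%s' readout", readout)
  }
  if (p <= 0) {
    warning(sprintf("median p = 0 clipped to floor %g", p_floor))
    p <- p_floor
  }
  list(x = as.numeric(rq), y = -log10(p))
}

#' Call a "confused" decision phenotype
#'
#' A genotype is confused when its ratio response quotient is attenuated
#' (mean RQ_ratio below `rq_threshold`) while its ratio response is not
#' strongly significant (median P_ratio at or above `p_threshold`): the
#' lower-left quadrant of the RQ-vs-P volcano plot. The P boundary is the
#' attenuated-significance threshold (1e-5), not 0.05: genotypes with median
#' ratio p-values of 0.003-0.02 still land in the confused quadrant.
#'
#' @param summary One-row genotype summary (or list) with `mean_rq_ratio`
#'   and `median_p_ratio`.
#' @param rq_threshold Attenuation boundary on the mean RQ_ratio.
#' @param p_threshold Significance boundary on the median P_ratio.
#' @return Logical.
#' @export
#' @examples
#' confused_call(list(mean_rq_ratio = 0.39, median_p_ratio = 0.19))  # TRUE
confused_call <- function(summary, rq_threshold = 0.8, p_threshold = 1e-5) {
  rq <- summary[["mean_rq_ratio"]]
  p <- summary[["median_p_ratio"]]
  if (is.null(rq) || is.null(p) || is.na(rq) || is.na(p)) {
    stop_input("summary lacks a complete ratio readout")
  }
  rq < rq_threshold && p >= p_threshold
}

#' Organ exceedance of the wild type under a condition
#'
#' Per organ, tests whether the mutant's mean length exceeds the paired
#' wild type's under the given condition with [compare_groups()] p < alpha.
#' Decision mutants typically keep a long hypocotyl under darkW, exceeding
#' the wild type.
#'
#' @param mutant_records,wildtype_records Seedling tables.
#' @param condition Condition to test under (default `"darkW"`).
#' @param alpha Significance gate.
#' @return Named logical vector `c(hypocotyl = , root = )`.
#' @export
organ_exceedance <- function(mutant_records, wildtype_records,
                             condition = "darkW", alpha = 0.05) {
  mut <- mutant_records[mutant_records$condition == condition, , drop = FALSE]
  wt <- wildtype_records[wildtype_records$condition == condition, , drop = FALSE]
  if (!nrow(mut) || !nrow(wt)) {
    stop_input("empty group for condition '%s'", condition)
  }
  test_one <- function(col) {
    exceeds <- mean(mut[[col]]) > mean(wt[[col]])
    if (!exceeds) return(FALSE)
    cg <- suppressWarnings(compare_groups(mut[[col]], wt[[col]]))
    cg$p_value < alpha
  }
  c(hypocotyl = test_one("hypocotyl_length_mm"),
    root = test_one("root_length_mm"))
}

#' Direction of an organ's response relative to the wild type
#'
#' An organ's response is `"inverse"` when it is significantly different
#' from 1 (dark vs darkW organ lengths differ at `alpha` for both
#' genotypes) but falls on the opposite side of 1 from the paired wild
#' type's response — e.g. a root that gets shorter under darkW while the
#' wild-type root elongates. Otherwise `"wild-type-like"`.
#'
#' @param mutant_records,wildtype_records Seedling tables covering both
#'   conditions.
#' @param organ `"hypocotyl"` or `"root"`.
#' @param conditions Length-2 character vector, reference first.
#' @param alpha Significance gate for both responses.
#' @return `"inverse"` or `"wild-type-like"`.
#' @export
organ_direction <- function(mutant_records, wildtype_records,
                            organ = c("hypocotyl", "root"),
                            conditions = c("dark", "darkW"), alpha = 0.05) {
  organ <- match.arg(organ)
  col <- paste0(organ, "_length_mm")
  split_cond <- function(rows) {
    list(dark = rows[rows$condition == conditions[1], col, drop = TRUE],
         darkW = rows[rows$condition == conditions[2], col, drop = TRUE])
  }
  m <- split_cond(mutant_records)
  w <- split_cond(wildtype_records)
  if (!length(m$dark) || !length(m$darkW) || !length(w$dark) || !length(w$darkW)) {
    stop_input("both genotypes must be present in both conditions")
  }
  resp_m <- organ_response(m$dark, m$darkW)
  resp_w <- organ_response(w$dark, w$darkW)
  p_m <- suppressWarnings(compare_groups(m$dark, m$darkW))$p_value
  p_w <- suppressWarnings(compare_groups(w$dark, w$darkW))$p_value
  inverse <- p_m < alpha && p_w < alpha &&
    sign(resp_m - 1) != 0 && sign(resp_w - 1) != 0 &&
    sign(resp_m - 1) != sign(resp_w - 1)
  if (inverse) "inverse" else "wild-type-like"
}

#' Assemble a decision-mutant call
#'
#' A genotype qualifies as a decision mutant when all three criteria hold:
#' (i) failure to adjust the hypocotyl/root ratio to darkW — attenuated
#' ratio RQ or any organ responding in the inverse direction; (ii) weak
#' significance — the ratio response's median p-value is insignificant or of
#' attenuated significance; (iii) one organ exceeds wild-type length under
#' darkW. The confused call (lower-left volcano quadrant) is recorded
#' alongside.
#'
#' @param summary One-row genotype summary from [aggregate_genotype()].
#' @param exceedance Named logical vector from [organ_exceedance()].
#' @param directions Named character vector, e.g.
#'   `c(hypocotyl = "wild-type-like", root = "inverse")`.
#' @param rq_bounds Length-2 numeric, the attenuated/exaggerated RQ bounds.
#' @param p_bounds Length-2 numeric, `c(alpha, alpha_strong)`.
#' @return One-row tibble: labels per readout, direction per organ,
#'   `criteria_met` (comma-joined subset of `ratio_failure`,
#'   `weak_significance`, `organ_exceedance`), `confused`,
#'   `decision_mutant`.
#' @export
decision_mutant_call <- function(summary, exceedance, directions,
                                 rq_bounds = c(0.8, 1.2),
                                 p_bounds = c(0.05, 1e-5)) {
  needed <- c("genotype_id", "mean_rq_ratio", "median_p_ratio")
  if (any(!needed %in% names(summary))) {
    stop_input("summary must carry %s", paste(needed, collapse = ", "))
  }
  if (!all(c("hypocotyl", "root") %in% names(exceedance)) ||
      !all(c("hypocotyl", "root") %in% names(directions))) {
    stop_input("exceedance and directions must be named for hypocotyl and root")
  }
  rq_label <- classify_rq(summary$mean_rq_ratio, rq_bounds[1], rq_bounds[2])
  p_label <- classify_p(summary$median_p_ratio, p_bounds[1], p_bounds[2])

  criteria <- character(0)
  if (rq_label == "attenuated" || any(directions == "inverse")) {
    criteria <- c(criteria, "ratio_failure")
  }
  if (p_label %in% c("insignificant", "attenuated_significance")) {
    criteria <- c(criteria, "weak_significance")
  }
  if (any(exceedance)) criteria <- c(criteria, "organ_exceedance")

  tibble(
    genotype_id = summary$genotype_id,
    rq_label_ratio = rq_label,
    p_label_ratio = p_label,
    direction_hypocotyl = unname(directions[["hypocotyl"]]),
    direction_root = unname(directions[["root"]]),
    exceeds_hypocotyl = unname(exceedance[["hypocotyl"]]),
    exceeds_root = unname(exceedance[["root"]]),
    criteria_met = paste(criteria, collapse = ","),
    n_criteria = length(criteria),
    confused = confused_call(summary, rq_bounds[1], p_bounds[2]),
    decision_mutant = length(criteria) == 3L
  )
}

#' Classify every genotype in a screen
#'
#' End-to-end readout: per-replicate summaries ([summarize_screen()]),
#' per-genotype aggregation ([aggregate_genotype()]), organ exceedance and
#' direction against the paired wild type, and the decision-mutant call,
#' plus volcano coordinates for the ratio readout.
#'
#' @param records Seedling table covering both conditions.
#' @param conditions Length-2 character vector, reference condition first.
#' @param min_n Minimum seedlings per group.
#' @return Tibble with one row per genotype joining the genotype summary
#'   and the [decision_mutant_call()] fields plus `volcano_x`, `volcano_y`.
#' @export
classify_screen <- function(records, conditions = c("dark", "darkW"), min_n = 3L) {
  reps <- summarize_screen(records, conditions, min_n)
  summaries <- aggregate_genotype(reps)
  calls <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, , drop = FALSE]
    gid <- s$genotype_id
    mut_rows <- records[records$genotype_id == gid, , drop = FALSE]
    wt_id <- unique(mut_rows$ecotype_ref)[1]
    wt_rows <- records[records$genotype_id == wt_id &
                         records$plate_id %in% mut_rows$plate_id, , drop = FALSE]
    exc <- organ_exceedance(mut_rows, wt_rows, condition = conditions[2])
    dirs <- c(
      hypocotyl = organ_direction(mut_rows, wt_rows, "hypocotyl", conditions),
      root = organ_direction(mut_rows, wt_rows, "root", conditions)
    )
    call <- decision_mutant_call(s, exc, dirs)
    vc <- volcano_coords(s, "ratio")
    call$volcano_x <- vc$x
    call$volcano_y <- vc$y
    call
  })
  dplyr::left_join(summaries, dplyr::bind_rows(calls), by = "genotype_id")
}

#' Volcano plot of genotype summaries
#'
#' Mean RQ on the x-axis against -log10 median p on the y-axis for the
#' chosen readout, with guide lines at the RQ class bounds and the two
#' p-value thresholds. Genotypes in the lower-left quadrant (attenuated RQ,
#' weak significance) show the confused decision phenotype.
#'
#' @param summaries Tibble from [aggregate_genotype()] or
#'   [classify_screen()].
#' @param readout `"ratio"` (default), `"hypocotyl"` or `"root"`.
#' @param rq_bounds,p_bounds Guide-line positions.
#' @return A ggplot object.
#' @export
volcano_plot <- function(summaries, readout = "ratio",
                         rq_bounds = c(0.8, 1.2), p_bounds = c(0.05, 1e-5)) {
  rq_col <- paste0("mean_rq_", readout)
  p_col <- paste0("median_p_", readout)
  assert_columns(summaries, c("genotype_id", rq_col, p_col), "summaries")
  df <- tibble(
    genotype_id = summaries$genotype_id,
    x = summaries[[rq_col]],
    y = -log10(pmax(summaries[[p_col]], 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_vline(xintercept = rq_bounds, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(p_bounds), linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("mean RQ (%s)", readout),
      y = sprintf("-log10 median P (%s)", readout)
    ) +
    ggplot2::theme_minimal()
}
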