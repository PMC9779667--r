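#' Organ response to water stress in the dark
#'
#' The response of an organ is the ratio of its mean length in the dark to
#' its mean length under water stress in the dark (darkW). Values above 1
#' mean the organ is shorter under darkW (the wild-type hypocotyl
#' behaviour); values below 1 mean it elongates under darkW (the wild-type
#' root behaviour).
#'
#' @param lengths_dark,lengths_darkW Numeric samples of per-seedling organ
#'   lengths (mm) in the two conditions.
#' @return Dimensionless response (ratio of group means).
#' @export
#' @examples
#' organ_response(c(9, 10, 11), c(4, 5, 6))  # 2: shorter under darkW
organ_response <- function(lengths_dark, lengths_darkW) {
  assert_sample(lengths_dark, "lengths_dark", min_n = 1L)
  assert_sample(lengths_darkW, "lengths_darkW", min_n = 1L)
  m <- mean(lengths_darkW)
  if (m == 0 || mean(lengths_dark) == 0) {
    stop_computation("organ response undefined: a group mean is zero")
  }
  mean(lengths_dark) / m
}

#' Hypocotyl/root ratio adjustment
#'
#' The ratio adjustment quantifies the trade-off shift between conditions:
#' the hypocotyl/root ratio (of group means) in the dark divided by the same
#' ratio under darkW. Algebraically identical to
#' `organ_response(hypocotyl) / organ_response(root)`.
#'
#' @param hyp_dark,root_dark,hyp_darkW,root_darkW Numeric samples of organ
#'   lengths (mm).
#' @return Dimensionless ratio adjustment.
#' @export
#' @examples
#' ratio_adjustment(10, 3, 5, 9)  # (10/3)/(5/9) = 6
ratio_adjustment <- function(hyp_dark, root_dark, hyp_darkW, root_darkW) {
  r_h <- organ_response(hyp_dark, hyp_darkW)
  r_r <- organ_response(root_dark, root_darkW)
  r_h / r_r
}

#' Normalize a response to the paired wild type
#'
#' Plate and PEG-lot variability make raw responses incomparable across
#' experiments, so every mutant response (organ response or ratio
#' adjustment) is divided by the response of the wild-type ecotype grown on
#' the same plate. The result is the response quotient (RQ): 1 means
#' wild-type-like.
#'
#' @param mutant_value,wildtype_value Dimensionless responses.
#' @return RQ = `mutant_value / wildtype_value`.
#' @export
#' @examples
#' rq_normalize(3, 6)  # 0.5
rq_normalize <- function(mutant_value, wildtype_value) {
  if (!is.numeric(mutant_value) || !is.numeric(wildtype_value)) {
    stop_input("RQ inputs must be numeric")
  }
  if (any(wildtype_value <= 0)) {
    stop_computation("wild-type response must be strictly positive")
  }
  mutant_value / wildtype_value
}

#' Compare two groups with the screen's test-selection cascade
#'
#' Normality of each group is screened with Shapiro-Wilk; if either group
#' rejects at `alpha_normality` the two-sided Mann-Whitney U test is used.
#' Otherwise equality of variances is screened with the Brown-Forsythe
#' (median-centred Levene) test at `alpha_variance`, choosing between the
#' two-tailed Student's (equal variances) and Welch's (unequal) t test.
#'
#' @param a,b Numeric samples (>= 3 values each).
#' @param alpha_normality,alpha_variance Gate significance levels.
#' @return List with `p_value` and `test_used` (one of `"student_t"`,
#'   `"welch_t"`, `"mann_whitney"`).
#' @export
#' @examples
#' compare_groups(rnorm(20), rnorm(20, 2))
compare_groups <- function(a, b, alpha_normality = 0.05, alpha_variance = 0.05) {
  assert_sample(a, "a", min_n = 3L)
  assert_sample(b, "b", min_n = 3L)
  assert_number(alpha_normality, "alpha_normality", lower = 0, upper = 1)
  assert_number(alpha_variance, "alpha_variance", lower = 0, upper = 1)

  const_a <- stats::sd(a) == 0
  const_b <- stats::sd(b) == 0
  if (const_a && const_b && a[1] == b[1]) {
    warning("both samples constant and identical; returning p = 1")
    return(list(p_value = 1, test_used = "degenerate"))
  }

  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(0)             # a constant group is non-normal
    if (length(x) > 5000L) x <- x[round(seq(1L, length(x), length.out = 5000L))]
    stats::shapiro.test(x)$p.value
  }
  non_normal <- shapiro_p(a) < alpha_normality || shapiro_p(b) < alpha_normality

  if (non_normal) {
    p <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))$p.value
    return(list(p_value = p, test_used = "mann_whitney"))
  }
  grp <- factor(rep(c("a", "b"), times = c(length(a), length(b))))
  lev_p <- car::leveneTest(c(a, b), grp, center = stats::median)[1, "Pr(>F)"]
  equal_var <- !is.na(lev_p) && lev_p >= alpha_variance
  p <- stats::t.test(a, b, var.equal = equal_var, alternative = "two.sided")$p.value
  list(p_value = p, test_used = if (equal_var) "student_t" else "welch_t")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a declared comparison
#' family (for example a series of wavelengths or condition pairs).
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop_input("`p_values` must be probabilities in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Summarize one mutant/wild-type pairing for one replicate
#'
#' Computes, for a single biological replicate, both genotypes' organ
#' responses and ratio adjustment, the mutant's response quotients against
#' its same-plate wild type, and per-genotype significance of each response
#' (dark vs darkW) via [compare_groups()]: `p_hypocotyl` and `p_root` on
#' per-seedling organ lengths, `p_ratio` on per-seedling hypocotyl/root
#' ratios.
#'
#' @param records Seedling table (as from [generate_screen_dataset()] or
#'   [read_measurements()]) restricted to one replicate, containing
#'   `genotype_id` and its wild-type ecotype in both conditions.
#' @param genotype_id Mutant (or wild-type) genotype to summarize.
#' @param conditions Length-2 character vector, reference condition first
#'   (default `c("dark", "darkW")`).
#' @param min_n Minimum seedlings per genotype x condition group.
#' @return Tibble with two rows (`role` = `"mutant"`, `"wildtype"`; a single
#'   self-referenced wild type yields one row) carrying responses, RQs,
#'   p-values and the test used per comparison.
#' @export
summarize_replicate <- function(records, genotype_id,
                                conditions = c("dark", "darkW"),
                                min_n = 3L) {
  assert_columns(records, c("genotype_id", "ecotype_ref", "plate_id",
                            "replicate_id", "condition",
                            "hypocotyl_length_mm", "root_length_mm"),
                 "seedling table")
  if (length(conditions) != 2L) stop_input("`conditions` must name two conditions")
  if (length(unique(records$replicate_id)) != 1L) {
    stop_input("`records` must contain exactly one replicate")
  }
  mut_rows <- records[records$genotype_id == genotype_id, , drop = FALSE]
  if (!nrow(mut_rows)) stop_input("genotype '%s' absent from records", genotype_id)
  wt_id <- unique(mut_rows$ecotype_ref)
  if (length(wt_id) != 1L) stop_input("genotype '%s' has ambiguous ecotype_ref", genotype_id)

  # restrict the wild type to the plates the mutant was grown on: RQ
  # normalization is same-plate by construction
  wt_rows <- records[records$genotype_id == wt_id &
                       records$plate_id %in% mut_rows$plate_id, , drop = FALSE]
  missing_cells <- character(0)
  pull_group <- function(rows, gid, cond) {
    g <- rows[rows$condition == cond, , drop = FALSE]
    if (nrow(g) < min_n) {
      missing_cells <<- c(missing_cells, sprintf("%s/%s (n=%d)", gid, cond, nrow(g)))
    }
    g
  }
  mut_dark <- pull_group(mut_rows, genotype_id, conditions[1])
  mut_darkW <- pull_group(mut_rows, genotype_id, conditions[2])
  wt_dark <- pull_group(wt_rows, wt_id, conditions[1])
  wt_darkW <- pull_group(wt_rows, wt_id, conditions[2])
  if (length(missing_cells)) {
    stop_input("insufficient or missing mutant/wild-type pairing for cells: %s",
               paste(unique(missing_cells), collapse = "; "))
  }

  summarize_one <- function(dark, darkW, gid) {
    resp_h <- organ_response(dark$hypocotyl_length_mm, darkW$hypocotyl_length_mm)
    resp_r <- organ_response(dark$root_length_mm, darkW$root_length_mm)
    radj <- resp_h / resp_r
    ph <- compare_groups(dark$hypocotyl_length_mm, darkW$hypocotyl_length_mm)
    pr <- compare_groups(dark$root_length_mm, darkW$root_length_mm)
    pq <- compare_groups(dark$hypocotyl_length_mm / dark$root_length_mm,
                         darkW$hypocotyl_length_mm / darkW$root_length_mm)
    tibble(
      genotype_id = gid,
      response_hypocotyl = resp_h, response_root = resp_r,
      ratio_adjustment = radj,
      p_hypocotyl = ph$p_value, p_root = pr$p_value, p_ratio = pq$p_value,
      test_hypocotyl = ph$test_used, test_root = pr$test_used,
      test_ratio = pq$test_used,
      n_dark = nrow(dark), n_darkW = nrow(darkW)
    )
  }

  mut <- summarize_one(mut_dark, mut_darkW, genotype_id)
  wt <- summarize_one(wt_dark, wt_darkW, wt_id)
  mut$rq_hypocotyl <- rq_normalize(mut$response_hypocotyl, wt$response_hypocotyl)
  mut$rq_root <- rq_normalize(mut$response_root, wt$response_root)
  mut$rq_ratio <- rq_normalize(mut$ratio_adjustment, wt$ratio_adjustment)
  wt$rq_hypocotyl <- rq_normalize(wt$response_hypocotyl, wt$response_hypocotyl)
  wt$rq_root <- rq_normalize(wt$response_root, wt$response_root)
  wt$rq_ratio <- rq_normalize(wt$ratio_adjustment, wt$ratio_adjustment)

  res <- dplyr::bind_rows(
    dplyr::mutate(mut, role = "mutant"),
    dplyr::mutate(wt, role = "wildtype")
  )
  if (genotype_id == wt_id) res <- res[1L, , drop = FALSE]
  res$replicate_id <- unique(records$replicate_id)
  dplyr::relocate(res, "genotype_id", "replicate_id", "role")
}

#' Summarize every genotype and replicate in a screen table
#'
#' Applies [summarize_replicate()] across all genotype x replicate cells and
#' keeps each genotype's own row (wild types are summarized against
#' themselves, so their RQs are exactly 1).
#'
#' @inheritParams summarize_replicate
#' @param records Full seedling table.
#' @return Long tibble of per-replicate summaries.
#' @export
summarize_screen <- function(records, conditions = c("dark", "darkW"), min_n = 3L) {
  assert_columns(records, c("genotype_id", "replicate_id"), "seedling table")
  combos <- dplyr::distinct(records, .data$genotype_id, .data$replicate_id)
  dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    rows <- records[records$replicate_id == combos$replicate_id[i], , drop = FALSE]
    out <- summarize_replicate(rows, combos$genotype_id[i], conditions, min_n)
    out[out$genotype_id == combos$genotype_id[i], , drop = FALSE][1L, ]
  }))
}

#' Aggregate replicate summaries per genotype
#'
#' Mean RQs and median p-values across biological replicates; with an even
#' number of replicates the median is the mean of the two central values.
#' Genotypes with fewer than three replicates are flagged `"insufficient"`,
#' since stable calls need at least three.
#'
#' @param summaries Per-replicate tibble from [summarize_screen()] or
#'   [summarize_replicate()].
#' @return Tibble with one row per genotype: `mean_rq_*`, `median_p_*`,
#'   `n_replicates`, `replication`.
#' @export
aggregate_genotype <- function(summaries) {
  if (!nrow(summaries %||% data.frame())) stop_input("`summaries` must be non-empty")
  assert_columns(summaries, c("genotype_id", "rq_hypocotyl", "rq_root", "rq_ratio",
                              "p_hypocotyl", "p_root", "p_ratio"),
                 "replicate summaries")
  dplyr::summarise(
    dplyr::group_by(summaries, .data$genotype_id),
    mean_rq_hypocotyl = mean(.data$rq_hypocotyl),
    mean_rq_root = mean(.data$rq_root),
    mean_rq_ratio = mean(.data$rq_ratio),
    median_p_hypocotyl = stats::median(.data$p_hypocotyl),
    median_p_root = stats::median(.data$p_root),
    median_p_ratio = stats::median(.data$p_ratio),
    n_replicates = dplyr::n(),
    replication = ifelse(dplyr::n() >= 3L, "sufficient", "insufficient"),
    .groups = "drop"
  )
}

#' Hypocotyl volume
#'
#' Volume of the hypocotyl assuming a cylindrical organ, computed as
#' `V = pi * W * L` (the screen's working formula). The dimensionally
#' conventional cylinder volume `pi * (W/2)^2 * L` is available behind
#' `proper_cylinder = TRUE`.
#'
#' @param width,length Organ width and length (mm), > 0. Vectorized.
#' @param proper_cylinder Use `pi * (W/2)^2 * L` instead of the default
#'   `pi * W * L`.
#' @return Volume in mm^3.
#' @export
#' @examples
#' hypocotyl_volume(0.2, 10)  # 6.2832
hypocotyl_volume <- function(width, length, proper_cylinder = FALSE) {
  if (!is.numeric(width) || !is.numeric(length) ||
      any(width <= 0) || any(length <= 0)) {
    stop_input("`width` and `length` must be strictly positive")
  }
  if (proper_cylinder) pi * (width / 2)^2 * length else pi * width * length
}

#' Cell anisotropy in 2D
#'
#' Length divided by width; 1 for isodiametric cells.
#'
#' @param length,width Cell dimensions (um), width > 0. Vectorized.
#' @return Dimensionless anisotropy.
#' @export
#' @examples
#' anisotropy(60, 20)  # 3
anisotropy <- function(length, width) {
  if (!is.numeric(length) || !is.numeric(width)) {
    stop_input("`length` and `width` must be numeric")
  }
  if (any(width == 0)) stop_computation("anisotropy undefined for zero width")
  length / width
}

#' Fold-change table with cellular contributions
#'
#' For each condition and variable (organ length/width, cell length/width),
#' computes the fold change (FC) of the group mean relative to the reference
#' condition, and for each cell/organ pair the contribution
#' `100 * FC_cell / FC_organ` — the share of the organ-level fold change
#' accounted for by the cellular parameter. Contributions can exceed 100%
#' when the cellular change overshoots the organ change.
#'
#' @param records Table with columns `condition` and (any subset of)
#'   `organ_length`, `organ_width`, `cell_length`, `cell_width`; rows may
#'   carry `NA` for unmeasured variables.
#' @param reference_condition Condition the FCs are relative to.
#' @return Tibble: `condition`, `variable`, `fc`, `contribution_pct`
#'   (non-`NA` only for cell variables with a matched organ variable).
#' @export
contribution_table <- function(records, reference_condition = "light") {
  assert_columns(records, "condition", "measurement table")
  vars <- intersect(c("organ_length", "organ_width", "cell_length", "cell_width"),
                    names(records))
  if (!length(vars)) {
    stop_input("no measurement columns found (expected organ_/cell_ length/width)")
  }
  if (!reference_condition %in% records$condition) {
    stop_input("reference condition '%s' absent from records", reference_condition)
  }
  means <- dplyr::summarise(
    dplyr::group_by(records, .data$condition),
    dplyr::across(dplyr::all_of(vars), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  ref <- means[means$condition == reference_condition, , drop = FALSE]
  long <- tidyr::pivot_longer(means, dplyr::all_of(vars),
                              names_to = "variable", values_to = "mean_value")
  ref_long <- tidyr::pivot_longer(ref, dplyr::all_of(vars),
                                  names_to = "variable", values_to = "ref_value")
  out <- dplyr::left_join(long, ref_long[, c("variable", "ref_value")], by = "variable")
  out$fc <- out$mean_value / out$ref_value
  # contribution: cell FC as a percentage of the matched organ FC
  out$contribution_pct <- NA_real_
  for (dim_ in c("length", "width")) {
    cellv <- paste0("cell_", dim_)
    organv <- paste0("organ_", dim_)
    if (cellv %in% vars && organv %in% vars) {
      for (cond in unique(out$condition)) {
        fc_cell <- out$fc[out$condition == cond & out$variable == cellv]
        fc_organ <- out$fc[out$condition == cond & out$variable == organv]
        out$contribution_pct[out$condition == cond & out$variable == cellv] <-
          100 * fc_cell / fc_organ
      }
    }
  }
  dplyr::select(out, "condition", "variable", "fc", "contribution_pct")
}
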