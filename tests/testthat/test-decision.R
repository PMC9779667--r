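test_that("classify_rq partitions its domain with inclusive normal boundaries", {
  expect_equal(classify_rq(0.57), "attenuated")
  expect_equal(classify_rq(0.8), "normal")     # boundary inclusive
  expect_equal(classify_rq(1.2), "normal")     # boundary inclusive
  expect_equal(classify_rq(1.21), "exaggerated")
  expect_equal(classify_rq(0.7999999), "attenuated")
  # partition: every value gets exactly one label
  grid <- seq(0.01, 3, by = 0.01)
  labels <- classify_rq(grid)
  expect_true(all(labels %in% c("attenuated", "normal", "exaggerated")))
  expect_error(classify_rq(0), class = "ds_input_error")
})

test_that("classify_p partitions probabilities at 0.05 and 1e-5", {
  expect_equal(classify_p(0.19), "insignificant")
  expect_equal(classify_p(0.05), "insignificant")          # >= 0.05
  expect_equal(classify_p(0.003), "attenuated_significance")
  expect_equal(classify_p(1e-5), "attenuated_significance") # >= 1e-5
  expect_equal(classify_p(1e-11), "significant")
  expect_error(classify_p(1.5), class = "ds_input_error")
})

test_that("volcano coordinates are (mean RQ, -log10 median P) with a floor", {
  expect_equal(volcano_coords(list(mean_rq_ratio = 1.0, median_p_ratio = 0.01)),
               list(x = 1.0, y = 2.0))
  vc <- volcano_coords(list(mean_rq_ratio = 0.39, median_p_ratio = 0.19))
  expect_equal(vc$x, 0.39)
  expect_equal(vc$y, 0.721, tolerance = 1e-3)
  expect_warning(
    vc0 <- volcano_coords(list(mean_rq_ratio = 1, median_p_ratio = 0)),
    "floor"
  )
  expect_equal(vc0$y, 300)
})

test_that("confused_call reproduces the lower-left-quadrant memberships", {
  # the three published archetypes: strongly attenuated + insignificant,
  # attenuated + weakly significant, and wild-type-like + strongly significant
  expect_true(confused_call(list(mean_rq_ratio = 0.39, median_p_ratio = 0.19)))
  expect_true(confused_call(list(mean_rq_ratio = 0.46, median_p_ratio = 0.003)))
  expect_false(confused_call(list(mean_rq_ratio = 0.89, median_p_ratio = 1e-12)))
  # attenuated RQ label is implied by a confused call
  for (rq in c(0.1, 0.5, 0.79)) {
    if (confused_call(list(mean_rq_ratio = rq, median_p_ratio = 0.5))) {
      expect_equal(classify_rq(rq), "attenuated")
    }
  }
  expect_false(confused_call(list(mean_rq_ratio = 0.5, median_p_ratio = 1e-9)))
})

test_that("organ_exceedance requires both a larger mean and significance", {
  withr::with_seed(31, {
    mut <- tibble::tibble(condition = "darkW",
                          hypocotyl_length_mm = rnorm(30, 6, 0.5),
                          root_length_mm = rnorm(30, 3, 0.5))
    wt <- tibble::tibble(condition = "darkW",
                         hypocotyl_length_mm = rnorm(30, 4, 0.5),
                         root_length_mm = rnorm(30, 3, 0.5))
  })
  exc <- organ_exceedance(mut, wt)
  expect_true(exc[["hypocotyl"]])
  expect_false(exc[["root"]])
  # identical groups exceed nothing
  exc_id <- suppressWarnings(organ_exceedance(wt, wt))
  expect_false(any(exc_id))
  # larger mean without significance does not qualify
  withr::with_seed(32, {
    mut2 <- tibble::tibble(condition = "darkW",
                           hypocotyl_length_mm = rnorm(5, 4.2, 2),
                           root_length_mm = rnorm(5, 3, 2))
  })
  exc2 <- organ_exceedance(mut2, wt)
  expect_false(exc2[["hypocotyl"]])
  expect_error(organ_exceedance(mut[0, ], wt), class = "ds_input_error")
})

test_that("decision_mutant_call needs all three criteria", {
  base_summary <- tibble::tibble(genotype_id = "g", mean_rq_ratio = 0.4,
                                 median_p_ratio = 0.2)
  exc <- c(hypocotyl = TRUE, root = FALSE)
  dirs <- c(hypocotyl = "wild-type-like", root = "inverse")
  call <- decision_mutant_call(base_summary, exc, dirs)
  expect_true(call$decision_mutant)
  expect_equal(call$n_criteria, 3L)
  expect_true(call$confused)

  # wild-type-like summary: no criteria fire
  wt_summary <- tibble::tibble(genotype_id = "wt", mean_rq_ratio = 1.0,
                               median_p_ratio = 1e-20)
  call_wt <- decision_mutant_call(
    wt_summary, c(hypocotyl = FALSE, root = FALSE),
    c(hypocotyl = "wild-type-like", root = "wild-type-like")
  )
  expect_false(call_wt$decision_mutant)
  expect_equal(call_wt$criteria_met, "")
  expect_false(call_wt$confused)

  # strong significance blocks the weak-significance criterion
  sig_summary <- tibble::tibble(genotype_id = "g", mean_rq_ratio = 0.4,
                                median_p_ratio = 1e-9)
  call_sig <- decision_mutant_call(sig_summary, exc, dirs)
  expect_false(call_sig$decision_mutant)
  expect_equal(call_sig$n_criteria, 2L)
})

test_that("a bin2-like synthetic genotype is a decision mutant on 3 counts", {
  # inverse root response, weakly significant erratic ratio response, and a
  # hypocotyl that exceeds the wild type under darkW
  d <- screen_pair("inverse", n_per_group = 40, seed = 33, mutant_id = "bin2like")
  calls <- classify_screen(d)
  mut <- calls[calls$genotype_id == "bin2like", ]
  expect_true(mut$decision_mutant)
  expect_equal(mut$n_criteria, 3L)
  expect_equal(mut$direction_root, "inverse")
  expect_true(mut$exceeds_hypocotyl)
  expect_true(mut$p_label_ratio %in% c("insignificant", "attenuated_significance"))
  wt <- calls[calls$genotype_id == "wt", ]
  expect_false(wt$decision_mutant)
  expect_false(wt$confused)
})

test_that("a perception-null genotype with normal darkW adjustment is not called", {
  d <- screen_pair("perception_null", n_per_group = 40, seed = 34)
  calls <- classify_screen(d)
  mut <- calls[calls$genotype_id == "mut", ]
  expect_false(mut$decision_mutant)
  expect_false(mut$confused)
  expect_equal(mut$rq_label_ratio, "normal")
})

test_that("volcano_plot returns a ggplot with the guide lines", {
  d <- screen_pair("confused", n_per_group = 10, seed = 35)
  calls <- classify_screen(d)
  p <- volcano_plot(calls)
  expect_s3_class(p, "ggplot")
})
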