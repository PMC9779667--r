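test_that("EM recovers a well-separated two-population mixture", {
  withr::with_seed(41, {
    x <- sample(c(rnorm(200, 8, 1.5), rnorm(100, 60, 15)))
  })
  fit <- fit_two_gaussian_em(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_short - 8) / 8, 0.10)
  expect_lt(abs(fit$mu_long - 60) / 60, 0.10)
  expect_lt(abs(fit$weight_short - 2 / 3), 0.1)
  expect_true(all(fit$posterior_short >= 0 & fit$posterior_short <= 1))
  expect_lte(fit$mu_short, fit$mu_long)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(42, {
    x <- c(rnorm(150, 10, 2), rnorm(150, 80, 20))
  })
  fit <- fit_two_gaussian_em(x)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mus <- unname(sort(ref$parameters$mean))
  expect_equal(fit$mu_short, mus[1], tolerance = 0.02)
  expect_equal(fit$mu_long, mus[2], tolerance = 0.02)
})

test_that("EM log-likelihood trace is monotone non-decreasing on every fit", {
  withr::with_seed(43, {
    for (i in 1:10) {
      x <- c(rnorm(60, runif(1, 5, 12), runif(1, 0.5, 3)),
             rnorm(40, runif(1, 30, 90), runif(1, 5, 25)))
      fit <- suppressWarnings(fit_two_gaussian_em(x))
      expect_true(all(diff(fit$log_likelihood_trace) >= -1e-6))
    }
  })
})

test_that("a single tight cluster is flagged degenerate with means in range", {
  withr::with_seed(44, {
    x <- rnorm(50, 8, 1e-4)
  })
  expect_warning(fit <- fit_two_gaussian_em(x), "degenerate")
  expect_gte(fit$mu_short, min(x) - 1e-3)
  expect_lte(fit$mu_long, max(x) + 1e-3)
  expect_error(fit_two_gaussian_em(rep(5, 20)), class = "ds_input_error")
  expect_error(fit_two_gaussian_em(c(1, 2, 3)), class = "ds_input_error")
})

test_that("meristematic labels use a strict posterior cutoff", {
  fit <- structure(list(posterior_short = c(0, 0.5, 0.80, 0.81, 1)),
                   class = "gmm_fit")
  expect_equal(classify_meristematic(fit),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))  # 0.80 is NOT meristematic
  expect_equal(sum(classify_meristematic(
    structure(list(posterior_short = rep(0, 5)), class = "gmm_fit"))), 0)
  expect_error(classify_meristematic(fit, threshold = 1), class = "ds_input_error")
})

test_that("isodiametric and transition counts follow the worked examples", {
  expect_equal(count_isodiametric(c(5, 6, 7, 5), c(6, 6, 6, 6)), 2L)
  expect_equal(count_isodiametric(c(9, 5), c(6, 6)), 0L)
  expect_equal(count_isodiametric(c(5, 5, 5), c(6, 6, 6)), 3L)
  expect_equal(count_isodiametric(c(5, 9, 5, 9), c(6, 6, 6, 6), contiguous = FALSE), 2L)

  expect_equal(count_transition(c(5, 5, 7, 9, 14, 30), rep(6, 6)), 2L)
  expect_equal(count_transition(c(5, 5, 5), c(6, 6, 6)), 0L)
  # monotone 10% growth after onset runs to the file end
  lens <- c(5, 5, 7 * 1.1^(0:5))
  expect_equal(count_transition(lens, rep(6, length(lens))), 6L)
})

test_that("zonation scans agree with brute-force oracles on random files", {
  withr::with_seed(45, {
    for (i in 1:300) {
      f <- random_cell_file(sample(1:15, 1))
      expect_identical(count_isodiametric(f$lengths, f$widths),
                       iso_brute_force(f$lengths, f$widths))
      expect_identical(count_transition(f$lengths, f$widths),
                       transition_brute_force(f$lengths, f$widths))
      total <- count_isodiametric(f$lengths, f$widths) +
        count_transition(f$lengths, f$widths)
      expect_lte(total, length(f$lengths))
    }
  })
})

test_that("mature_cell_length averages the k most elongated cells", {
  expect_equal(mature_cell_length(1:20, 10), 15.5)
  expect_equal(mature_cell_length(c(4, 8, 2), 3), mean(c(4, 8, 2)))  # k = n
  expect_equal(mature_cell_length(c(4, 8, 2), 1), 8)                 # k = 1
  expect_error(mature_cell_length(1:5, 10), class = "ds_input_error")
})

test_that("first_elongated_length finds the lowest-index elongating cell", {
  expect_equal(first_elongated_length(c(8, 9, 22, 40), c(TRUE, TRUE, FALSE, FALSE)), 22)
  expect_equal(first_elongated_length(c(30, 35), c(FALSE, FALSE)), 30)
  expect_warning(res <- first_elongated_length(c(8, 9), c(TRUE, TRUE)),
                 "meristematic")
  expect_true(is.na(res))
})

test_that("mitotic_summary computes means, fold-changes and corrected tests", {
  ct <- tibble::tibble(condition = rep(c("dark", "darkW"), each = 3),
                       count = c(1, 1, 2, 8, 10, 6))
  ms <- mitotic_summary(ct, pairs = list(c("darkW", "dark")))
  expect_equal(ms$fold_changes$fold_change, 6.0)
  expect_equal(ms$means$mean_count[ms$means$condition == "darkW"], 8)
  # identical condition maps give fold-change 1
  ct2 <- tibble::tibble(condition = rep(c("a", "b"), each = 4), count = rep(2:5, 2))
  ms2 <- mitotic_summary(ct2, pairs = list(c("a", "b")))
  expect_equal(ms2$fold_changes$fold_change, 1.0)
  expect_error(mitotic_summary(ct, pairs = list(c("light", "dark"))),
               class = "ds_input_error")
  # BH correction spans the requested pairs
  ms3 <- mitotic_summary(ct, pairs = list(c("darkW", "dark"), c("dark", "darkW")))
  expect_equal(ms3$fold_changes$p_adjusted, bh_brute_force(ms3$fold_changes$p_value))
})

test_that("zonation_summary recovers the configured meristem size on generator output", {
  files <- generate_cell_files(default_cell_file_specs()[c("dark", "darkW")],
                               n_roots = 8, seed = 46)
  z <- zonation_summary(files)
  per_cond <- z$per_condition
  dark <- per_cond[per_cond$condition == "dark", ]
  darkW <- per_cond[per_cond$condition == "darkW", ]
  expect_lt(abs(dark$meristem_cell_count_gmm - 25) / 25, 0.20)
  expect_lt(abs(darkW$meristem_cell_count_gmm - 18) / 18, 0.20)
  # labels cover every cell and counts are consistent
  expect_false(anyNA(z$labels$meristematic))
  expect_equal(nrow(z$per_root), 16L)
  expect_true(all(z$per_root$meristem_run_from_qc <= z$per_root$n_cells))
})
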