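test_that("screen generator honours the size contract and determinism", {
  gts <- list(genotype_spec("wt", "wt"), genotype_spec("mut", "wt", "attenuated"))
  d <- generate_screen_dataset(gts, n_per_group = 20, n_replicates = 3, seed = 11)
  # 2 genotypes x 2 conditions x 20 seedlings x 3 replicates
  expect_equal(nrow(d), 240L)
  expect_true(all(d$hypocotyl_length_mm > 0))
  expect_true(all(d$root_length_mm > 0))
  expect_setequal(unique(d$condition), c("dark", "darkW"))

  d2 <- generate_screen_dataset(gts, n_per_group = 20, n_replicates = 3, seed = 11)
  expect_identical(d, d2)
  d3 <- generate_screen_dataset(gts, n_per_group = 20, n_replicates = 3, seed = 12)
  expect_false(identical(d, d3))
})

test_that("every mutant cohort has a same-plate, same-replicate wild-type cohort", {
  gts <- list(
    genotype_spec("Col0", "Col0"), genotype_spec("Ws2", "Ws2"),
    genotype_spec("m1", "Col0", "attenuated"),
    genotype_spec("m2", "Ws2", "confused"),
    genotype_spec("m3", "Col0", "exaggerated")
  )
  d <- generate_screen_dataset(gts, n_per_group = 5, n_replicates = 2, seed = 3)
  muts <- d[d$genotype_id != d$ecotype_ref, , drop = FALSE]
  cells <- unique(muts[, c("genotype_id", "ecotype_ref", "plate_id", "replicate_id")])
  for (i in seq_len(nrow(cells))) {
    wt_here <- d$genotype_id == cells$ecotype_ref[i] &
      d$plate_id == cells$plate_id[i] &
      d$replicate_id == cells$replicate_id[i]
    expect_gte(sum(wt_here), 5L)
  }
})

test_that("generator rejects broken configurations", {
  expect_error(
    generate_screen_dataset(list(genotype_spec("m", "ghost", "attenuated")), seed = 1),
    class = "ds_config_error"
  )
  gts <- list(genotype_spec("wt", "wt"), genotype_spec("m", "wt", "attenuated"))
  expect_error(generate_screen_dataset(gts, n_per_group = 1, seed = 1),
               class = "ds_input_error")
  expect_error(generate_screen_dataset(gts, n_per_group = 5),
               class = "ds_input_error")  # seed mandatory
  expect_error(genotype_spec("m", "wt", "nonsense"), class = "ds_config_error")
})

test_that("a self-paired wild type normalizes to RQ exactly 1", {
  d <- generate_screen_dataset(list(genotype_spec("wt", "wt")),
                               n_per_group = 10, seed = 4)
  reps <- summarize_screen(d)
  expect_equal(reps$rq_hypocotyl, rep(1, 3))
  expect_equal(reps$rq_root, rep(1, 3))
  expect_equal(reps$rq_ratio, rep(1, 3))
})

test_that("configured multipliers are recovered as RQs (parameter recovery)", {
  # mean RQs over simulated screens must sit within 5% of the configured
  # response multipliers
  n_sims <- 30
  rq_hyp <- rq_root <- rq_ratio <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    gts <- list(genotype_spec("wt", "wt"),
                genotype_spec("m", "wt", "normal",
                              hypocotyl_multiplier = 0.6, root_multiplier = 1.5))
    d <- generate_screen_dataset(gts, n_per_group = 40, seed = 1000 + s)
    agg <- aggregate_genotype(summarize_screen(d))
    m <- agg[agg$genotype_id == "m", ]
    rq_hyp[s] <- m$mean_rq_hypocotyl
    rq_root[s] <- m$mean_rq_root
    rq_ratio[s] <- m$mean_rq_ratio
  }
  expect_lt(abs(mean(rq_hyp) - 0.6) / 0.6, 0.05)
  expect_lt(abs(mean(rq_root) - 1.5) / 1.5, 0.05)
  expect_lt(abs(mean(rq_ratio) - 0.4) / 0.4, 0.05)
})

test_that("inverse-class roots respond in the opposite direction to the wild type", {
  d <- screen_pair("inverse", n_per_group = 40, seed = 21)
  wt_rows <- d[d$genotype_id == "wt", ]
  mut_rows <- d[d$genotype_id == "mut", ]
  resp_wt <- organ_response(wt_rows$root_length_mm[wt_rows$condition == "dark"],
                            wt_rows$root_length_mm[wt_rows$condition == "darkW"])
  resp_mut <- organ_response(mut_rows$root_length_mm[mut_rows$condition == "dark"],
                             mut_rows$root_length_mm[mut_rows$condition == "darkW"])
  expect_lt(resp_wt, 1)   # wild-type roots elongate under darkW
  expect_gt(resp_mut, 1)  # inverse mutant roots shorten under darkW
})

test_that("cell files are zoned as specified", {
  spec <- cell_file_spec(30, meristem_length_mean = 8, meristem_length_sd = 1.5,
                         elongation_rate = 1.4)
  files <- generate_cell_files(list(dark = spec), n_roots = 6, seed = 5)
  expect_true(all(files$length_um > 0))
  first30 <- files$length_um[files$cell_index <= 30]
  # mean of meristem cells close to the configured mean (2 sd of the mean)
  expect_lt(abs(mean(first30) - 8), 2 * 1.5 / sqrt(length(first30)))
  # first cells isodiametric on average: widths >= lengths near the QC
  near_qc <- files$cell_index <= 10
  expect_gt(mean(files$width_um[near_qc] - files$length_um[near_qc]), 0)

  expect_identical(files, generate_cell_files(list(dark = spec), n_roots = 6, seed = 5))
  expect_error(generate_cell_files(list(), 3, seed = 1), class = "ds_input_error")
})

test_that("elongation-zone lengths follow geometric growth before mature clipping", {
  # tiny dispersion makes the closed form visible: cell at onset + j has
  # length ~ meristem_mean * rate^j
  spec <- cell_file_spec(30, meristem_length_mean = 8, meristem_length_sd = 0.01,
                         elongation_rate = 1.5,
                         mature_length_mean = 400, mature_length_sd = 1)
  files <- generate_cell_files(list(dark = spec), n_roots = 4, seed = 6)
  at <- files$length_um[files$cell_index == 34]  # onset + 4
  expect_true(all(abs(at - 8 * 1.5^4) / (8 * 1.5^4) < 0.02))
})

test_that("mitotic counts are Poisson-like, non-negative and deterministic", {
  z <- generate_mitotic_counts(c(dark = 0), n_roots = 20, seed = 1)
  expect_true(all(z$count == 0))

  ct <- generate_mitotic_counts(c(dark = 8), n_roots = 500, seed = 2)
  expect_true(all(ct$count >= 0))
  expect_true(all(ct$count == round(ct$count)))
  expect_gt(mean(ct$count), 7.0)
  expect_lt(mean(ct$count), 9.0)

  expect_identical(ct, generate_mitotic_counts(c(dark = 8), n_roots = 500, seed = 2))
  expect_error(generate_mitotic_counts(c(dark = -1), 5, seed = 1),
               class = "ds_input_error")
})
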