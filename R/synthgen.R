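#' Describe a growth condition
#'
#' A condition specifies the organ-length distributions the generator draws
#' from for wild-type seedlings. The screen contrasts darkness (`dark`) with
#' darkness plus PEG-imposed water deficit (`darkW`, water potential in MPa);
#' `light` and `lightW` are available for light-response contrasts.
#'
#' @param name Condition label, one of `"light"`, `"dark"`, `"darkW"`,
#'   `"lightW"`.
#' @param hypocotyl_mean,hypocotyl_sd Hypocotyl length distribution (mm).
#' @param root_mean,root_sd Root length distribution (mm).
#' @param hypocotyl_width_mean,hypocotyl_width_sd Hypocotyl width
#'   distribution (mm).
#' @param water_potential Medium water potential in MPa (<= 0; 0 = no PEG).
#' @param light_intensity Light intensity in umol m-2 s-1 (>= 0; 0 = dark).
#' @return A `condition_spec` object (named list).
#' @export
#' @examples
#' condition_spec("darkW", 5, 1, 9, 3, water_potential = -0.4)
condition_spec <- function(name,
                           hypocotyl_mean, hypocotyl_sd,
                           root_mean, root_sd,
                           hypocotyl_width_mean = 0.25,
                           hypocotyl_width_sd = 0.03,
                           water_potential = 0,
                           light_intensity = 0) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("light", "dark", "darkW", "lightW")) {
    stop_config("condition `name` must be one of light, dark, darkW, lightW")
  }
  assert_number(water_potential, "water_potential", upper = 0)
  assert_number(light_intensity, "light_intensity", lower = 0)
  for (nm in c("hypocotyl_mean", "hypocotyl_sd", "root_mean", "root_sd",
               "hypocotyl_width_mean", "hypocotyl_width_sd")) {
    assert_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  structure(
    list(name = name,
         water_potential = water_potential,
         light_intensity = light_intensity,
         hypocotyl_mean = hypocotyl_mean, hypocotyl_sd = hypocotyl_sd,
         root_mean = root_mean, root_sd = root_sd,
         hypocotyl_width_mean = hypocotyl_width_mean,
         hypocotyl_width_sd = hypocotyl_width_sd,
         # conditions whose name carries the water-stress suffix are the
         # stressed member of a response pair; genotype multipliers act there
         is_stress = grepl("W$", name)),
    class = "condition_spec"
  )
}

#' Default growth conditions
#'
#' Qualitative emulation of the screen's condition contrasts: in the dark the
#' hypocotyl is long and the root short (etiolation); adding water stress in
#' the dark (`darkW`) flips the trade-off (short hypocotyl, long root) and
#' inflates root variance roughly three-fold, mirroring the high wild-type
#' root variance observed under combined stress. Light conditions keep the
#' hypocotyl short. All values are generator defaults, overridable per call.
#'
#' @return Named list of [condition_spec()] objects
#'   (`light`, `dark`, `darkW`, `lightW`).
#' @export
default_conditions <- function() {
  list(
    light = condition_spec("light", 2.0, 0.4, 8.0, 1.5,
                           hypocotyl_width_mean = 0.30,
                           light_intensity = 80),
    dark = condition_spec("dark", 10.0, 1.5, 3.0, 0.8,
                          hypocotyl_width_mean = 0.25),
    darkW = condition_spec("darkW", 5.0, 1.0, 9.0, 3.0,
                           hypocotyl_width_mean = 0.20,
                           water_potential = -0.4),
    lightW = condition_spec("lightW", 1.2, 0.3, 9.0, 2.0,
                            hypocotyl_width_mean = 0.28,
                            water_potential = -0.4, light_intensity = 80)
  )
}

# Response-class presets. A multiplier m on an organ multiplies that organ's
# dark/darkW response relative to the wild type, so the configured value is
# the expected organ RQ. The "confused" preset cancels both organ adjustments
# (responses ~ 1, so the per-seedling ratio distributions overlap between
# conditions and P_ratio is large) and inflates noise; "inverse" drives the
# root response well above 1 (roots markedly shorter under darkW than dark)
# with erratic growth, while the hypocotyl fails to adjust and exceeds the
# wild type under darkW — the decision-mutant archetype.
response_class_presets <- function() {
  list(
    normal          = list(hypocotyl_multiplier = 1.0, root_multiplier = 1.0, noise_inflation = 1.0),
    attenuated      = list(hypocotyl_multiplier = 0.5, root_multiplier = 1.0, noise_inflation = 1.0),
    exaggerated     = list(hypocotyl_multiplier = 1.5, root_multiplier = 1.0, noise_inflation = 1.0),
    inverse         = list(hypocotyl_multiplier = 0.5, root_multiplier = 4.5, noise_inflation = 2.5),
    confused        = list(hypocotyl_multiplier = 0.5, root_multiplier = 3.0, noise_inflation = 2.0),
    perception_null = list(hypocotyl_multiplier = 1.0, root_multiplier = 1.0, noise_inflation = 1.0)
  )
}

#' Describe a genotype for the synthetic screen
#'
#' Each genotype carries a response class and organ-response multipliers.
#' A multiplier scales the genotype's dark/darkW response for that organ
#' relative to its wild type, so it equals the genotype's expected organ RQ.
#' Class presets: `normal` (1, 1), `attenuated` (hypocotyl 0.5),
#' `exaggerated` (hypocotyl 1.5), `inverse` (root response pushed well above
#' 1 — roots shorter under darkW than in the dark — with erratic growth),
#' `confused` (both organ
#' adjustments cancelled and noise doubled, so the ratio response is both
#' attenuated and non-significant), `perception_null` (wild-type-like water
#' stress adjustment; its defining light-response defect is outside the
#' dark/darkW contrast).
#'
#' @param genotype_id Genotype label.
#' @param ecotype_ref Label of the paired wild-type ecotype; a wild type
#'   references itself.
#' @param response_class One of `"normal"`, `"attenuated"`, `"exaggerated"`,
#'   `"inverse"`, `"confused"`, `"perception_null"`.
#' @param hypocotyl_multiplier,root_multiplier Optional overrides of the
#'   class preset (> 0).
#' @param noise_inflation Optional override; multiplies the genotype's
#'   within-group standard deviations (>= 1).
#' @return A `genotype_spec` object.
#' @export
#' @examples
#' genotype_spec("Ws2", "Ws2", "normal")
#' genotype_spec("bin2like", "Ws2", "confused")
genotype_spec <- function(genotype_id, ecotype_ref, response_class = "normal",
                          hypocotyl_multiplier = NULL, root_multiplier = NULL,
                          noise_inflation = NULL) {
  presets <- response_class_presets()
  if (!response_class %in% names(presets)) {
    stop_config("unknown response_class '%s'", response_class)
  }
  p <- presets[[response_class]]
  hm <- hypocotyl_multiplier %||% p$hypocotyl_multiplier
  rm_ <- root_multiplier %||% p$root_multiplier
  ni <- noise_inflation %||% p$noise_inflation
  assert_number(hm, "hypocotyl_multiplier", lower = 0, strict_lower = TRUE)
  assert_number(rm_, "root_multiplier", lower = 0, strict_lower = TRUE)
  assert_number(ni, "noise_inflation", lower = 1)
  structure(
    list(genotype_id = genotype_id, ecotype_ref = ecotype_ref,
         response_class = response_class,
         hypocotyl_multiplier = hm, root_multiplier = rm_,
         noise_inflation = ni),
    class = "genotype_spec"
  )
}

#' Generate a synthetic screen dataset
#'
#' Draws per-seedling organ measurements for each genotype under each
#' condition, with multiplicative log-normal plate effects. Each mutant
#' cohort is grown together with a cohort of its paired wild-type ecotype on
#' the same plate within each replicate, which is what makes the downstream
#' same-plate RQ normalization well defined. Wild types not referenced by
#' any mutant get a standalone cohort.
#'
#' @param genotypes List of [genotype_spec()] objects. Every `ecotype_ref`
#'   must resolve to a listed genotype with `response_class = "normal"`.
#' @param conditions List of [condition_spec()] objects (default: the
#'   `dark`/`darkW` contrast of [default_conditions()]).
#' @param n_per_group Seedlings per genotype x condition x replicate (>= 2).
#' @param n_replicates Biological replicates.
#' @param n_plates Plates per replicate x condition; mutant/wild-type
#'   pairings are assigned to plates round-robin. Default: one plate per
#'   pairing.
#' @param plate_sd Standard deviation (log scale) of the per-plate
#'   multiplicative effect on each organ.
#' @param seed Integer seed; identical seed and configuration give a
#'   byte-identical table.
#' @return Tibble with one row per seedling: `genotype_id`, `ecotype_ref`,
#'   `plate_id`, `replicate_id`, `condition`, `hypocotyl_length_mm`,
#'   `root_length_mm`, `hypocotyl_width_mm`.
#' @export
#' @examples
#' gts <- list(genotype_spec("wt", "wt"), genotype_spec("mut", "wt", "attenuated"))
#' d <- generate_screen_dataset(gts, n_per_group = 5, n_replicates = 2, seed = 1)
#' nrow(d)  # 2 genotypes x 2 conditions x 5 seedlings x 2 replicates
generate_screen_dataset <- function(genotypes,
                                    conditions = default_conditions()[c("dark", "darkW")],
                                    n_per_group = 20,
                                    n_replicates = 3,
                                    n_plates = NULL,
                                    plate_sd = 0.1,
                                    seed) {
  if (missing(seed)) stop_input("`seed` is required")
  seed <- assert_count(seed, "seed", lower = 0L)
  n_per_group <- assert_count(n_per_group, "n_per_group", lower = 2L)
  n_replicates <- assert_count(n_replicates, "n_replicates", lower = 1L)
  assert_number(plate_sd, "plate_sd", lower = 0)
  if (!length(genotypes)) stop_config("`genotypes` must be non-empty")
  ids <- vapply(genotypes, function(g) g$genotype_id, character(1))
  if (anyDuplicated(ids)) stop_config("duplicated genotype_id in `genotypes`")
  names(genotypes) <- ids
  for (g in genotypes) {
    ref <- genotypes[[g$ecotype_ref]]
    if (is.null(ref)) {
      stop_config("ecotype_ref '%s' of genotype '%s' does not resolve to a listed genotype",
                  g$ecotype_ref, g$genotype_id)
    }
    if (ref$response_class != "normal") {
      stop_config("ecotype_ref '%s' must have response_class 'normal'", g$ecotype_ref)
    }
  }
  cond_names <- vapply(conditions, function(cc) cc$name, character(1))
  if (anyDuplicated(cond_names)) stop_config("condition names must be unique")
  names(conditions) <- cond_names

  mutants <- ids[vapply(genotypes, function(g) g$genotype_id != g$ecotype_ref, logical(1))]
  referenced <- unique(vapply(genotypes[mutants], function(g) g$ecotype_ref, character(1)))
  standalone_wt <- setdiff(ids[!ids %in% mutants], referenced)
  # a pairing = the cohort(s) grown together on one plate
  pairings <- c(lapply(mutants, function(m) c(genotypes[[m]]$ecotype_ref, m)),
                lapply(standalone_wt, function(w) w))
  if (!length(pairings)) stop_config("no genotypes to simulate")
  n_plates <- if (is.null(n_plates)) length(pairings) else assert_count(n_plates, "n_plates")

  draw_cohort <- function(g, cond) {
    hm <- cond$hypocotyl_mean
    rm_ <- cond$root_mean
    if (cond$is_stress) {
      hm <- hm / g$hypocotyl_multiplier
      rm_ <- rm_ / g$root_multiplier
    }
    ni <- g$noise_inflation
    # mutant dispersion scales with the shifted mean (constant coefficient of
    # variation), so a response multiplier moves the location without
    # truncation distorting it
    hyp_sd <- cond$hypocotyl_sd * (hm / cond$hypocotyl_mean) * ni
    root_sd <- cond$root_sd * (rm_ / cond$root_mean) * ni
    tibble(
      hypocotyl_length_mm = rpositive(n_per_group, hm, hyp_sd),
      root_length_mm = rpositive(n_per_group, rm_, root_sd),
      hypocotyl_width_mm = rpositive(n_per_group, cond$hypocotyl_width_mean,
                                     cond$hypocotyl_width_sd * ni)
    )
  }

  withr::with_seed(seed, {
    out <- vector("list", n_replicates * length(pairings) * length(conditions) * 2L)
    k <- 0L
    for (r in seq_len(n_replicates)) {
      rep_id <- sprintf("rep%d", r)
      for (i in seq_along(pairings)) {
        plate <- ((i - 1L) %% n_plates) + 1L
        for (cond in conditions) {
          plate_id <- sprintf("%s_p%d_%s", rep_id, plate, cond$name)
          scale_hyp <- stats::rlnorm(1, 0, plate_sd)
          scale_root <- stats::rlnorm(1, 0, plate_sd)
          for (gid in pairings[[i]]) {
            g <- genotypes[[gid]]
            cohort <- draw_cohort(g, cond)
            cohort$hypocotyl_length_mm <- cohort$hypocotyl_length_mm * scale_hyp
            cohort$root_length_mm <- cohort$root_length_mm * scale_root
            k <- k + 1L
            out[[k]] <- tibble(
              genotype_id = gid,
              ecotype_ref = g$ecotype_ref,
              plate_id = plate_id,
              replicate_id = rep_id,
              condition = cond$name,
              cohort
            )
          }
        }
      }
    }
    dplyr::bind_rows(out[seq_len(k)])
  })
}

#' Describe a synthetic epidermal cell file
#'
#' A cell file is an ordered sequence of cells starting at the quiescent
#' centre (QC): a zone of short, near-isodiametric meristematic cells,
#' followed by an elongation zone in which cell length grows geometrically
#' per cell position until it saturates at the mature cell length.
#'
#' @param meristem_cell_count Number of meristematic cells from the QC.
#' @param meristem_length_mean,meristem_length_sd Meristematic cell length
#'   distribution (um).
#' @param width_mean,width_sd Cell width distribution, all zones (um).
#' @param elongation_onset_index Index of the last meristem-like cell;
#'   defaults to `meristem_cell_count`.
#' @param elongation_rate Per-cell geometric growth factor (> 1) beyond the
#'   onset.
#' @param mature_length_mean,mature_length_sd Mature cell length
#'   distribution (um).
#' @return A `cell_file_spec` object.
#' @export
cell_file_spec <- function(meristem_cell_count,
                           meristem_length_mean = 8, meristem_length_sd = 1.5,
                           width_mean = 12, width_sd = 1.5,
                           elongation_onset_index = meristem_cell_count,
                           elongation_rate = 1.4,
                           mature_length_mean = 180, mature_length_sd = 25) {
  meristem_cell_count <- assert_count(meristem_cell_count, "meristem_cell_count")
  elongation_onset_index <- assert_count(elongation_onset_index, "elongation_onset_index")
  for (nm in c("meristem_length_mean", "meristem_length_sd", "width_mean",
               "width_sd", "mature_length_mean", "mature_length_sd")) {
    assert_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  assert_number(elongation_rate, "elongation_rate", lower = 1, strict_lower = TRUE)
  structure(
    list(meristem_cell_count = meristem_cell_count,
         meristem_length_mean = meristem_length_mean,
         meristem_length_sd = meristem_length_sd,
         width_mean = width_mean, width_sd = width_sd,
         elongation_onset_index = elongation_onset_index,
         elongation_rate = elongation_rate,
         mature_length_mean = mature_length_mean,
         mature_length_sd = mature_length_sd),
    class = "cell_file_spec"
  )
}

#' Default cell-file specifications per condition
#'
#' Encodes the qualitative zonation contrasts the root analysis detects:
#' darkW has the smallest meristem, a steeper elongation ramp (hence a longer
#' first elongated cell) than dark, while mature cell length peaks in the
#' dark. Widths exceed meristematic lengths, so the zone nearest the QC is
#' isodiametric on average.
#'
#' @return Named list of [cell_file_spec()] objects (`light`, `dark`,
#'   `darkW`).
#' @export
default_cell_file_specs <- function() {
  list(
    light = cell_file_spec(30, elongation_rate = 1.30,
                           mature_length_mean = 140, mature_length_sd = 20),
    dark = cell_file_spec(25, elongation_rate = 1.35,
                          mature_length_mean = 220, mature_length_sd = 30),
    darkW = cell_file_spec(18, width_mean = 11, elongation_rate = 2.0,
                           mature_length_mean = 180, mature_length_sd = 25)
  )
}

#' Generate synthetic epidermal cell files
#'
#' For each root, draws `elongation_onset_index` meristematic cells, then
#' grows cell length geometrically (`elongation_rate` per cell, with
#' multiplicative noise at the meristem's coefficient of variation) until it
#' reaches that root's mature length, and appends `n_mature` mature cells.
#'
#' @param spec_by_condition Named list mapping condition to
#'   [cell_file_spec()].
#' @param n_roots Roots per condition (>= 1).
#' @param seed Integer seed.
#' @param genotype_id Genotype label stamped on the output.
#' @param n_mature Number of fully mature cells appended per file.
#' @return Long-format tibble: `root_id`, `condition`, `genotype_id`,
#'   `cell_index` (1-based from the QC), `length_um`, `width_um`.
#' @export
#' @examples
#' files <- generate_cell_files(default_cell_file_specs()["dark"], n_roots = 2, seed = 1)
generate_cell_files <- function(spec_by_condition, n_roots, seed,
                                genotype_id = "WT", n_mature = 10L) {
  if (!length(spec_by_condition)) stop_input("`spec_by_condition` must be non-empty")
  if (is.null(names(spec_by_condition)) || any(!nzchar(names(spec_by_condition)))) {
    stop_input("`spec_by_condition` must be a named list (condition -> spec)")
  }
  n_roots <- assert_count(n_roots, "n_roots")
  n_mature <- assert_count(n_mature, "n_mature", lower = 0L)
  if (missing(seed)) stop_input("`seed` is required")
  seed <- assert_count(seed, "seed", lower = 0L)

  one_file <- function(spec) {
    onset <- spec$elongation_onset_index
    lengths <- rpositive(onset, spec$meristem_length_mean, spec$meristem_length_sd)
    # positional growth in the elongation zone is more regular than meristem
    # cell size: half the meristem's coefficient of variation
    cv <- spec$meristem_length_sd / spec$meristem_length_mean / 2
    mature <- rpositive(1, spec$mature_length_mean, spec$mature_length_sd)
    j <- 1L
    repeat {
      base <- spec$meristem_length_mean * spec$elongation_rate^j
      if (base >= mature || j > 500L) break
      lengths <- c(lengths, min(base, mature) * exp(stats::rnorm(1, 0, cv)))
      j <- j + 1L
    }
    lengths <- c(lengths, rpositive(n_mature, spec$mature_length_mean, spec$mature_length_sd))
    widths <- rpositive(length(lengths), spec$width_mean, spec$width_sd)
    tibble(cell_index = seq_along(lengths), length_um = lengths, width_um = widths)
  }

  withr::with_seed(seed, {
    out <- list()
    for (cond in names(spec_by_condition)) {
      spec <- spec_by_condition[[cond]]
      if (!inherits(spec, "cell_file_spec")) {
        stop_input("spec for condition '%s' is not a cell_file_spec", cond)
      }
      for (i in seq_len(n_roots)) {
        cells <- one_file(spec)
        out[[length(out) + 1L]] <- tibble(
          root_id = sprintf("%s_%s_root%02d", genotype_id, cond, i),
          condition = cond,
          genotype_id = genotype_id,
          cells
        )
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Generate synthetic mitotic-marker counts
#'
#' Emulates counts of M-phase marker positive cells per root tip as Poisson
#' draws with condition-specific means.
#'
#' @param mean_by_condition Named numeric vector (condition -> expected
#'   count, >= 0).
#' @param n_roots Roots per condition.
#' @param seed Integer seed.
#' @return Tibble: `root_id`, `condition`, `count`.
#' @export
#' @examples
#' generate_mitotic_counts(c(dark = 1, darkW = 8), n_roots = 3, seed = 1)
generate_mitotic_counts <- function(mean_by_condition, n_roots, seed) {
  if (!length(mean_by_condition) || is.null(names(mean_by_condition)) ||
      any(!nzchar(names(mean_by_condition)))) {
    stop_input("`mean_by_condition` must be a non-empty named numeric vector")
  }
  if (!is.numeric(mean_by_condition) || any(mean_by_condition < 0)) {
    stop_input("mitotic means must be non-negative")
  }
  n_roots <- assert_count(n_roots, "n_roots")
  if (missing(seed)) stop_input("`seed` is required")
  seed <- assert_count(seed, "seed", lower = 0L)
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(names(mean_by_condition), function(cond) {
      tibble(
        root_id = sprintf("%s_root%03d", cond, seq_len(n_roots)),
        condition = cond,
        count = stats::rpois(n_roots, mean_by_condition[[cond]])
      )
    }))
  })
}

#' Default mitotic-index means per condition
#'
#' Mean M-phase marker counts per root tip: lower in the dark than in the
#' light, and eight-fold higher under darkW than dark — the direction and
#' magnitude the root-growth analysis is designed to detect.
#'
#' @return Named numeric vector.
#' @export
default_mitotic_means <- function() {
  c(light = 4, dark = 1, darkW = 8)
}
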