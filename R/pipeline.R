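#' Build a pipeline configuration
#'
#' Collects every tunable of the simulate-then-analyse pipeline in one
#' validated list. Inputs are either file paths (`organ_csv`,
#' `cellfile_csv`, `mitotic_csv`) or, when a path is `NULL`, the
#' corresponding synthetic generator with the supplied parameters.
#'
#' @param seed Integer seed, mandatory: every stochastic stage derives from
#'   it.
#' @param organ_csv,cellfile_csv,mitotic_csv Optional input CSV paths; when
#'   `NULL` the stage simulates its input.
#' @param genotypes List of [genotype_spec()] objects (or lists coercible to
#'   them) for simulation.
#' @param conditions Character vector of condition names (resolved against
#'   [default_conditions()]) or a list of [condition_spec()] objects.
#' @param n_per_group,n_replicates,n_plates Screen-generator sizes.
#' @param cellfile_specs Named list of [cell_file_spec()] per condition.
#' @param n_roots Roots per condition for cell files and mitotic counts.
#' @param mitotic_means Named vector of expected marker counts.
#' @param rq_bounds,p_bounds Classification thresholds
#'   (attenuated/exaggerated RQ bounds; insignificance and
#'   strong-significance p bounds).
#' @param posterior_threshold Meristematic posterior cutoff in (0, 1).
#' @param transition_factor Transition-zone stop ratio (> 1).
#' @param k_mature Longest cells averaged for mature cell length.
#' @param span,degree,ci,n_boot Positional-curve smoothing parameters.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            organ_csv = NULL, cellfile_csv = NULL,
                            mitotic_csv = NULL,
                            genotypes = list(
                              genotype_spec("Col0", "Col0", "normal"),
                              genotype_spec("mut_attenuated", "Col0", "attenuated"),
                              genotype_spec("mut_confused", "Col0", "confused")
                            ),
                            conditions = c("dark", "darkW"),
                            n_per_group = 20L, n_replicates = 3L,
                            n_plates = NULL,
                            cellfile_specs = default_cell_file_specs(),
                            n_roots = 8L,
                            mitotic_means = default_mitotic_means(),
                            rq_bounds = c(0.8, 1.2),
                            p_bounds = c(0.05, 1e-5),
                            posterior_threshold = 0.8,
                            transition_factor = 1.5,
                            k_mature = 10L,
                            span = 0.75, degree = 2L, ci = 0.95,
                            n_boot = 200L) {
  cfg <- list(
    seed = seed, organ_csv = organ_csv, cellfile_csv = cellfile_csv,
    mitotic_csv = mitotic_csv, genotypes = genotypes, conditions = conditions,
    n_per_group = n_per_group, n_replicates = n_replicates, n_plates = n_plates,
    cellfile_specs = cellfile_specs, n_roots = n_roots,
    mitotic_means = mitotic_means, rq_bounds = rq_bounds, p_bounds = p_bounds,
    posterior_threshold = posterior_threshold,
    transition_factor = transition_factor, k_mature = k_mature,
    span = span, degree = degree, ci = ci, n_boot = n_boot
  )
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks thresholds, sizes and input paths before any computation runs, so
#' misconfiguration fails fast. Also accepts plain lists (e.g. parsed from
#' YAML) and fills unset fields with the [pipeline_config()] defaults.
#'
#' @param config A `pipeline_config` or plain named list.
#' @return The validated `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop_config("config must be a list")
  if (is.null(config$seed)) stop_config("config must set `seed`")
  config$seed <- assert_count(config$seed, "seed", lower = 0L)

  defaults <- formals(pipeline_config)
  for (nm in setdiff(names(defaults), c("seed", "..."))) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- eval(defaults[[nm]], envir = asNamespace("decisionscreen"))
    }
  }
  if (length(config$rq_bounds) != 2L || config$rq_bounds[1] > config$rq_bounds[2]) {
    stop_config("rq_bounds must be c(lower, upper) with lower <= upper")
  }
  if (length(config$p_bounds) != 2L || config$p_bounds[2] > config$p_bounds[1]) {
    stop_config("p_bounds must be c(alpha, alpha_strong) with alpha_strong <= alpha")
  }
  if (any(config$p_bounds < 0) || any(config$p_bounds > 1)) {
    stop_config("p_bounds must lie in [0, 1]")
  }
  if (config$posterior_threshold <= 0 || config$posterior_threshold >= 1) {
    stop_config("posterior_threshold must lie strictly within (0, 1)")
  }
  if (config$transition_factor <= 1) stop_config("transition_factor must be > 1")
  assert_number(config$span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  config$n_per_group <- assert_count(config$n_per_group, "n_per_group", lower = 2L)
  config$n_replicates <- assert_count(config$n_replicates, "n_replicates")
  config$n_roots <- assert_count(config$n_roots, "n_roots")
  config$k_mature <- assert_count(config$k_mature, "k_mature")
  config$n_boot <- assert_count(config$n_boot, "n_boot", lower = 0L)
  for (pth in c(config$organ_csv, config$cellfile_csv, config$mitotic_csv)) {
    if (!is.null(pth) && !file.exists(pth)) stop_config("input file not found: %s", pth)
  }
  # genotype/condition entries given as plain lists (e.g. from YAML)
  config$genotypes <- lapply(config$genotypes, function(g) {
    if (inherits(g, "genotype_spec")) g else do.call(genotype_spec, g)
  })
  if (is.character(config$conditions)) {
    known <- default_conditions()
    missing <- setdiff(config$conditions, names(known))
    if (length(missing)) stop_config("unknown condition(s): %s",
                                     paste(missing, collapse = ", "))
    config$conditions <- known[config$conditions]
  }
  config$cellfile_specs <- lapply(config$cellfile_specs, function(s) {
    if (inherits(s, "cell_file_spec")) s else do.call(cell_file_spec, s)
  })
  config$mitotic_means <- unlist(config$mitotic_means)
  class(config) <- "pipeline_config"
  config
}

#' Run the full decision-phenotyping pipeline
#'
#' Simulates (or reads) the screen table, cell files and mitotic counts,
#' then runs every analysis stage and writes the result bundle to
#' `output_dir`: `replicate_summaries.csv`, `genotype_calls.csv`,
#' `zonation.csv` (per root), `curves.csv` (per condition x cell index),
#' `mitotic_summary.csv`, a plain-text `report.txt`, and `manifest.json`
#' recording the seed, configuration hash and package version. Identical
#' configuration and seed give byte-identical outputs; on failure, files
#' already written for this run are removed.
#'
#' @param config A [pipeline_config()] (or list, or path to a YAML file with
#'   the same fields).
#' @param output_dir Output directory, created if missing.
#' @return (Invisibly) a list with all stage results.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_pipeline_config(config)
  if (missing(output_dir)) stop_input("`output_dir` is required")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    log_stage("wrote %s (%d rows)", name, nrow(df))
  }

  tryCatch({
    cond_names <- vapply(config$conditions, function(cc) cc$name, character(1))

    # --- organ stage ------------------------------------------------------
    organ <- if (!is.null(config$organ_csv)) {
      read_measurements(config$organ_csv, "organ")
    } else {
      generate_screen_dataset(config$genotypes, config$conditions,
                              config$n_per_group, config$n_replicates,
                              config$n_plates, seed = config$seed)
    }
    log_stage("organ table: %d seedlings, %d genotypes", nrow(organ),
              length(unique(organ$genotype_id)))
    reps <- summarize_screen(organ, conditions = cond_names[1:2])
    calls <- classify_screen(organ, conditions = cond_names[1:2])

    # --- meristem stage ---------------------------------------------------
    cells <- if (!is.null(config$cellfile_csv)) {
      read_measurements(config$cellfile_csv, "cellfile")
    } else {
      generate_cell_files(config$cellfile_specs, config$n_roots,
                          seed = config$seed + 1L)
    }
    zon <- zonation_summary(cells, threshold = config$posterior_threshold,
                            transition_factor = config$transition_factor,
                            k_mature = config$k_mature)
    curves <- dplyr::bind_rows(lapply(unique(cells$condition), function(cond) {
      pc <- positional_curve(cells[cells$condition == cond, , drop = FALSE],
                             "length", span = config$span,
                             degree = config$degree, ci = config$ci,
                             n_boot = config$n_boot, seed = config$seed + 2L)
      dplyr::mutate(as_tibble(pc), condition = cond, .before = 1L)
    }))

    counts <- if (!is.null(config$mitotic_csv)) {
      read_measurements(config$mitotic_csv, "mitotic")
    } else {
      generate_mitotic_counts(config$mitotic_means, config$n_roots,
                              seed = config$seed + 3L)
    }
    mit <- mitotic_summary(counts)
    mit_tbl <- dplyr::left_join(
      mit$fold_changes,
      dplyr::rename(mit$means, numerator = "condition"),
      by = "numerator"
    )

    emit(reps, "replicate_summaries.csv")
    emit(calls, "genotype_calls.csv")
    emit(zon$per_root, "zonation.csv")
    emit(curves, "curves.csv")
    emit(mit_tbl, "mitotic_summary.csv")

    report <- c(
      "decision-phenotyping pipeline report",
      sprintf("seed: %d", config$seed),
      sprintf("seedlings: %d; genotypes: %d; replicates: %d",
              nrow(organ), length(unique(organ$genotype_id)),
              length(unique(organ$replicate_id))),
      sprintf("decision mutants: %s",
              paste(calls$genotype_id[calls$decision_mutant], collapse = ", ")),
      sprintf("confused genotypes: %s",
              paste(calls$genotype_id[calls$confused], collapse = ", ")),
      sprintf("cell files: %d roots, %d cells",
              length(unique(cells$root_id)), nrow(cells)),
      paste(utils::capture.output(print(as.data.frame(zon$per_condition))),
            collapse = "\n")
    )
    report_path <- file.path(output_dir, "report.txt")
    writeLines(report, report_path)
    written <- c(written, report_path)

    manifest <- list(
      package = "decisionscreen",
      version = as.character(utils::packageVersion("decisionscreen")),
      seed = config$seed,
      config = config_for_manifest(config),
      config_hash = rlang::hash(config_for_manifest(config)),
      outputs = basename(written)
    )
    manifest_path <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, manifest_path)

    invisible(list(organ = organ, replicate_summaries = reps,
                   genotype_calls = calls, cell_files = cells, zonation = zon,
                   curves = curves, mitotic = mit, manifest = manifest,
                   output_files = written))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

# config serialized for the manifest: spec objects flattened to plain lists
config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$genotypes <- lapply(cfg$genotypes, unclass)
  cfg$conditions <- lapply(cfg$conditions, unclass)
  cfg$cellfile_specs <- lapply(cfg$cellfile_specs, unclass)
  cfg$mitotic_means <- as.list(cfg$mitotic_means)
  cfg
}

log_stage <- function(msg, ...) {
  if (isTRUE(getOption("decisionscreen.quiet", TRUE))) return(invisible())
  message(sprintf(paste0("[decisionscreen] ", msg), ...))
}
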