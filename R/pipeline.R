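#' Derive a stage seed from the global seed
#'
#' Deterministic, collision-poor mapping from the run's global seed and a
#' stage name to a stage-local seed (kept below 2^31).
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483647)
}

pipeline_stage_names <- c("simulate_traces", "analyze_traces", "pda",
                          "simulate_field", "density", "discriminate")

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order: trace simulation,
#' trace correction and population fitting, photon distribution analysis,
#' localization-field simulation, cluster-density analysis, and dimer-form
#' discrimination. Every stochastic stage draws from a seed derived
#' deterministically from the global seed and the stage name. A run
#' manifest records the package version, seeds, stage parameters and
#' per-stage summary outputs; when `out_dir` is set, stage outputs and the
#' manifest are written there as delimited text / JSON.
#'
#' @param config A named list or the path of a YAML file. Top-level keys:
#'   `seed` (integer), `out_dir` (optional), and `stages` -- a named list
#'   whose entries select and parameterize the stages
#'   (`simulate_traces`, `analyze_traces`, `pda`, `simulate_field`,
#'   `density`, `discriminate`). Unknown keys are rejected.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allowed <- c("seed", "out_dir", "stages")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% list()
  unknown <- setdiff(names(stages), pipeline_stage_names)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  manifest <- list(package = "fretarch",
                   version = as.character(utils::packageVersion("fretarch")),
                   seed = seed, stages = list())
  state <- list()

  if (!is.null(stages$simulate_traces)) {
    cfg <- stages$simulate_traces
    sp <- do.call(trace_sim_params,
                  c(cfg$params %||% list(),
                    list(seed = derive_seed(seed, "simulate_traces"))))
    state$traces <- simulate_trace_cohort(
      cfg$n_traces %||% 200L, sp,
      donor_only_fraction = cfg$donor_only_fraction %||% 0.15,
      acceptor_only_fraction = cfg$acceptor_only_fraction %||% 0.15)
    if (!is.null(out_dir)) write_trace_set(state$traces,
                                           file.path(out_dir, "traces"))
    manifest$stages$simulate_traces <- list(
      seed = derive_seed(seed, "simulate_traces"),
      n_traces = length(state$traces),
      true_distance_nm = sp$true_distance)
  }

  if (!is.null(stages$analyze_traces)) {
    cfg <- stages$analyze_traces
    traces <- state$traces %||%
      (if (!is.null(cfg$traces_dir)) read_trace_set(cfg$traces_dir) else
        stop("analyze_traces: no traces simulated and no traces_dir given"))
    state$analysis <- analyze_trace_set(
      traces, s_window = cfg$s_window %||% c(0.3, 0.7))
    pop <- state$analysis$population
    if (!is.null(out_dir)) {
      write.csv(state$analysis$es, file.path(out_dir, "es_points.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(mean_E = pop$mean_E, sigma_E = pop$sigma_E,
             n_traces = pop$n_traces,
             factors = unclass(state$analysis$factors)),
        file.path(out_dir, "population.json"), auto_unbox = TRUE, digits = NA)
    }
    manifest$stages$analyze_traces <- list(
      mean_E = pop$mean_E, sigma_E = pop$sigma_E, n_traces = pop$n_traces,
      factors = unclass(state$analysis$factors))
  }

  if (!is.null(stages$pda)) {
    cfg <- stages$pda
    if (is.null(state$analysis)) stop("pda requires analyze_traces")
    win <- pda_windows(state$analysis$selection)
    state$pda <- pda_fit(win, R0 = cfg$R0 %||% 6.34,
                         factors = state$analysis$factors)
    if (!is.null(out_dir)) {
      write.csv(cbind(state$pda$predicted, observed = state$pda$observed),
                file.path(out_dir, "pda_histogram.csv"), row.names = FALSE)
    }
    manifest$stages$pda <- list(distance_nm = state$pda$distance_nm,
                                width_nm = state$pda$width_nm,
                                chisq_red = state$pda$chisq_red)
  }

  if (!is.null(stages$simulate_field)) {
    cfg <- stages$simulate_field
    fp <- do.call(field_params,
                  c(cfg$params %||% list(),
                    list(seed = derive_seed(seed, "simulate_field"))))
    state$field <- simulate_localization_field(fp)
    state$field_params <- fp
    if (!is.null(out_dir)) {
      write.csv(state$field$localizations,
                file.path(out_dir, "localizations.csv"), row.names = FALSE)
    }
    manifest$stages$simulate_field <- list(
      seed = derive_seed(seed, "simulate_field"),
      n_localizations = nrow(state$field$localizations),
      n_clusters_true = nrow(state$field$truth))
  }

  if (!is.null(stages$density)) {
    cfg <- stages$density
    locs <- state$field$localizations %||%
      (if (!is.null(cfg$locs_file)) read_localizations(cfg$locs_file) else
        stop("density: no field simulated and no locs_file given"))
    area <- cfg$area_um2 %||% state$field_params$area_um2 %||%
      stop("density: area_um2 required")
    state$density <- smlm_density_pipeline(locs, area)
    manifest$stages$density <- list(
      density_per_um2 = state$density$density,
      n_clusters = state$density$n_clusters,
      nena_nm = state$density$nena_nm)
  }

  if (!is.null(stages$discriminate)) {
    cfg <- stages$discriminate
    measured <- if (!is.null(cfg$measured)) {
      do.call(measured_distance_set, cfg$measured)
    } else if (!is.null(state$analysis)) {
      pop <- state$analysis$population
      R0 <- cfg$R0 %||% 6.34
      measured_distance_set(
        pairs = cfg$pair_label %||% "T-T",
        R_nm = efficiency_to_distance(pop$mean_E, R0),
        sigma_nm = distance_uncertainty(pop$mean_E, pop$sigma_E, R0))
    } else stop("discriminate: needs measured distances or analyze_traces")
    preds <- lapply(cfg$predictions, function(p) {
      df <- as.data.frame(p[setdiff(names(p), "form")])
      attr(df, "form") <- p$form %||% "candidate"
      df
    })
    state$ranking <- select_form(measured, preds)
    if (!is.null(out_dir)) {
      jsonlite::write_json(state$ranking$table,
                           file.path(out_dir, "form_ranking.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest$stages$discriminate <- list(best = state$ranking$best,
                                         table = state$ranking$table)
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(manifest, list(state = state)))
}
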