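# Pipeline orchestration: ensemble -> RMSD filter -> pairwise-distance
# features -> regular-space cluster centers -> [external MD or the toy
# CV-space simulator] -> AMINO -> SPIB, driven by one YAML config with
# per-stage manifests and idempotent re-runs.

.pipeline_stages <- c("io", "filter", "features", "cluster", "dynamics",
                      "amino", "spib")

#' Read and validate a pipeline configuration
#'
#' The config is a YAML file (or an equivalent named list) with one block per
#' stage plus `output_dir` and `seed`. Every numeric parameter is validated
#' against its stage's preconditions before any stage runs, so a bad value
#' fails fast instead of after hours of computation.
#'
#' ```yaml
#' output_dir: runs/demo
#' seed: 1
#' io:       {structures: "structs/*.pdb", selection: "name CA"}
#' filter:   {cutoff: 10.0}                  # Angstrom; no silent default
#' features: {selection: "name CA", min_residue_separation: 3, top_m: ~}
#' cluster:  {d_min: ~, target_centers: [2, 20]}
#' dynamics: {mode: toy, n_steps: 20000, step_size: 0.05, temperature: 0.15,
#'            kappa: 2.0}
#' # or: dynamics: {mode: files, paths: [t1.dat, t2.dat], dt: 1.0}
#' amino:    {k_max: 20, n_bins: 50}
#' spib:     {lag_steps: 10, latent_dim: 2, beta: 0.01, n_initial_states: 8}
#' ```
#'
#' @param config path to a YAML file, or a named list with the same shape
#' @return validated config list of class `PipelineConfig`
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  need <- function(x, what) {
    if (is.null(x)) stop("pipeline config is missing ", what, call. = FALSE)
    x
  }
  need(config$output_dir, "'output_dir'")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  io <- need(config$io, "the 'io' block")
  need(io$structures, "io$structures")
  if (is.null(io$selection)) config$io$selection <- "all"

  flt <- need(config$filter, "the 'filter' block")
  cutoff <- need(flt$cutoff, "filter$cutoff (Angstrom; no silent default)")
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("filter$cutoff must be a positive number", call. = FALSE)
  }

  if (is.null(config$features)) config$features <- list()
  fe <- config$features
  if (is.null(fe$selection)) config$features$selection <- "name CA"
  if (is.null(fe$min_residue_separation)) config$features$min_residue_separation <- 3L
  if (config$features$min_residue_separation < 0) {
    stop("features$min_residue_separation must be >= 0", call. = FALSE)
  }

  if (is.null(config$cluster)) config$cluster <- list()
  cl <- config$cluster
  if (!is.null(cl$d_min) && (!is.numeric(cl$d_min) || cl$d_min < 0)) {
    stop("cluster$d_min must be >= 0", call. = FALSE)
  }
  if (is.null(cl$target_centers)) config$cluster$target_centers <- c(5L, 20L)

  dyn <- need(config$dynamics, "the 'dynamics' block")
  mode <- need(dyn$mode, "dynamics$mode ('toy' or 'files')")
  if (!mode %in% c("toy", "files")) {
    stop("dynamics$mode must be 'toy' or 'files'", call. = FALSE)
  }
  if (mode == "files") {
    need(dyn$paths, "dynamics$paths")
  } else {
    if (is.null(dyn$n_steps)) config$dynamics$n_steps <- 20000L
    if (is.null(dyn$step_size)) config$dynamics$step_size <- 0.05
    if (is.null(dyn$temperature)) config$dynamics$temperature <- 0.15
    if (is.null(dyn$kappa)) config$dynamics$kappa <- 2.0
    if (config$dynamics$n_steps < 2L || config$dynamics$step_size <= 0) {
      stop("dynamics$n_steps must be >= 2 and step_size > 0", call. = FALSE)
    }
  }

  if (is.null(config$amino)) config$amino <- list()
  if (is.null(config$amino$k_max)) config$amino$k_max <- 20L
  if (is.null(config$amino$n_bins)) config$amino$n_bins <- 50L
  if (config$amino$k_max < 1L || config$amino$n_bins < 2L) {
    stop("amino$k_max must be >= 1 and n_bins >= 2", call. = FALSE)
  }

  sp <- need(config$spib, "the 'spib' block")
  need(sp$lag_steps, "spib$lag_steps")
  spib_defaults <- list(latent_dim = 2L, beta = 0.01, n_initial_states = 10L,
                        max_epochs = 40L)
  for (nm in names(spib_defaults)) {
    if (is.null(sp[[nm]])) config$spib[[nm]] <- spib_defaults[[nm]]
  }
  # surface SPIB preconditions before any stage runs
  cfg_args <- config$spib
  cfg_args$seed <- config$seed
  do.call(spib_config, cfg_args)
  if (config$dynamics$mode == "toy" &&
      config$spib$lag_steps >= config$dynamics$n_steps) {
    stop("spib$lag_steps (", config$spib$lag_steps, ") must be smaller than ",
         "the toy-dynamics trajectory length (", config$dynamics$n_steps, ")",
         call. = FALSE)
  }
  class(config) <- c("PipelineConfig", "list")
  config
}

.hash_file <- function(path) unname(tools::md5sum(path))

.hash_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), tmp)
  .hash_file(tmp)
}

.manifest_path <- function(out_dir, stage) {
  file.path(out_dir, stage, "manifest.json")
}

.write_manifest <- function(out_dir, stage, params, inputs, outputs) {
  dir.create(file.path(out_dir, stage), showWarnings = FALSE, recursive = TRUE)
  man <- list(stage = stage,
              params_hash = .hash_obj(params),
              input_hashes = as.list(vapply(inputs, .hash_file, character(1))),
              outputs = as.list(outputs))
  jsonlite::write_json(man, .manifest_path(out_dir, stage),
                       auto_unbox = TRUE, pretty = TRUE)
  man
}

.stage_current <- function(out_dir, stage, params, inputs) {
  mp <- .manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp)
  if (!identical(man$params_hash, unname(.hash_obj(params)))) return(FALSE)
  old <- unlist(man$input_hashes)
  new <- vapply(inputs, .hash_file, character(1))
  if (length(old) != length(new) || !all(old == new)) return(FALSE)
  all(file.exists(unlist(man$outputs)))
}

#' Run the analysis pipeline
#'
#' Executes the stages `io`, `filter`, `features`, `cluster`, `dynamics`,
#' `amino`, `spib` in order from one validated config. Each stage writes its
#' artifacts plus a manifest (parameter hash, input-file hashes, output
#' paths) under `output_dir/<stage>/`; re-running with an unchanged config
#' skips stages whose manifests still match (idempotent resume). The
#' `dynamics` stage is the pipeline's external boundary: with
#' `mode: files` it ingests user-supplied MD time series of the watched CVs,
#' while `mode: toy` fills the slot with the harmonic CV-space simulator for
#' testing.
#'
#' @param config a `PipelineConfig`, YAML path, or named list
#' @param from_stage,to_stage optional stage-name bounds
#' @param quiet suppress progress messages
#' @return named list of per-stage manifests
#' @export
run_pipeline <- function(config, from_stage = NULL, to_stage = NULL,
                         quiet = FALSE) {
  config <- pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- .pipeline_stages
  from_i <- if (is.null(from_stage)) 1L else match(from_stage, stages)
  to_i <- if (is.null(to_stage)) length(stages) else match(to_stage, stages)
  if (is.na(from_i) || is.na(to_i)) {
    stop("unknown stage name; stages are: ", paste(stages, collapse = ", "),
         call. = FALSE)
  }
  say <- function(...) if (!quiet) message("[cvstates] ", ...)
  manifests <- list()
  state <- new.env(parent = emptyenv())

  load_upstream <- function(stage) {
    # lazily reload artifacts a later entry stage depends on
    p <- file.path(out_dir, stage, "artifact.rds")
    if (!file.exists(p)) {
      stop("missing artifact of upstream stage '", stage,
           "'; re-run from that stage", call. = FALSE)
    }
    readRDS(p)
  }
  save_artifact <- function(stage, obj) {
    p <- file.path(out_dir, stage, "artifact.rds")
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    saveRDS(obj, p)
    p
  }

  run_stage <- function(stage, params, inputs, fn) {
    if (.stage_current(out_dir, stage, params, inputs)) {
      say("stage ", stage, ": up to date, skipping")
      manifests[[stage]] <<- jsonlite::read_json(.manifest_path(out_dir, stage))
      return(invisible(NULL))
    }
    say("stage ", stage, ": running")
    outputs <- fn()
    manifests[[stage]] <<- .write_manifest(out_dir, stage, params, inputs, outputs)
    invisible(NULL)
  }

  # --- io ------------------------------------------------------------------
  if (from_i <= 1L && to_i >= 1L) {
    paths <- config$io$structures
    expanded <- unlist(lapply(paths, function(p) {
      if (grepl("[*?]", p)) sort(Sys.glob(p)) else p
    }))
    params <- config$io
    run_stage("io", params, expanded, function() {
      ens <- load_ensemble(expanded, selection = config$io$selection)
      state$ensemble <- ens
      save_artifact("io", ens)
    })
  }

  # --- filter --------------------------------------------------------------
  if (from_i <= 2L && to_i >= 2L) {
    inputs <- file.path(out_dir, "io", "artifact.rds")
    run_stage("filter", config$filter, inputs, function() {
      ens <- if (!is.null(state$ensemble)) state$ensemble else load_upstream("io")
      ref <- select_reference(ens)
      filt <- rmsd_filter(ens, cutoff = config$filter$cutoff,
                          reference_index = ref)
      rms <- data.frame(source_id = ens$source_ids,
                        rmsd = attr(filt, "rmsd"),
                        kept = seq_along(ens$source_ids) %in% attr(filt, "kept"))
      csv <- file.path(out_dir, "filter", "rmsd.csv")
      dir.create(dirname(csv), showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(rms, csv, row.names = FALSE)
      state$filtered <- filt
      c(save_artifact("filter", filt), csv)
    })
  }

  # --- features ------------------------------------------------------------
  if (from_i <= 3L && to_i >= 3L) {
    inputs <- file.path(out_dir, "filter", "artifact.rds")
    run_stage("features", config$features, inputs, function() {
      ens <- if (!is.null(state$filtered)) state$filtered else load_upstream("filter")
      specs <- enumerate_pair_features(
        ens, selection = config$features$selection,
        min_residue_separation = config$features$min_residue_separation)
      fm <- compute_feature_matrix(ens, specs)
      ranked <- rank_by_cov(fm, top_m = config$features$top_m)
      csv <- file.path(out_dir, "features", "feature_stats.csv")
      dir.create(dirname(csv), showWarnings = FALSE, recursive = TRUE)
      write_feature_report(ranked$stats, csv)
      state$features <- list(ensemble = ens, matrix = ranked$matrix)
      c(save_artifact("features", state$features), csv)
    })
  }

  # --- cluster -------------------------------------------------------------
  if (from_i <= 4L && to_i >= 4L) {
    inputs <- file.path(out_dir, "features", "artifact.rds")
    run_stage("cluster", config$cluster, inputs, function() {
      fe <- if (!is.null(state$features)) state$features else load_upstream("features")
      if (!is.null(config$cluster$d_min)) {
        cl <- regular_space_cluster(fe$matrix, config$cluster$d_min)
      } else {
        cl <- suggest_d_min(fe$matrix,
                            target_centers = config$cluster$target_centers)$cluster
      }
      adir <- file.path(out_dir, "cluster")
      dir.create(adir, showWarnings = FALSE, recursive = TRUE)
      acsv <- file.path(adir, "assignments.csv")
      utils::write.csv(data.frame(source_id = fe$matrix$source_ids,
                                  center = cl$center_indices[cl$assignments]),
                       acsv, row.names = FALSE)
      pdbs <- export_centers(fe$ensemble, cl, file.path(adir, "centers"))
      state$cluster <- cl
      c(save_artifact("cluster", cl), acsv, pdbs)
    })
  }

  # --- dynamics ------------------------------------------------------------
  if (from_i <= 5L && to_i >= 5L) {
    dyn <- config$dynamics
    if (dyn$mode == "files") {
      inputs <- unlist(dyn$paths)
      run_stage("dynamics", dyn, inputs, function() {
        ts <- load_timeseries(inputs, dt = if (is.null(dyn$dt)) 1 else dyn$dt)
        state$timeseries <- ts
        save_artifact("dynamics", ts)
      })
    } else {
      inputs <- file.path(out_dir, c("features", "cluster"), "artifact.rds")
      run_stage("dynamics", c(dyn, seed = config$seed), inputs, function() {
        fe <- if (!is.null(state$features)) state$features else load_upstream("features")
        cl <- if (!is.null(state$cluster)) state$cluster else load_upstream("cluster")
        centers <- fe$matrix$values[cl$center_indices, , drop = FALSE]
        ts <- simulate_cv_watch(centers, n_steps = dyn$n_steps,
                                step_size = dyn$step_size,
                                temperature = dyn$temperature,
                                kappa = dyn$kappa, seed = config$seed)
        files <- file.path(out_dir, "dynamics",
                           sprintf("traj_%02d.dat", seq_along(ts$trajectories)))
        dir.create(dirname(files[1]), showWarnings = FALSE, recursive = TRUE)
        write_timeseries(ts, files)
        state$timeseries <- ts
        c(save_artifact("dynamics", ts), files)
      })
    }
  }

  # --- amino ---------------------------------------------------------------
  if (from_i <= 6L && to_i >= 6L) {
    inputs <- file.path(out_dir, "dynamics", "artifact.rds")
    params <- c(config$amino, seed = config$seed)
    run_stage("amino", params, inputs, function() {
      ts <- if (!is.null(state$timeseries)) state$timeseries else load_upstream("dynamics")
      res <- amino_reduce(ts, k_max = config$amino$k_max,
                          n_bins = config$amino$n_bins, seed = config$seed)
      adir <- file.path(out_dir, "amino")
      dir.create(adir, showWarnings = FALSE, recursive = TRUE)
      sel_txt <- file.path(adir, "selected_cvs.txt")
      writeLines(res$selected, sel_txt)
      dcsv <- file.path(adir, "mi_distance.csv")
      utils::write.csv(res$distance_matrix, dcsv)
      state$amino <- res
      c(save_artifact("amino", res), sel_txt, dcsv)
    })
  }

  # --- spib ----------------------------------------------------------------
  if (from_i <= 7L && to_i >= 7L) {
    inputs <- file.path(out_dir, c("dynamics", "amino"), "artifact.rds")
    params <- c(config$spib, seed = config$seed)
    run_stage("spib", params, inputs, function() {
      ts <- if (!is.null(state$timeseries)) state$timeseries else load_upstream("dynamics")
      am <- if (!is.null(state$amino)) state$amino else load_upstream("amino")
      ts_red <- ts_select(ts, am$selected)
      cfg_args <- config$spib
      cfg_args$seed <- config$seed
      cfg <- do.call(spib_config, cfg_args)
      fit <- train_spib(ts_red, cfg)
      sdir <- file.path(out_dir, "spib")
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      label_files <- character(0)
      for (i in seq_along(fit$labels$labels)) {
        f <- file.path(sdir, sprintf("labels_traj_%02d.csv", i))
        utils::write.csv(data.frame(frame = seq_along(fit$labels$labels[[i]]),
                                    state = fit$labels$labels[[i]],
                                    fit$labels$latent[[i]]),
                         f, row.names = FALSE)
        label_files <- c(label_files, f)
      }
      c(save_artifact("spib", fit), label_files)
    })
  }

  manifests
}
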