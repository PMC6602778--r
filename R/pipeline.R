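# End-to-end pipeline: simulate -> detect (+ per-sound features) ->
# extract (aggregate) -> train -> evaluate -> stats. Each stage writes CSV
# artifacts stamped with the config hash; a rerun with the same config and
# seed reproduces them byte for byte.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort (the
#'   pipeline's `simulate` stage); the master seed lives here.
#' @param out_dir output directory for all artifacts.
#' @param detector a [detector_config()].
#' @param lambda ridge penalty for the classifier.
#' @param eval_modes subset of `c("loocv", "kfold", "bootstrap")`.
#' @param bootstrap_B bootstrap repetitions (default 300).
#' @param select run feature selection inside each LOOCV fold (slow).
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, out_dir, detector = detector_config(),
                            lambda = 1, eval_modes = "loocv",
                            bootstrap_B = 300L, select = FALSE,
                            log_level = "info") {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(detector, "detector_config"))
  eval_modes <- match.arg(eval_modes, c("loocv", "kfold", "bootstrap"),
                          several.ok = TRUE)
  structure(list(cohort = cohort, out_dir = out_dir, detector = detector,
                 lambda = lambda, eval_modes = eval_modes,
                 bootstrap_B = as.integer(bootstrap_B),
                 select = isTRUE(select), log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"),
                    ...))
}

pipeline_paths <- function(out_dir) {
  list(events = file.path(out_dir, "events.csv"),
       features = file.path(out_dir, "features.csv"),
       registry = file.path(out_dir, "registry.csv"),
       model = file.path(out_dir, "model.json"),
       evaluation = file.path(out_dir, "evaluation.csv"),
       contingency = file.path(out_dir, "contingency.csv"),
       stats = file.path(out_dir, "stats.csv"),
       manifest = file.path(out_dir, "pipeline_manifest.csv"))
}

require_artifact <- function(stage, path) {
  if (!file.exists(path))
    stop_invalid("stage '%s': required input %s is missing", stage,
                 basename(path))
}

#' Run the full analysis pipeline
#'
#' Stages in order: `simulate` and `detect` stream participant by
#' participant (audio is generated, detected and reduced to per-sound
#' features, then discarded), `extract` aggregates per-sound features into
#' the participant feature matrix, `train` fits the acoustic-index model on
#' all participants, `evaluate` runs the configured evaluation modes and
#' `stats` fits the random-intercept mixed models for quantity density and
#' summed amplitude. All randomness derives from the cohort's master seed.
#'
#' @param config a [pipeline_config()].
#' @param from first stage to run, one of `"simulate"`, `"extract"`,
#'   `"train"`, `"evaluate"`, `"stats"`; earlier stages' artifacts must
#'   already exist in `out_dir`.
#' @return named list of artifact paths, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, from = "simulate") {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "extract", "train", "evaluate", "stats")
  from <- match.arg(from, stages)
  run <- stages[match(from, stages):length(stages)]
  paths <- pipeline_paths(config$out_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- config$cohort
  parts <- cohort_participants(cohort)
  durations <- c(fasted = cohort$fasted_duration, fed = cohort$fed_duration)

  if ("simulate" %in% run) {
    pipe_log(config, "simulate+detect: %d participants", nrow(parts))
    ev_all <- vector("list", nrow(parts))
    for (i in seq_len(nrow(parts))) {
      p <- generate_participant(parts$participant_id[i], parts$group[i],
                                cohort)
      ev <- rbind(extract_sounds(p$fasted, config$detector),
                  extract_sounds(p$fed, config$detector))
      ev_all[[i]] <- ev
      pipe_log(config, "  %s (%s): %d sounds", parts$participant_id[i],
               parts$group[i], nrow(ev))
    }
    events <- do.call(rbind, ev_all)
    utils::write.csv(events, paths$events, row.names = FALSE)
  }

  if ("extract" %in% run) {
    require_artifact("extract", paths$events)
    events <- utils::read.csv(paths$events, stringsAsFactors = FALSE)
    reg <- feature_registry()
    rows <- lapply(seq_len(nrow(parts)), function(i) {
      sub <- events[events$participant_id == parts$participant_id[i], ,
                    drop = FALSE]
      aggregate_participant(sub, durations, reg, extended = TRUE)
    })
    fm <- do.call(rbind, rows)
    fm <- data.frame(participant_id = parts$participant_id,
                     group = parts$group, fm, check.names = FALSE)
    utils::write.csv(fm, paths$features, row.names = FALSE)
    utils::write.csv(reg, paths$registry, row.names = FALSE)
    pipe_log(config, "extract: %d x %d feature matrix", nrow(fm),
             ncol(fm) - 2L)
  }

  feats <- NULL
  load_features <- function(stage) {
    require_artifact(stage, paths$features)
    utils::read.csv(paths$features, stringsAsFactors = FALSE,
                    check.names = FALSE)
  }
  model_matrix <- function(fm) {
    as.matrix(fm[, feature_registry()$name, drop = FALSE])
  }

  if ("train" %in% run) {
    feats <- load_features("train")
    m <- fit_logistic(model_matrix(feats), feats$group,
                      lambda = config$lambda)
    write_model(m, paths$model)
    pipe_log(config, "train: model with %d features (%d dropped)",
             length(m$kept), length(m$dropped))
  }

  if ("evaluate" %in% run) {
    if (is.null(feats)) feats <- load_features("evaluate")
    x <- model_matrix(feats)
    y <- feats$group
    out <- list(); tabs <- list()
    if ("loocv" %in% config$eval_modes) {
      r <- loocv(x, y, lambda = config$lambda, select = config$select)
      out$loocv <- diagnostic_metrics(r$table)
      tabs$loocv <- r$table
    }
    if ("kfold" %in% config$eval_modes) {
      bat <- cv_battery(x, y, seed = cohort$seed, lambda = config$lambda)
      utils::write.csv(bat, file.path(config$out_dir, "kfold_battery.csv"),
                       row.names = FALSE)
    }
    if ("bootstrap" %in% config$eval_modes) {
      r <- bootstrap_eval(x, y, B = config$bootstrap_B, seed = cohort$seed,
                          lambda = config$lambda)
      out$bootstrap <- r$metrics
      tabs$bootstrap <- r$table
    }
    ev_rows <- do.call(rbind, lapply(names(out), function(mode)
      cbind(mode = mode, as.data.frame(out[[mode]]))))
    utils::write.csv(ev_rows, paths$evaluation, row.names = FALSE)
    tab_rows <- do.call(rbind, lapply(names(tabs), function(mode)
      data.frame(mode = mode, TP = tabs[[mode]]$TP, FN = tabs[[mode]]$FN,
                 FP = tabs[[mode]]$FP, TN = tabs[[mode]]$TN)))
    utils::write.csv(tab_rows, paths$contingency, row.names = FALSE)
    pipe_log(config, "evaluate: %s", paste(config$eval_modes,
                                           collapse = ", "))
  }

  if ("stats" %in% run) {
    if (is.null(feats)) feats <- load_features("stats")
    long <- function(metric) {
      do.call(rbind, lapply(c("fasted", "fed"), function(p)
        data.frame(participant_id = feats$participant_id,
                   group = feats$group, period = p,
                   response = feats[[paste0(metric, "_", p)]],
                   stringsAsFactors = FALSE)))
    }
    rows <- do.call(rbind, lapply(
      c("quantity_density", "summed_amplitude"), function(metric) {
        fit <- fit_random_intercept_lmm(long(metric))
        cbind(response = metric, fit$coefficients,
              sigma_b2 = fit$sigma_b2, sigma_e2 = fit$sigma_e2)
      }))
    utils::write.csv(rows, paths$stats, row.names = FALSE)
    pipe_log(config, "stats: mixed models fitted")
  }

  utils::write.csv(
    data.frame(artifact = names(paths), path = unlist(paths),
               config_hash = config_hash(config), seed = cohort$seed,
               exists = file.exists(unlist(paths))),
    paths$manifest, row.names = FALSE)
  invisible(paths)
}
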