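# Config-driven pipeline orchestration.
#
# Every stage reads files written by its upstream stage and writes its own
# versioned outputs plus a manifest record, so any stage can be swapped for
# another tool. Reruns with the same config and seed reproduce identical
# outputs (no timestamps in any artifact).

default_rois <- function() {
  list(
    N2 = list(channels = c("FC1", "FC2", "C1", "Cz", "C2"),
              window_ms = c(250, 350)),
    P3b = list(channels = c("CP3", "CP1", "CPz", "CP2", "CP4",
                            "P3", "Pz", "P4", "PO3", "POz", "PO4"),
               window_ms = c(400, 550)))
}

#' Validate and normalize a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), fills every missing field with the
#' package defaults (standard preprocessing parameters, N2/P3b ROIs, CBPT
#' defaults), and validates the result. All violations are reported at
#' once in a single error rather than one at a time.
#'
#' @param config Path to a YAML file, a list, or `NULL`/empty for pure
#'   defaults.
#' @return A normalized list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    yaml::read_yaml(config) %||% list()
  } else {
    config %||% list()
  }
  defaults <- list(
    seed = 1L,
    out_dir = "trialerp_out",
    montage = default_montage_path(),
    channels = NULL,
    simulate = list(n_participants = 12, n_trials = 64),
    preprocess = list(highpass_hz = 0.5, lowpass_hz = 40,
                      epoch_window_ms = c(-200, 800),
                      baseline_window_ms = c(-200, 0),
                      abs_thresh_uv = 150, grad_thresh_uv = 50),
    cbpt = list(factor = "perceptual_certainty", alpha = 0.05,
                cluster_forming_p = 0.05, n_permutations = 1000,
                max_dist = 0.06),
    rois = default_rois(),
    models = list(list(
      name = "rt",
      formula = paste("rt_ms ~ perceptual_certainty * deviant_position",
                      "+ (1 + perceptual_certainty | participant_id)",
                      "+ (1 | item_id)"),
      family = "gaussian", stage = "rt_erp")))
  cfg <- modifyList(defaults, cfg, keep.null = TRUE)

  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)
  layout <- tryCatch(read_montage(cfg$montage),
                     error = function(e) { note(conditionMessage(e)); NULL })
  pp <- tryCatch(do.call(preprocess_config, cfg$preprocess),
                 error = function(e) { note(sprintf("preprocess: %s",
                                                    conditionMessage(e))); NULL })
  tryCatch(cbpt_config(cfg$cbpt$alpha, cfg$cbpt$cluster_forming_p,
                       cfg$cbpt$n_permutations),
           error = function(e) note(sprintf("cbpt: %s", conditionMessage(e))))
  if (!is.null(layout)) {
    for (nm in names(cfg$rois)) {
      roi <- cfg$rois[[nm]]
      missing <- setdiff(roi$channels, layout$label)
      if (length(missing) > 0)
        note(sprintf("ROI %s references unknown channel(s): %s", nm,
                     paste(missing, collapse = ", ")))
      w <- as.numeric(roi$window_ms)
      if (length(w) != 2 || w[1] >= w[2])
        note(sprintf("ROI %s: window_ms must be c(start, end) with start < end.", nm))
      else if (!is.null(pp) &&
               (w[1] < pp$epoch_window_ms[1] || w[2] > pp$epoch_window_ms[2]))
        note(sprintf("ROI %s: window [%g, %g) lies outside the epoch window.",
                     nm, w[1], w[2]))
    }
  }
  if (length(errors) > 0)
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", errors, collapse = "\n")))
  cfg$preprocess_config <- pp
  structure(cfg, class = "run_config")
}

read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.json")
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = FALSE)
  else list()
}

append_manifest <- function(out_dir, record) {
  path <- file.path(out_dir, "manifest.json")
  manifest <- c(read_manifest(out_dir), list(record))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}

stage_record <- function(stage, inputs, outputs, seed, counts) {
  list(stage = stage, inputs = as.list(inputs), outputs = as.list(outputs),
       seed = seed, counts = as.list(counts))
}

# Reconstruct per-participant epoch_sets from a store (for stages that
# operate participant-wise).
store_to_epochs <- function(store) {
  pids <- unique(store$meta$participant_id)
  lapply(pids, function(pid) {
    idx <- which(store$meta$participant_id == pid)
    epoch_set(store$amplitudes[, , idx, drop = FALSE], store$time_ms,
              store$sampling_rate, channel_labels = store$channel_labels,
              participant_id = pid,
              valid = store$meta$eeg_valid[idx])
  })
}

#' Run the pipeline stages
#'
#' Executes the requested subset of
#' `simulate -> preprocess -> store -> cbpt -> export -> fit`, each stage
#' reading its upstream artifacts from `cfg$out_dir` and writing its own,
#' plus one manifest record per stage (append-only audit trail). Asking for
#' a stage whose upstream artifact is missing raises an error naming the
#' required stage.
#'
#' @param cfg A [validate_config()] result (or anything it accepts).
#' @param stages Character subset of the six stages, in any order; they are
#'   executed in pipeline order.
#' @return The manifest (list of stage records), invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "preprocess", "store",
                                         "cbpt", "export", "fit")) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  all_stages <- c("simulate", "preprocess", "store", "cbpt", "export", "fit")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  layout <- read_montage(cfg$montage)
  pp <- cfg$preprocess_config
  seeds <- child_seeds(cfg$seed, 2)
  need <- function(path, stage) {
    if (!file.exists(path))
      abort(sprintf("missing upstream artifact %s: run stage `%s` first.",
                    path, stage))
    path
  }
  p_raw <- file.path(out, "store_raw.h5")
  p_pre <- file.path(out, "store_preprocessed.h5")
  p_store <- file.path(out, "store.h5")
  p_beh <- file.path(out, "behavior.csv")

  for (stage in stages) {
    if (stage == "simulate") {
      gt <- do.call(ground_truth, c(cfg$simulate, list(seed = seeds[1])))
      design <- simulate_design(gt)
      sim <- simulate_epochs(design, gt, layout, channels = cfg$channels)
      behavior <- simulate_behavior(design, sim$truth, gt)
      ep <- sim$epochs[[1]]
      amp <- array(unlist(lapply(sim$epochs, function(e) e$data)),
                   dim = c(dim(ep$data)[1:2], nrow(design)))
      raw <- trial_store(amp, ep$time_ms, ep$channel_labels,
                         design, sampling_rate = ep$sampling_rate)
      save_store(raw, p_raw)
      write.csv(behavior, p_beh, row.names = FALSE)
      write.csv(sim$truth, file.path(out, "truth_synthetic.csv"),
                row.names = FALSE)
      inform(sprintf("simulate: %d participants x %d trials.",
                     gt$n_participants, gt$n_trials))
      append_manifest(out, stage_record(
        "simulate", character(),
        c(p_raw, p_beh, file.path(out, "truth_synthetic.csv")), cfg$seed,
        list(participants = gt$n_participants, trials_total = nrow(design))))
    } else if (stage == "preprocess") {
      raw <- load_store(need(p_raw, "simulate"))
      epochs <- store_to_epochs(raw)
      epochs <- lapply(epochs, function(e) {
        e <- baseline_correct(e, pp)
        e$valid <- detect_artifacts(e, pp)
        e
      })
      meta <- raw$meta
      meta$eeg_valid <- unlist(lapply(epochs, function(e) e$valid))
      amp <- array(unlist(lapply(epochs, function(e) e$data)),
                   dim = dim(raw$amplitudes))
      pre <- trial_store(amp, raw$time_ms, raw$channel_labels, meta,
                         sampling_rate = raw$sampling_rate)
      save_store(pre, p_pre)
      inform(sprintf("preprocess: %d/%d trials invalidated.",
                     sum(!meta$eeg_valid), nrow(meta)))
      append_manifest(out, stage_record(
        "preprocess", p_raw, p_pre, cfg$seed,
        list(trials = nrow(meta), invalid = sum(!meta$eeg_valid))))
    } else if (stage == "store") {
      pre <- load_store(need(p_pre, "preprocess"))
      behavior <- as_tibble(read.csv(need(p_beh, "simulate"),
                                     stringsAsFactors = FALSE))
      epochs <- store_to_epochs(pre)
      beh_split <- split(behavior, behavior$participant_id)
      pids <- vapply(epochs, function(e) as.character(e$participant_id),
                     character(1))
      full <- build_store(epochs, beh_split[pids])
      full$meta$perceptual_certainty <-
        factor(full$meta$perceptual_certainty, pc_levels)
      full$meta$deviant_position <-
        factor(full$meta$deviant_position, dp_levels)
      full$meta$response <- factor(full$meta$response,
                                   c("hit", "error", "miss"))
      save_store(full, p_store)
      append_manifest(out, stage_record(
        "store", c(p_pre, p_beh), p_store, cfg$seed,
        list(trials = n_trials(full))))
    } else if (stage == "cbpt") {
      full <- load_store(need(p_store, "store"))
      ana <- apply_analysis_filters(full, "rt_erp")
      ca <- condition_averages(ana, cfg$cbpt$factor)
      cells <- ca$cells
      res <- cbpt_test(cond_avg(ca, cells[1]), cond_avg(ca, cells[2]),
                       layout,
                       cbpt_config(cfg$cbpt$alpha, cfg$cbpt$cluster_forming_p,
                                   cfg$cbpt$n_permutations, seed = seeds[2]),
                       max_dist = cfg$cbpt$max_dist, time_ms = ana$time_ms)
      p_clusters <- file.path(out, "clusters.csv")
      write_cluster_table(res, p_clusters)
      p_mask <- file.path(out, "significance_mask.csv")
      write.csv(data.frame(channel = rownames(attr(res, "mask")),
                           attr(res, "mask"), check.names = FALSE),
                p_mask, row.names = FALSE)
      inform(sprintf("cbpt: %d cluster(s), %d significant.",
                     nrow(res), sum(res$significant)))
      append_manifest(out, stage_record(
        "cbpt", p_store, c(p_clusters, p_mask), cfg$seed,
        list(clusters = nrow(res), significant = sum(res$significant))))
    } else if (stage == "export") {
      full <- load_store(need(p_store, "store"))
      ana <- apply_analysis_filters(full, "rt_erp")
      outputs <- character()
      for (nm in names(cfg$rois)) {
        roi <- cfg$rois[[nm]]
        p_roi <- file.path(out, sprintf("roi_%s.csv", nm))
        export_long(ana, roi$channels, as.numeric(roi$window_ms),
                    amplitude_col = nm, path = p_roi)
        outputs <- c(outputs, p_roi)
      }
      append_manifest(out, stage_record(
        "export", p_store, outputs, cfg$seed,
        list(rois = length(cfg$rois), trials = n_trials(ana))))
    } else if (stage == "fit") {
      outputs <- character()
      counts <- list()
      roi1 <- names(cfg$rois)[1]
      p_roi <- need(file.path(out, sprintf("roi_%s.csv", roi1)), "export")
      roi_tab <- as_tibble(read.csv(p_roi, stringsAsFactors = TRUE))
      for (m in cfg$models) {
        fit <- fit_trial_model(as.formula(m$formula), roi_tab,
                               family = m$family %||% "gaussian")
        p_fit <- file.path(out, sprintf("model_%s.csv", m$name))
        write.csv(tidy(fit), p_fit, row.names = FALSE)
        outputs <- c(outputs, p_fit)
        counts[[m$name]] <- nrow(fit$data)
      }
      append_manifest(out, stage_record("fit", p_roi, outputs, cfg$seed,
                                        counts))
    }
  }
  invisible(read_manifest(out))
}
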