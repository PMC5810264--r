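# Ground-truth synthetic EEG/behavior generator.
#
# Emulates a 2 (perceptual certainty: blurred/intact) x 4 (deviant
# position: left/right/top/bottom) visual-search study: two ERP components
# (a fronto-central negative N2 at 250-350 ms and a centro-parietal
# positive P3b at 400-550 ms) whose single-trial amplitudes carry fixed
# condition effects plus crossed participant/item random effects, embedded
# in spatially correlated 1/f noise; behavior (RT, hit/error/miss) is
# generated from the same latent amplitudes so brain-behavior effects are
# recoverable by construction.

#' ERP component template for the simulator
#'
#' @param name Component name.
#' @param center_channel Channel at the spatial peak.
#' @param spatial_sd Gaussian spatial spread (montage units).
#' @param window_ms Half-open active window `c(start, end)` in ms.
#' @param roi_channels Channels whose window mean defines the component's
#'   single-trial amplitude; spatial weights are normalized so that the
#'   noise-free ROI/window mean equals the latent amplitude exactly.
#' @param intercept Grand-mean amplitude (uV; sign = polarity).
#' @param pc_effect,dp_effect,pcdp_effect Fixed effects (uV) on the
#'   sliding-difference codes (intact - blurred; right - left).
#' @param subj_int_sd,subj_pc_sd By-participant intercept/PC-slope SDs (uV).
#' @param item_int_sd,item_pc_sd By-item intercept/PC-slope SDs (uV).
#' @return List of class `erp_component`.
#' @export
erp_component <- function(name, center_channel, spatial_sd = 0.045,
                          window_ms, roi_channels,
                          intercept, pc_effect = 0, dp_effect = 0,
                          pcdp_effect = 0,
                          subj_int_sd = 0, subj_pc_sd = 0,
                          item_int_sd = 0, item_pc_sd = 0) {
  structure(as.list(environment()), class = "erp_component")
}

#' Ground truth for a simulated study
#'
#' Defaults reproduce the reference study design: 40 participants, 1920
#' trials in 5 blocks, 2 x 4 factor crossing, N2/P3b component templates
#' with effect and variance magnitudes at the scale of published
#' single-trial LMM estimates, a 2 s response timeout, and 500 Hz epochs
#' from -200 to 800 ms.
#'
#' @param n_participants,n_trials,n_blocks,n_items Design sizes.
#' @param sampling_rate Hz.
#' @param epoch_window_ms Half-open epoch window (ms).
#' @param components List of [erp_component()]s.
#' @param noise_sd Total noise SD per channel/sample (uV).
#' @param noise_spatial_sd Spatial correlation length of the noise
#'   (montage units; 0 = spatially white).
#' @param noise_pink_fraction Share of noise variance given to 1/f
#'   (temporally correlated) noise; the rest is white.
#' @param artifact_rate Per-trial probability of an injected high-amplitude
#'   artifact (exceeds the 150 uV / 50 uV-gradient thresholds).
#' @param behavior List of behavioral model parameters: RT linear predictor
#'   (`rt_intercept`, `rt_pc`, `rt_dp`, `rt_pcdp`, `rt_beta_n2`,
#'   `rt_beta_p3` — the two betas per 10 uV), RT random SDs
#'   (`rt_subj_sd`, `rt_item_sd`, `rt_resid_sd`), `timeout_ms`, and the
#'   accuracy logit (`acc_intercept`, `acc_pc`, `acc_dp`, `acc_pcdp`,
#'   `acc_subj_sd`).
#' @param seed Default RNG seed for the generators.
#' @return List of class `ground_truth`.
#' @export
ground_truth <- function(n_participants = 40, n_trials = 1920, n_blocks = 5,
                         n_items = 4, sampling_rate = 500,
                         epoch_window_ms = c(-200, 800),
                         components = list(
                           N2 = erp_component(
                             "N2", center_channel = "FCz", spatial_sd = 0.045,
                             window_ms = c(250, 350),
                             roi_channels = c("FC1", "FC2", "C1", "Cz", "C2"),
                             intercept = -3.4, pc_effect = -0.9,
                             dp_effect = 0.3, pcdp_effect = 0.25,
                             subj_int_sd = 1.9, subj_pc_sd = 0.5,
                             item_int_sd = 0.4, item_pc_sd = 0.3),
                           P3b = erp_component(
                             "P3b", center_channel = "Pz", spatial_sd = 0.055,
                             window_ms = c(400, 550),
                             roi_channels = c("CP3", "CP1", "CPz", "CP2", "CP4",
                                              "P3", "Pz", "P4", "PO3", "POz", "PO4"),
                             intercept = 4.2, pc_effect = 1.2,
                             subj_int_sd = 3.2, subj_pc_sd = 0.5,
                             item_int_sd = 0.6, item_pc_sd = 0.6)),
                         noise_sd = 8, noise_spatial_sd = 0.05,
                         noise_pink_fraction = 0.6,
                         artifact_rate = 0.02,
                         behavior = list(
                           rt_intercept = 470, rt_pc = -30, rt_dp = -4.7,
                           rt_pcdp = 3.7, rt_beta_n2 = 13, rt_beta_p3 = -32.2,
                           rt_subj_sd = 50, rt_item_sd = 15, rt_resid_sd = 90,
                           timeout_ms = 2000,
                           acc_intercept = 3.3, acc_pc = 0.95, acc_dp = 0.3,
                           acc_pcdp = -0.2, acc_subj_sd = 0.9),
                         seed = 1L) {
  stopifnot(n_participants >= 1, n_trials >= 1, n_blocks >= 1, n_items >= 1)
  structure(as.list(environment()), class = "ground_truth")
}

pc_levels <- c("blurred", "intact")
dp_levels <- c("left", "right", "top", "bottom")

# Sliding-difference style numeric codes used by the generator.
pc_code <- function(pc) ifelse(pc == "intact", 0.5, -0.5)
dp_code <- function(dp) ifelse(dp == "right", 0.5, ifelse(dp == "left", -0.5, 0))

#' Simulate the behavioral design tables
#'
#' Balanced 2 x 4 factor crossing (equal trials per cell), items rotated
#' within cells, presentation order randomized independently per
#' participant, block labels assigned in order. `trial_index` is strictly
#' increasing: the recording order.
#'
#' @param gt A [ground_truth()].
#' @param n_participants,n_trials Overrides of the ground-truth defaults.
#' @param seed RNG seed (default `gt$seed`).
#' @return Tibble with one row per trial: `participant_id`, `trial_index`,
#'   `block`, `perceptual_certainty`, `deviant_position`, `item_id`.
#' @export
simulate_design <- function(gt = ground_truth(),
                            n_participants = gt$n_participants,
                            n_trials = gt$n_trials, seed = gt$seed) {
  n_cells <- length(pc_levels) * length(dp_levels)
  if (n_trials %% n_cells != 0) {
    near <- round(n_trials / n_cells) * n_cells
    if (near == 0) near <- n_cells
    abort(sprintf("n_trials (%d) must be divisible by the %d design cells; nearest valid value: %d.",
                  n_trials, n_cells, near))
  }
  cells <- tidyr::expand_grid(perceptual_certainty = pc_levels,
                              deviant_position = dp_levels)
  per_cell <- n_trials / n_cells
  base <- cells[rep(seq_len(n_cells), each = per_cell), ]
  base$item_id <- sprintf("item%02d",
                          rep_len(seq_len(gt$n_items), n_trials))
  with_seed(seed, {
    purrr::map(seq_len(n_participants), function(p) {
      tb <- base[sample.int(n_trials), ]
      tb$participant_id <- sprintf("P%02d", p)
      tb$trial_index <- seq_len(n_trials)
      tb$block <- ceiling(tb$trial_index / ceiling(n_trials / gt$n_blocks))
      tb[, c("participant_id", "trial_index", "block",
             "perceptual_certainty", "deviant_position", "item_id")]
    }) |> dplyr::bind_rows() |>
      dplyr::mutate(
        perceptual_certainty = factor(.data$perceptual_certainty, pc_levels),
        deviant_position = factor(.data$deviant_position, dp_levels))
  })
}

# Spatially correlated 1/f + white noise, channels x samples.
noise_matrix <- function(n_ch, n_samp, fs, positions, spatial_sd,
                         pink_fraction, sd_target) {
  white <- matrix(rnorm(n_ch * n_samp), n_ch, n_samp)
  pink <- matrix(rnorm(n_ch * n_samp), n_ch, n_samp)
  if (n_samp > 2) {
    freqs <- c(1, seq_len(n_samp - 1)) * fs / n_samp
    shape <- 1 / sqrt(pmax(freqs, fs / n_samp))
    pink <- t(apply(pink, 1, function(x) Re(fft(fft(x) * shape, inverse = TRUE)) / n_samp))
  }
  norm_rows <- function(m) m / max(sd(as.vector(m)), .Machine$double.eps)
  x <- sqrt(1 - pink_fraction) * norm_rows(white) +
    sqrt(pink_fraction) * norm_rows(pink)
  if (spatial_sd > 0 && !is.null(positions)) {
    D2 <- as.matrix(stats::dist(positions))^2
    W <- exp(-D2 / (2 * spatial_sd^2))
    W <- W / sqrt(rowSums(W^2))  # keep per-channel variance at 1
    x <- W %*% x
  }
  x * sd_target / max(sd(as.vector(x)), .Machine$double.eps)
}

component_fields <- function(comp, layout, channels, time_ms) {
  pos <- as.matrix(layout[match(channels, layout$label), c("x", "y", "z")])
  ci <- match(comp$center_channel, layout$label)
  if (is.na(ci)) abort(sprintf("component %s: center channel %s not in the montage.",
                               comp$name, comp$center_channel))
  center <- as.numeric(layout[ci, c("x", "y", "z")])
  d2 <- rowSums((pos - matrix(center, nrow(pos), 3, byrow = TRUE))^2)
  w <- exp(-d2 / (2 * comp$spatial_sd^2))
  roi <- match(comp$roi_channels, channels)
  if (anyNA(roi)) abort(sprintf("component %s: ROI channel(s) missing from montage.",
                                comp$name))
  w <- w / mean(w[roi])
  widx <- window_index(time_ms, comp$window_ms)
  k <- numeric(length(time_ms))
  phase <- (time_ms[widx] - comp$window_ms[1]) /
    (comp$window_ms[2] - comp$window_ms[1])
  bump <- sin(pi * phase)^2
  k[widx] <- bump / mean(bump)
  list(spatial = w, kernel = k)
}

# Latent single-trial component amplitude from design codes + random effects.
component_amplitude <- function(comp, design, subj_re, item_re) {
  p <- match(design$participant_id, subj_re$participant_id)
  i <- match(design$item_id, item_re$item_id)
  pcc <- pc_code(design$perceptual_certainty)
  dpc <- dp_code(design$deviant_position)
  comp$intercept + comp$pc_effect * pcc + comp$dp_effect * dpc +
    comp$pcdp_effect * pcc * dpc +
    subj_re[[paste0(comp$name, "_int")]][p] +
    subj_re[[paste0(comp$name, "_pc")]][p] * pcc +
    item_re[[paste0(comp$name, "_int")]][i] +
    item_re[[paste0(comp$name, "_pc")]][i] * pcc
}

#' Draw latent single-trial component amplitudes for a design
#'
#' Samples the by-participant and by-item random effects of every component
#' and combines them with the fixed condition effects into one latent
#' amplitude per trial and component — the ground truth that both the EEG
#' epochs and the behavioral model are generated from.
#'
#' @param design Output of [simulate_design()].
#' @param gt A [ground_truth()].
#' @param seed RNG seed.
#' @return List: `truth` (tibble: `participant_id`, `trial_index`, one
#'   amplitude column per component, `artifact` flag), `random_effects`
#'   (list of subject/item tibbles).
#' @export
simulate_amplitudes <- function(design, gt = ground_truth(), seed = gt$seed + 1L) {
  participants <- unique(design$participant_id)
  items <- sort(unique(design$item_id))
  with_seed(seed, {
    subj_re <- tibble(participant_id = participants)
    item_re <- tibble(item_id = items)
    for (comp in gt$components) {
      subj_re[[paste0(comp$name, "_int")]] <-
        rnorm(length(participants), 0, comp$subj_int_sd)
      subj_re[[paste0(comp$name, "_pc")]] <-
        rnorm(length(participants), 0, comp$subj_pc_sd)
      item_re[[paste0(comp$name, "_int")]] <-
        rnorm(length(items), 0, comp$item_int_sd)
      item_re[[paste0(comp$name, "_pc")]] <-
        rnorm(length(items), 0, comp$item_pc_sd)
    }
    truth <- design[, c("participant_id", "trial_index")]
    for (comp in gt$components)
      truth[[comp$name]] <- component_amplitude(comp, design, subj_re, item_re)
    truth$artifact <- runif(nrow(design)) < gt$artifact_rate
    list(truth = truth, random_effects = list(subject = subj_re, item = item_re))
  })
}

#' Simulate epochs for a design
#'
#' Builds, per participant, an [epoch_set()] where every trial is the sum
#' of the component templates (spatial weight x temporal kernel, scaled by
#' the latent single-trial amplitude) plus spatially correlated 1/f + white
#' noise. A fraction `gt$artifact_rate` of trials receives an injected
#' high-amplitude artifact. The latent truth is returned alongside for
#' recovery testing.
#'
#' @param design Output of [simulate_design()] (all participants).
#' @param gt A [ground_truth()].
#' @param layout A [read_montage()] layout; scalp channels are simulated.
#' @param channels Optional subset of scalp channels to simulate (speeds up
#'   desk-scale runs); must contain every component ROI channel.
#' @param seed RNG seed (default `gt$seed + 1`).
#' @return List: `epochs` (list of [epoch_set()], one per participant),
#'   `truth` (tibble: per-trial latent component amplitudes and
#'   `artifact` flag), `random_effects` (list of the drawn subject/item
#'   effects).
#' @export
simulate_epochs <- function(design, gt = ground_truth(),
                            layout = read_montage(default_montage_path()),
                            channels = NULL, seed = gt$seed + 1L) {
  scalp <- layout$label[layout$type == "scalp"]
  channels <- channels %||% scalp
  if (!all(channels %in% scalp))
    abort("`channels` must be scalp channels of the layout.")
  fs <- gt$sampling_rate
  n_samp <- round(diff(gt$epoch_window_ms) * fs / 1000)
  off0 <- ceiling(gt$epoch_window_ms[1] * fs / 1000)
  time_ms <- (off0 + seq_len(n_samp) - 1) * 1000 / fs
  fields <- lapply(gt$components, component_fields, layout = layout,
                   channels = channels, time_ms = time_ms)
  pos <- as.matrix(layout[match(channels, layout$label), c("x", "y", "z")])

  participants <- unique(design$participant_id)
  seeds <- child_seeds(seed, 2)
  amp <- simulate_amplitudes(design, gt, seed = seeds[1])
  truth <- amp$truth
  with_seed(seeds[2], {
    epochs <- lapply(participants, function(pid) {
      rows <- which(design$participant_id == pid)
      dat <- array(0, dim = c(length(channels), n_samp, length(rows)))
      for (j in seq_along(rows)) {
        tr <- rows[j]
        sig <- matrix(0, length(channels), n_samp)
        for (ci in seq_along(gt$components)) {
          comp <- gt$components[[ci]]
          sig <- sig + truth[[comp$name]][tr] *
            outer(fields[[ci]]$spatial, fields[[ci]]$kernel)
        }
        if (gt$noise_sd > 0)
          sig <- sig + noise_matrix(length(channels), n_samp, fs, pos,
                                    gt$noise_spatial_sd,
                                    gt$noise_pink_fraction, gt$noise_sd)
        if (truth$artifact[tr]) {
          ch <- sample.int(length(channels), 1)
          s0 <- sample.int(n_samp - 2L, 1)
          sig[ch, s0 + 0:2] <- sig[ch, s0 + 0:2] + 400
        }
        dat[, , j] <- sig
      }
      epoch_set(dat, time_ms, fs, channel_labels = channels,
                event_codes = rep("S  1", length(rows)),
                participant_id = pid)
    })
    list(epochs = epochs, truth = truth,
         random_effects = amp$random_effects)
  })
}

#' Simulate behavior from latent component amplitudes
#'
#' RT is gaussian around a linear predictor in the condition codes and the
#' per-10-uV component amplitudes, with by-participant and by-item shifts;
#' draws at or beyond the response timeout become misses (RT = NA).
#' Responses are Bernoulli via a logistic predictor with a by-participant
#' intercept.
#'
#' @param design Output of [simulate_design()].
#' @param amplitudes Tibble with one row per design row holding the latent
#'   component amplitudes (uV), e.g. the `truth` of [simulate_epochs()].
#' @param gt A [ground_truth()].
#' @param seed RNG seed (default `gt$seed + 2`).
#' @return `design` with `rt_ms` and `response` (`hit`/`error`/`miss`)
#'   columns appended.
#' @export
simulate_behavior <- function(design, amplitudes, gt = ground_truth(),
                              seed = gt$seed + 2L) {
  b <- gt$behavior
  pcc <- pc_code(design$perceptual_certainty)
  dpc <- dp_code(design$deviant_position)
  n2 <- amplitudes[["N2"]] %||% rep(0, nrow(design))
  p3 <- amplitudes[["P3b"]] %||% rep(0, nrow(design))
  participants <- unique(design$participant_id)
  items <- sort(unique(design$item_id))
  with_seed(seed, {
    rt_subj <- setNames(rnorm(length(participants), 0, b$rt_subj_sd), participants)
    rt_item <- setNames(rnorm(length(items), 0, b$rt_item_sd), items)
    acc_subj <- setNames(rnorm(length(participants), 0, b$acc_subj_sd), participants)
    mu <- b$rt_intercept + b$rt_pc * pcc + b$rt_dp * dpc +
      b$rt_pcdp * pcc * dpc +
      b$rt_beta_n2 * (n2 - mean(n2)) / 10 +
      b$rt_beta_p3 * (p3 - mean(p3)) / 10 +
      rt_subj[as.character(design$participant_id)] +
      rt_item[as.character(design$item_id)]
    rt <- rnorm(nrow(design), mu, b$rt_resid_sd)
    miss <- rt >= b$timeout_ms
    eta <- b$acc_intercept + b$acc_pc * pcc + b$acc_dp * dpc +
      b$acc_pcdp * pcc * dpc +
      acc_subj[as.character(design$participant_id)]
    hit <- rbinom(nrow(design), 1, plogis(eta)) == 1
    out <- design
    out$rt_ms <- ifelse(miss, NA_real_, pmax(rt, 150))
    out$response <- factor(ifelse(miss, "miss", ifelse(hit, "hit", "error")),
                           levels = c("hit", "error", "miss"))
    out
  })
}

#' Simulate a complete study into a trial store
#'
#' Convenience wrapper: design → epochs (+ artifact flags via
#' [detect_artifacts()]) → behavior → [build_store()].
#'
#' @inheritParams simulate_epochs
#' @param n_participants,n_trials Overrides of the ground-truth defaults.
#' @param cfg [preprocess_config()] used for the artifact flags.
#' @return List: `store` (a [trial_store()] whose metadata includes the
#'   behavioral columns), `truth`, `random_effects`, `gt`.
#' @export
simulate_study <- function(gt = ground_truth(),
                           layout = read_montage(default_montage_path()),
                           channels = NULL,
                           n_participants = gt$n_participants,
                           n_trials = gt$n_trials,
                           cfg = preprocess_config(), seed = gt$seed) {
  seeds <- child_seeds(seed, 3)
  design <- simulate_design(gt, n_participants, n_trials, seed = seeds[1])
  sim <- simulate_epochs(design, gt, layout, channels, seed = seeds[2])
  behavior <- simulate_behavior(design, sim$truth, gt, seed = seeds[3])
  epochs <- lapply(sim$epochs, function(ep) {
    ep$valid <- detect_artifacts(ep, cfg)
    ep
  })
  beh_split <- split(behavior, behavior$participant_id)
  pids <- vapply(epochs, function(e) as.character(e$participant_id), character(1))
  store <- build_store(epochs, beh_split[pids])
  list(store = store, truth = sim$truth,
       random_effects = sim$random_effects, gt = gt)
}

#' Simulate null condition averages for calibration studies
#'
#' Draws participant-level "condition average" arrays for two conditions
#' from one identical distribution (spatially correlated 1/f + white
#' noise), i.e. data exactly exchangeable under the null hypothesis of the
#' cluster-based permutation test. Used to measure the empirical
#' family-wise false-positive rate.
#'
#' @param n_participants Number of participants.
#' @param channels Channel labels (must be scalp channels of `layout`).
#' @param n_samples Samples per pseudo-epoch.
#' @param layout A [read_montage()] layout supplying positions.
#' @param sampling_rate Hz (controls the 1/f shaping only).
#' @param noise_sd Per-point SD of the averages.
#' @param noise_spatial_sd Spatial correlation length (montage units).
#' @param noise_pink_fraction Share of 1/f noise variance.
#' @param seed RNG seed.
#' @return List `avgA`, `avgB`: arrays participants x channels x samples
#'   with channel dimnames.
#' @export
simulate_null_averages <- function(n_participants, channels, n_samples,
                                   layout = read_montage(default_montage_path()),
                                   sampling_rate = 500, noise_sd = 1,
                                   noise_spatial_sd = 0.05,
                                   noise_pink_fraction = 0.6, seed = NULL) {
  scalp <- layout$label[layout$type == "scalp"]
  if (!all(channels %in% scalp))
    abort("`channels` must be scalp channels of the layout.")
  pos <- as.matrix(layout[match(channels, layout$label), c("x", "y", "z")])
  draw <- function() {
    a <- array(0, dim = c(n_participants, length(channels), n_samples),
               dimnames = list(NULL, channels, NULL))
    for (p in seq_len(n_participants))
      a[p, , ] <- noise_matrix(length(channels), n_samples, sampling_rate,
                               pos, noise_spatial_sd, noise_pink_fraction,
                               noise_sd)
    a
  }
  with_seed(seed, list(avgA = draw(), avgB = draw()))
}
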