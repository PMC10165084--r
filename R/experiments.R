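# Experiment harnesses: preprocess -> window -> train -> complete ->
# evaluate pipelines on synthetic subjects. These are the package's own
# reduced-scale versions of the study designs the model is meant for
# (single-subject completion, input-distance sweeps, cross-subject
# transfer), and are what the test suite and the command-line tool drive.

#' Preprocess a training/test session pair
#'
#' Band-pass filters both sessions and normalizes them with statistics
#' estimated on the training session only (the test session reuses the
#' stored parameters, avoiding leakage).
#'
#' @param train_rec,test_rec raw `eeg_recording`s.
#' @param low,high band edges in Hz.
#' @return List with `train`, `test` (normalized recordings) and `params`.
#' @export
preprocess_pair <- function(train_rec, test_rec, low = 2, high = 40) {
  ftr <- bandpass_filter(train_rec, low, high)
  fte <- bandpass_filter(test_rec, low, high)
  nz <- normalize_recording(ftr)
  list(train = nz$rec, test = apply_normalization(fte, nz$params),
       params = nz$params)
}

#' Train a completion model and evaluate it on a held-out session
#'
#' The full single-subject pipeline: preprocess the session pair, window
#' the training session, train the network, stitch a complementary signal
#' across the test session, and score it against the measured target
#' channel (baseline-corrected, on the normalized scale). The
#' inverse-distance interpolation baseline is scored on the same test
#' session for comparison.
#'
#' @param train_rec,test_rec raw `eeg_recording`s containing inputs and
#'   target.
#' @param inputs four input channel ids.
#' @param target target channel id.
#' @param layout an `electrode_layout` (for the interpolation baseline and
#'   distance reporting).
#' @param config a [model_config()].
#' @param run a [training_run()].
#' @param amplitude also apply amplitude correction when scoring the model.
#' @return List with `model`, `run`, `metrics` (model), `interp_metrics`
#'   (baseline), `completed` (the complementary signal, normalized units)
#'   and `mean_distance_cm`.
#' @export
evaluate_subject <- function(train_rec, test_rec, inputs, target,
                             layout = build_2a_layout(),
                             config = model_config(),
                             run = training_run(preset = "satisfactory"),
                             amplitude = FALSE) {
  pp <- preprocess_pair(train_rec, test_rec)
  spec <- window_spec(L = config$seq_len, L_prime = config$label_len)
  tr <- train_model(make_windows(pp$train, inputs, target, spec),
                    config = config, run = run)
  comp <- complete_channel(tr$model, pp$test)
  truth <- channel_signal(pp$test, target)
  metrics <- evaluate_completion(truth, comp$data[1, ], baseline = TRUE,
                                 amplitude = amplitude)
  interp <- interpolate_channel(pp$test, layout, inputs, target)
  interp_metrics <- evaluate_completion(truth, interp$signal,
                                        baseline = TRUE)
  list(model = tr$model, run = tr$run, metrics = metrics,
       interp_metrics = interp_metrics, completed = comp,
       truth_signal = truth,
       mean_distance_cm = mean_input_distance(layout, inputs, target))
}

#' Identity-recovery experiment
#'
#' A sanity-recovery task: the target channel's signal is an exact copy of
#' the first input channel, so a correctly implemented and trained network
#' must reproduce it nearly perfectly on held-out data.
#'
#' @param seed experiment seed.
#' @param duration_s training-session length in seconds (test session is
#'   half as long).
#' @param config,run model and training settings.
#' @return The [evaluate_subject()] result.
#' @export
experiment_identity <- function(seed = 1L, duration_s = 72,
                                config = model_config(seed = seed),
                                run = training_run(preset = "satisfactory",
                                                   batch_size = 16L,
                                                   seed = seed)) {
  layout <- build_2a_layout()
  inputs <- c(1L, 8L, 12L, 20L)
  target <- 10L
  cfg <- synthetic_config(duration_s = duration_s, seed = seed)
  pair <- generate_subject_pair(layout, cfg)
  copy_target <- function(rec) {
    rec$data[match(target, rec$channel_ids), ] <-
      rec$data[match(inputs[1], rec$channel_ids), ]
    rec
  }
  train_rec <- copy_target(pair$train)
  test_rec <- copy_target(.crop_recording(pair$test, duration_s / 2))
  evaluate_subject(train_rec, test_rec, inputs, target, layout,
                   config = config, run = run)
}

#' Learnable-mixture experiment
#'
#' The target channel is a mildly nonlinear, noisy mixture of the source
#' field observed by the input channels. A trained network should track it
#' more closely than the fixed inverse-distance interpolation baseline.
#'
#' @inheritParams experiment_identity
#' @return The [evaluate_subject()] result.
#' @export
experiment_mixture <- function(seed = 1L, duration_s = 72,
                               config = model_config(seed = seed),
                               run = training_run(preset = "satisfactory",
                                                  batch_size = 16L,
                                                  seed = seed)) {
  layout <- build_2a_layout()
  cfg <- synthetic_config(duration_s = duration_s, nonlinearity = "mild",
                          seed = seed)
  pair <- generate_subject_pair(layout, cfg)
  evaluate_subject(pair$train, .crop_recording(pair$test, duration_s / 2),
                   c(1L, 8L, 12L, 20L), 10L, layout,
                   config = config, run = run)
}

#' Input-distance sweep
#'
#' Trains one model per input-set condition and seed, completing Cz from a
#' nearby ring (mean distance 2.5 cm) and from the most distant available
#' set, and reports held-out correlations. Completion quality is expected
#' to decay with the mean input-to-target distance.
#'
#' @param seeds experiment seeds (one subject each).
#' @param duration_s training-session length per subject in seconds.
#' @param conditions named list of input-channel sets.
#' @param config_fn,run_fn functions of the seed returning model/training
#'   settings.
#' @return A data.frame with one row per seed x condition: `seed`,
#'   `condition`, `mean_distance_cm`, `mse`, `rho`.
#' @export
experiment_distance <- function(seeds = 1:3, duration_s = 24,
                                conditions = list(
                                  near = c(4L, 9L, 11L, 16L),
                                  far = c(1L, 7L, 13L, 22L)),
                                config_fn = function(s) model_config(seed = s),
                                run_fn = function(s)
                                  training_run(preset = "satisfactory",
                                               batch_size = 16L,
                                               seed = s)) {
  layout <- build_2a_layout()
  target <- 10L
  rows <- list()
  for (s in seeds) {
    cfg <- synthetic_config(duration_s = duration_s, nonlinearity = "mild",
                            seed = s)
    pair <- generate_subject_pair(layout, cfg)
    test_rec <- .crop_recording(pair$test, duration_s / 2)
    for (cn in names(conditions)) {
      res <- evaluate_subject(pair$train, test_rec, conditions[[cn]],
                              target, layout, config = config_fn(s),
                              run = run_fn(s))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, condition = cn,
        mean_distance_cm = res$mean_distance_cm,
        mse = res$metrics$mse, rho = res$metrics$rho)
    }
  }
  do.call(rbind, rows)
}

#' Cross-subject transfer evaluation
#'
#' Trains on one synthetic subject and evaluates the frozen model on other
#' subjects (different generator seeds), each preprocessed with its own
#' training-session statistics. Mirrors the question of whether a model
#' fitted on one operator's data completes another operator's channels.
#'
#' @param train_seed seed of the training subject.
#' @param eval_seeds seeds of the evaluation subjects.
#' @param duration_s session length in seconds.
#' @param inputs,target channel ids.
#' @param config,run model and training settings.
#' @return A data.frame with `subject`, `mse`, `rho` (first row is the
#'   training subject's own held-out session).
#' @export
experiment_transfer <- function(train_seed = 1L, eval_seeds = 2:4,
                                duration_s = 48,
                                inputs = c(1L, 8L, 12L, 20L), target = 10L,
                                config = model_config(seed = train_seed),
                                run = training_run(preset = "satisfactory",
                                                   batch_size = 16L,
                                                   seed = train_seed)) {
  layout <- build_2a_layout()
  base_cfg <- synthetic_config(duration_s = duration_s,
                               nonlinearity = "mild", seed = train_seed)
  pair <- generate_subject_pair(layout, base_cfg)
  res <- evaluate_subject(pair$train, .crop_recording(pair$test,
                                                      duration_s / 2),
                          inputs, target, layout, config = config,
                          run = run)
  rows <- list(data.frame(subject = paste0("S", train_seed),
                          mse = res$metrics$mse, rho = res$metrics$rho))
  for (s in eval_seeds) {
    cfg_s <- synthetic_config(duration_s = duration_s,
                              nonlinearity = "mild", seed = s)
    pair_s <- generate_subject_pair(layout, cfg_s)
    pp <- preprocess_pair(pair_s$train,
                          .crop_recording(pair_s$test, duration_s / 2))
    comp <- complete_channel(res$model, pp$test)
    m <- evaluate_completion(channel_signal(pp$test, target),
                             comp$data[1, ], baseline = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(subject = paste0("S", s),
                                            mse = m$mse, rho = m$rho)
  }
  do.call(rbind, rows)
}

.crop_recording <- function(rec, duration_s) {
  n <- min(ncol(rec$data), round(duration_s * rec$rate))
  recording(rec$data[, seq_len(n), drop = FALSE], rate = rec$rate,
            channel_ids = rec$channel_ids, units_state = rec$units_state)
}

#' Write a metrics table as delimited text
#'
#' @param df a data.frame of evaluation results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
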