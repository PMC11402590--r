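# End-to-end pipeline commands: train (classifier + HMM smoother + detector
# tuning -> model archive), process (raw CSV -> epoch predictions, steps,
# minute series, daily summary), evaluate (grouped stratified k-fold CV or a
# fixed archive). These back the command-line interface in inst/cli.

pkg_version <- function() as.character(utils::packageVersion("wriststep"))

md5_of <- function(path) unname(tools::md5sum(path))

hash_config <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), tmp)
  md5_of(tmp)
}

log_run <- function(cmd, seed, config, inputs = character(0)) {
  message(sprintf("[wriststep %s] %s: seed=%s config=%s", pkg_version(), cmd,
                  seed, hash_config(config)))
  for (f in inputs) message(sprintf("  input %s md5=%s", basename(f), md5_of(f)))
}

#' Save a trained pipeline as a plain-text model archive
#'
#' The archive is a JSON file holding the classifier coefficients (or the
#' base64-encoded raw booster for the xgboost backend), the HMM smoother
#' matrices, the tuned detector parameters, and the run configuration.
#'
#' @param model a fitted `walk_model`.
#' @param hmm an [hmm_params()] object.
#' @param detector a [detector_params()] object.
#' @param path output file path.
#' @param seed the training seed (stored for provenance).
#' @return the path, invisibly.
#' @export
save_model_archive <- function(model, hmm, detector, path, seed = NA_integer_) {
  arc <- list(
    format = "wriststep-model", version = 1L, package = pkg_version(),
    seed = seed,
    backend = model$backend,
    sample_rate_hz = model$sample_rate_hz,
    epoch_length_s = model$epoch_length_s,
    feature_names = model$feature_names,
    coefficients = as.list(model$coefficients),
    xgb_raw_b64 = if (!is.null(model$xgb_raw))
      jsonlite::base64_enc(model$xgb_raw),
    best_iteration = model$best_iteration,
    config = list(val_fraction = model$config$val_fraction,
                  patience_epochs = model$config$patience_epochs,
                  target_class_balance = as.list(model$config$target_class_balance),
                  learning_rate = model$config$learning_rate),
    hmm = list(initial = hmm$initial,
               transition = as.vector(hmm$transition),
               emission = as.vector(hmm$emission)),
    detector = list(prominence_g = detector$prominence_g,
                    distance_s = detector$distance_s,
                    width_s = detector$width_s,
                    width_mode = detector$width_mode)
  )
  write_atomic(function(tmp)
    jsonlite::write_json(arc, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null"), path)
}

#' Load a model archive
#'
#' @param path archive path written by [save_model_archive()].
#' @return a list with `model` (`walk_model`), `hmm` ([hmm_params()]),
#'   `detector` ([detector_params()]) and the stored metadata.
#' @export
load_model_archive <- function(path) {
  arc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(arc$format, "wriststep-model"))
    stop("not a wriststep model archive: ", path)
  cfg <- train_config(val_fraction = arc$config$val_fraction,
                      patience_epochs = arc$config$patience_epochs,
                      target_class_balance = unlist(arc$config$target_class_balance),
                      learning_rate = arc$config$learning_rate)
  model <- structure(list(
    backend = arc$backend,
    feature_names = arc$feature_names,
    sample_rate_hz = arc$sample_rate_hz,
    epoch_length_s = arc$epoch_length_s,
    config = cfg, classes = walk_levels,
    coefficients = unlist(arc$coefficients),
    best_iteration = arc$best_iteration,
    xgb_raw = if (!is.null(arc$xgb_raw_b64) && !is.na(arc$xgb_raw_b64[1]))
      jsonlite::base64_dec(arc$xgb_raw_b64)
  ), class = "walk_model")
  list(model = model,
       hmm = hmm_params(arc$hmm$initial, matrix(arc$hmm$transition, 2, 2),
                        matrix(arc$hmm$emission, 2, 2)),
       detector = suppressWarnings(
         detector_params(arc$detector$prominence_g, arc$detector$distance_s,
                         arc$detector$width_s, arc$detector$width_mode)),
       seed = arc$seed, package = arc$package)
}

# --- cohort IO ---------------------------------------------------------------

# A cohort directory holds <id>.csv recordings plus <id>_steps.csv truth
# files (written by make_fixture_cohort, or supplied by the user in the same
# dialect).
read_cohort <- function(dir, sample_rate_hz = NULL, require_steps = TRUE) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  rec_files <- files[!grepl("_(steps|labels|wear)\\.csv$", files)]
  if (!length(rec_files)) stop("no recording CSVs found in ", dir)
  cohort <- lapply(rec_files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    rec <- read_recording(f, participant_id = id)
    if (!is.null(sample_rate_hz))
      rec <- resample_recording(rec, sample_rate_hz)
    sf <- file.path(dir, paste0(id, "_steps.csv"))
    steps <- NULL
    if (file.exists(sf)) steps <- data.table::fread(sf)$time_s
    else if (require_steps)
      stop("missing step annotation file: ", basename(sf))
    list(id = id, recording = rec, truth_steps = steps, file = f)
  })
  names(cohort) <- vapply(cohort, `[[`, "", "id")
  cohort
}

# Labelled epoch set of one cohort entry.
cohort_epochs <- function(entry, epoch_length_s = 10) {
  ep <- epoch_split(entry$recording, epoch_length_s)
  if (!is.null(entry$truth_steps))
    ep$labels <- label_epochs_from_steps(entry$truth_steps, ep)
  ep
}

# Detector-tuning items from ground truth: one item per maximal run of true
# walking epochs (conditioned VM of the run, true step count inside it).
tuning_items <- function(entry, labels, epoch_length_s = 10) {
  rec <- entry$recording
  fs <- rec$sample_rate_hz
  n_per <- round(epoch_length_s * fs)
  runs <- label_runs(labels == "walk")
  runs <- runs[runs$value, , drop = FALSE]
  items <- list()
  for (r in seq_len(nrow(runs))) {
    s0 <- (runs$start[r] - 1L) * n_per + 1L
    s1 <- runs$end[r] * n_per
    t0 <- (s0 - 1L) / fs
    t1 <- s1 / fs
    items[[length(items) + 1L]] <- list(
      vm = conditioned_vm(rec$samples[s0:s1, , drop = FALSE], fs),
      sample_rate_hz = fs,
      true_count = sum(entry$truth_steps >= t0 & entry$truth_steps < t1))
  }
  items
}

# Viterbi smoothing restarted across nonwear gaps: nonwear epochs are forced
# to nonwalk and each worn segment is decoded independently.
smooth_labels <- function(hmm, labels, nonwear_epochs = NULL) {
  labels <- as_walk_label(labels)
  if (is.null(nonwear_epochs) || !any(nonwear_epochs))
    return(viterbi_smooth(hmm, labels))
  out <- as_walk_label(rep("nonwalk", length(labels)))
  segs <- label_runs(!nonwear_epochs)
  segs <- segs[segs$value, , drop = FALSE]
  for (r in seq_len(nrow(segs))) {
    idx <- segs$start[r]:segs$end[r]
    out[idx] <- viterbi_smooth(hmm, labels[idx])
  }
  out
}

# --- train -------------------------------------------------------------------

#' Train the full pipeline on an annotated cohort
#'
#' Reads a cohort directory of recordings with step annotations, trains the
#' walk classifier with a grouped 80/20 training-validation split, fits the
#' HMM smoother on the validation predictions, tunes the step detector on the
#' validation participants' true walking runs, and writes everything to a
#' model archive.
#'
#' @param cohort_dir directory with `<id>.csv` and `<id>_steps.csv` files.
#' @param out_path archive path to write.
#' @param backend classifier backend (see [train_classifier()]).
#' @param seed integer seed controlling all randomness of the run.
#' @param sample_rate_hz rate all recordings are resampled to (default 25).
#' @param epoch_length_s epoch length in seconds (default 10).
#' @param config a [train_config()].
#' @param grid detector tuning grid (default [default_detector_grid()]).
#' @return the archive path, invisibly.
#' @export
cmd_train <- function(cohort_dir, out_path, backend = "logistic", seed = 1L,
                      sample_rate_hz = 25, epoch_length_s = 10,
                      config = train_config(), grid = default_detector_grid()) {
  cohort <- read_cohort(cohort_dir, sample_rate_hz)
  if (length(cohort) < 2L)
    stop("training error: grouped split impossible with a single participant")
  log_run("train", seed, list(backend = backend, fs = sample_rate_hz,
                              epoch = epoch_length_s),
          vapply(cohort, `[[`, "", "file"))
  set.seed(seed)
  epochs <- combine_epoch_sets(lapply(cohort, cohort_epochs,
                                      epoch_length_s = epoch_length_s))
  model <- train_classifier(epochs, config, backend = backend)

  val <- model$validation
  ord <- order(val$group_id, val$start_s)
  val <- val[ord, ]
  hmm <- fit_hmm(split(val$truth, val$group_id),
                 split(val$pred, val$group_id))

  items <- list()
  for (id in model$split$val) {
    ep <- cohort_epochs(cohort[[id]], epoch_length_s)
    items <- c(items, tuning_items(cohort[[id]], ep$labels, epoch_length_s))
  }
  detector <- tune_detector(items, grid)

  save_model_archive(model, hmm, detector, out_path, seed = seed)
  message(sprintf("  archive written: %s (detector: prom %.2g g, dist %.2g s, width %.2g s; val MAE %.2f)",
                  out_path, detector$prominence_g, detector$distance_s,
                  detector$width_s, attr(detector, "mae")))
  invisible(out_path)
}

# --- process -----------------------------------------------------------------

#' Process one raw recording into step counts and daily summaries
#'
#' The full inference pipeline: read, resample to the model's rate, epoch,
#' classify, HMM-smooth (restarting across nonwear gaps), detect steps on
#' predicted walking runs, bin to minutes with the nonwear mask, impute
#' nonwear from the same time of day, and summarise. All outputs are written
#' atomically; QC failures set flags in the summary rather than aborting.
#'
#' @param input_csv recording CSV (`time,x,y,z`, units g).
#' @param model_path model archive from [cmd_train()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (the inference path is deterministic; the seed is
#'   logged and reserved for stochastic backends).
#' @return a list with the epoch predictions, step events, minute series and
#'   `daily_summary`, invisibly.
#' @export
cmd_process <- function(input_csv, model_path, out_dir, seed = 1L) {
  if (!file.exists(input_csv)) stop("unreadable input: ", input_csv)
  arc <- load_model_archive(model_path)
  log_run("process", seed, list(model = basename(model_path)), input_csv)
  set.seed(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  rec <- read_recording(input_csv)
  rec <- resample_recording(rec, arc$model$sample_rate_hz)
  len <- arc$model$epoch_length_s
  epochs <- epoch_split(rec, len)
  preds <- predict_epochs(arc$model, epochs)

  worn_min <- detect_nonwear(rec)
  ep_nonwear <- epoch_in_nonwear(epochs, worn_min, len)
  smoothed <- smooth_labels(arc$hmm, preds$label, ep_nonwear)
  steps <- detect_steps(rec, smoothed, arc$detector, epoch_length_s = len)

  day0 <- floor(rec$start_time / 86400) * 86400
  n_days <- max(1L, ceiling((rec$start_time + duration_s(rec) - day0) / 86400))
  worn_mat <- matrix(FALSE, n_days, 1440)
  first_min <- floor((rec$start_time - day0) / 60)
  rec_minutes <- first_min + seq_len(max(
    length(worn_min), ceiling(duration_s(rec) / 60))) - 1L
  rec_worn <- c(worn_min, rep(TRUE, length(rec_minutes) - length(worn_min)))
  keep <- rec_minutes < n_days * 1440
  worn_mat[cbind(rec_minutes[keep] %/% 1440 + 1L,
                 rec_minutes[keep] %% 1440 + 1L)] <- rec_worn[keep]
  series <- steps_per_minute(steps, rec$start_time, n_days, worn = worn_mat)
  mean_acc <- mean(abs(vector_magnitude(rec$samples))) * 1000
  summ <- daily_summary(series, mean_acceleration_mg = mean_acc)
  imp <- impute_nonwear(series)

  write_atomic(function(tmp) data.table::fwrite(data.table::data.table(
    epoch_index = seq_len(n_epochs(epochs)), start_s = epochs$start_s,
    prob = preds$prob, label_raw = as.character(preds$label),
    label_smoothed = as.character(smoothed)), tmp),
    file.path(out_dir, "epochs.csv"))
  write_atomic(function(tmp) data.table::fwrite(as.data.frame(steps), tmp),
               file.path(out_dir, "steps.csv"))
  write_atomic(function(tmp) data.table::fwrite(data.table::data.table(
    day = rep(seq_len(n_days), each = 1440),
    minute_of_day = rep(0:1439, n_days),
    steps = as.vector(t(imp$counts)),
    worn = as.vector(t(imp$worn)),
    imputed = as.vector(t(imp$imputed))), tmp),
    file.path(out_dir, "minutes.csv"))
  write_atomic(function(tmp) jsonlite::write_json(list(
    median_daily_steps = summ$median_daily_steps,
    peak_1min_cadence = summ$peak_1min_cadence,
    total_steps = nrow(steps),
    daily_steps = summ$daily_steps,
    wear_hours = summ$wear_hours,
    mean_acceleration_mg = mean_acc,
    qc_flags = as.list(summ$qc_flags)), tmp,
    auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(out_dir, "summary.json"))

  invisible(list(predictions = preds, smoothed = smoothed, steps = steps,
                 minutes = imp, summary = summ))
}

# Epochs lying wholly inside nonwear minutes.
epoch_in_nonwear <- function(epochs, worn_min, epoch_length_s) {
  if (!length(worn_min)) return(rep(FALSE, n_epochs(epochs)))
  vapply(seq_len(n_epochs(epochs)), function(i) {
    m0 <- floor(epochs$start_s[i] / 60) + 1L
    m1 <- floor((epochs$start_s[i] + epoch_length_s - 1e-9) / 60) + 1L
    ms <- m0:m1
    ms <- ms[ms <= length(worn_min)]
    length(ms) > 0L && all(!worn_min[ms])
  }, logical(1))
}

# --- evaluate ----------------------------------------------------------------

#' Evaluate the pipeline on an annotated cohort
#'
#' Either applies a fixed model archive to every participant, or (default)
#' runs grouped, stratified k-fold cross-validation: per fold the classifier
#' is trained, the HMM fitted and the detector tuned on the training
#' participants, then steps are counted for the held-out participants.
#' Reports participant-level step agreement and pooled epoch classification
#' quality of the smoothed predictions.
#'
#' @param cohort_dir directory with annotated recordings (see [cmd_train()]).
#' @param out_dir optional directory; when given, `evaluation.json` is
#'   written.
#' @param k number of CV folds (default 10); ignored when `model_path` is
#'   given.
#' @param model_path optional model archive to evaluate as-is.
#' @param seed integer seed.
#' @param sample_rate_hz,epoch_length_s,config,grid as in [cmd_train()].
#' @return a list with `agreement` ([agreement_report()]), `classification`
#'   ([classification_metrics()]) and the per-participant count table.
#' @export
cmd_evaluate <- function(cohort_dir, out_dir = NULL, k = 10L,
                         model_path = NULL, seed = 1L, sample_rate_hz = 25,
                         epoch_length_s = 10, config = train_config(),
                         grid = default_detector_grid()) {
  cohort <- read_cohort(cohort_dir, sample_rate_hz)
  log_run("evaluate", seed, list(k = k, fs = sample_rate_hz),
          vapply(cohort, `[[`, "", "file"))
  set.seed(seed)
  eps <- lapply(cohort, cohort_epochs, epoch_length_s = epoch_length_s)

  truth_all <- character(0); pred_all <- character(0)
  per_part <- data.frame(id = names(cohort),
                         true_steps = NA_real_, pred_steps = NA_real_)
  evaluate_participant <- function(id, model, hmm, detector) {
    ep <- eps[[id]]
    preds <- predict_epochs(model, ep)
    sm <- smooth_labels(hmm, preds$label)
    steps <- detect_steps(cohort[[id]]$recording, sm, detector,
                          epoch_length_s = epoch_length_s)
    list(smoothed = as.character(sm), truth = as.character(ep$labels),
         pred_steps = nrow(steps),
         true_steps = length(cohort[[id]]$truth_steps))
  }

  if (!is.null(model_path)) {
    arc <- load_model_archive(model_path)
    for (id in names(cohort)) {
      r <- evaluate_participant(id, arc$model, arc$hmm, arc$detector)
      truth_all <- c(truth_all, r$truth); pred_all <- c(pred_all, r$smoothed)
      per_part[per_part$id == id, c("true_steps", "pred_steps")] <-
        c(r$true_steps, r$pred_steps)
    }
  } else {
    if (k > length(cohort)) stop("parameter error: more folds than participants")
    combined <- combine_epoch_sets(eps)
    folds <- attr(grouped_stratified_kfold(combined, k), "participant_folds")
    for (f in sort(unique(folds))) {
      test_ids <- names(folds)[folds == f]
      train_ids <- setdiff(names(cohort), test_ids)
      set.seed(derive_seed(seed, paste0("fold", f)))
      tr_set <- combine_epoch_sets(eps[train_ids])
      model <- train_classifier(tr_set, config)
      val <- model$validation
      val <- val[order(val$group_id, val$start_s), ]
      hmm <- fit_hmm(split(val$truth, val$group_id),
                     split(val$pred, val$group_id))
      items <- list()
      for (id in model$split$val)
        items <- c(items, tuning_items(cohort[[id]], eps[[id]]$labels,
                                       epoch_length_s))
      detector <- tune_detector(items, grid)
      for (id in test_ids) {
        r <- evaluate_participant(id, model, hmm, detector)
        truth_all <- c(truth_all, r$truth); pred_all <- c(pred_all, r$smoothed)
        per_part[per_part$id == id, c("true_steps", "pred_steps")] <-
          c(r$true_steps, r$pred_steps)
      }
    }
  }

  agreement <- agreement_report(per_part$true_steps, per_part$pred_steps)
  classification <- classification_metrics(truth_all, pred_all)
  out <- list(agreement = agreement, classification = classification,
              per_participant = per_part)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_atomic(function(tmp) jsonlite::write_json(list(
      agreement = list(mape_percent = agreement$mape_percent,
                       mean_bias_percent = agreement$mean_bias_percent,
                       spearman_rho = agreement$spearman_rho,
                       bland_altman = agreement$bland_altman,
                       n_subjects = agreement$n_subjects),
      classification = list(precision = classification$precision,
                            recall = classification$recall,
                            f1 = classification$f1,
                            accuracy = classification$accuracy,
                            cohens_kappa = classification$cohens_kappa),
      per_participant = per_part), tmp,
      auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, "evaluation.json"))
  }
  invisible(out)
}
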