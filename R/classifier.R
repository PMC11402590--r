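# Walk / non-walk epoch classification: ground-truth labelling from step
# annotations, rotation/permutation augmentation, hand-crafted VM features,
# trainable backends with class reweighting, and grouped stratified k-fold
# assignment.

#' Label epochs from ground-truth step times
#'
#' An epoch is labelled `walk` iff at least `min_steps` (default 4) annotated
#' steps fall inside it (`epoch_start <= t < epoch_end`).
#'
#' @param step_times numeric step timestamps in seconds relative to the
#'   recording start (or a [step_events()] object).
#' @param epochs an `epoch_set` from a single recording (contiguous epochs).
#' @param min_steps minimum step count defining a walking epoch.
#' @return factor of labels with levels `nonwalk`, `walk`.
#' @export
label_epochs_from_steps <- function(step_times, epochs, min_steps = 4L) {
  if (inherits(step_times, "step_events")) step_times <- step_times$time_s
  n <- n_epochs(epochs)
  if (!n) return(as_walk_label(character(0)))
  len <- epochs$epoch_length_s
  counts <- vapply(seq_len(n), function(i) {
    s <- epochs$start_s[i]
    sum(step_times >= s & step_times < s + len)
  }, numeric(1))
  as_walk_label(counts >= min_steps)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; right-handed rotation by `angle` radians about the
#' (normalised) `axis`.
#'
#' @param axis length-3 numeric axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * tcrossprod(u)
}

#' Randomly rotate and axis-permute an epoch
#'
#' Training-time augmentation: a rotation by a uniform random angle about a
#' uniformly random axis is applied to every sample, then a single random
#' permutation of the three axes is applied to the whole window. Both
#' operations are isometries, so per-sample Euclidean norms (and hence all
#' vector-magnitude features) are preserved.
#'
#' @param epoch numeric matrix of triaxial samples (rows = samples).
#' @return the transformed matrix, same dimensions.
#' @export
augment_epoch <- function(epoch) {
  axis <- stats::rnorm(3)
  angle <- stats::runif(1, 0, 2 * pi)
  perm <- sample(3L)
  (as.matrix(epoch) %*% t(rotation_matrix(axis, angle)))[, perm, drop = FALSE]
}

#' Hand-crafted features of one epoch
#'
#' A deterministic, rotation-invariant feature vector computed from the
#' conditioned vector magnitude of the window: moments and quantiles,
#' dominant frequency and band power in the 0.5-4 Hz gait band, spectral
#' entropy, the autocorrelation peak in the 0.3-1.2 s lag band, zero-crossing
#' rate, and the number of prominent peaks (a direct step-count proxy).
#' Degenerate all-zero windows map to all-zero features.
#'
#' @param epoch numeric matrix of triaxial samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @return a named numeric feature vector.
#' @export
extract_features <- function(epoch, sample_rate_hz) {
  fs <- sample_rate_hz
  vm <- conditioned_vm(epoch, fs)
  n <- length(vm)
  qs <- stats::quantile(vm, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  sdv <- stats::sd(vm)

  centred <- vm - mean(vm)
  pw <- Mod(stats::fft(centred))^2
  half <- seq(2L, floor(n / 2) + 1L)            # positive frequencies
  freqs <- (half - 1L) * fs / n
  pw <- pw[half]
  total_power <- sum(pw)
  band <- freqs >= 0.5 & freqs <= 4
  # power below numerical noise counts as a degenerate (constant) window
  if (total_power > 1e-12 && any(band)) {
    dom_freq <- freqs[band][which.max(pw[band])]
    band_frac <- sum(pw[band]) / total_power
    p_norm <- pw / total_power
    p_norm <- p_norm[p_norm > 0]
    spec_entropy <- -sum(p_norm * log(p_norm)) / log(length(pw))
  } else {
    dom_freq <- 0; band_frac <- 0; spec_entropy <- 0
  }

  ac_peak <- 0
  if (sdv > 1e-9) {
    lag_max <- min(n - 1L, ceiling(1.2 * fs))
    ac <- as.numeric(stats::acf(vm, lag.max = lag_max, plot = FALSE,
                                demean = TRUE)$acf)
    lags <- (seq_along(ac) - 1L) / fs
    in_band <- lags >= 0.3 & lags <= 1.2
    if (any(in_band)) ac_peak <- max(ac[in_band])
  }

  zcr <- if (n > 1L) mean(vm[-1] * vm[-n] < 0) else 0
  n_pk <- length(find_peaks_1d(vm, fs,
                               suppressWarnings(detector_params(0.1, 0.25, 1))))

  out <- c(vm_mean = mean(vm), vm_sd = sdv, vm_q10 = qs[1], vm_q25 = qs[2],
           vm_q50 = qs[3], vm_q75 = qs[4], vm_q90 = qs[5],
           dom_freq_hz = dom_freq, band_power_frac = band_frac,
           spec_entropy = spec_entropy, ac_peak = ac_peak, zcr = zcr,
           n_peaks = n_pk)
  out[!is.finite(out)] <- 0
  out
}

# Feature matrix for all epochs of a set; optionally augment each window
# first (training passes only).
epoch_features <- function(epochs, augment = FALSE) {
  n <- n_epochs(epochs)
  if (!n) return(matrix(0, 0, 13))
  rows <- lapply(seq_len(n), function(i) {
    w <- epochs$samples[i, , ]
    if (augment) w <- augment_epoch(w)
    extract_features(w, epochs$sample_rate_hz)
  })
  do.call(rbind, rows)
}

#' Training configuration
#'
#' @param val_fraction fraction of epochs held out (grouped by participant)
#'   as the internal validation set (default 0.20, i.e. an 80/20 split).
#' @param patience_epochs early-stopping patience for iterative backends:
#'   training stops when validation loss has not decreased for this many
#'   consecutive rounds (default 5); the best-validation-loss state is kept.
#' @param target_class_balance target walk/nonwalk balance the class weights
#'   rescale the empirical frequencies to (default walk 0.10, nonwalk 0.90).
#' @param learning_rate learning rate for iterative backends (default 1e-4;
#'   ignored by the closed-form logistic backend).
#' @param seed optional integer seed applied at the start of training.
#' @return an object of class `train_config`.
#' @export
train_config <- function(val_fraction = 0.2, patience_epochs = 5L,
                         target_class_balance = c(walk = 0.1, nonwalk = 0.9),
                         learning_rate = 1e-4, seed = NULL) {
  stopifnot(val_fraction > 0, val_fraction < 1, patience_epochs >= 1)
  if (abs(sum(target_class_balance) - 1) > 1e-8)
    stop("target_class_balance must sum to 1")
  if (!all(c("walk", "nonwalk") %in% names(target_class_balance)))
    stop("target_class_balance needs named 'walk' and 'nonwalk' entries")
  structure(list(val_fraction = val_fraction,
                 patience_epochs = as.integer(patience_epochs),
                 target_class_balance = target_class_balance,
                 learning_rate = learning_rate, seed = seed),
            class = "train_config")
}

#' Class-rebalancing observation weights
#'
#' Weights proportional to `target_balance[class] / empirical_freq[class]`,
#' normalised to mean 1, so the weighted class contributions match the target
#' 10/90 walk/nonwalk balance regardless of the empirical balance.
#'
#' @param labels walk/nonwalk labels.
#' @param target named target balance (walk, nonwalk).
#' @return numeric weight per observation.
#' @export
class_weights <- function(labels, target = c(walk = 0.1, nonwalk = 0.9)) {
  labels <- as_walk_label(labels)
  emp <- prop.table(table(labels))
  if (any(emp == 0)) stop("training error: both classes must be present")
  w_class <- c(nonwalk = unname(target["nonwalk"] / emp["nonwalk"]),
               walk = unname(target["walk"] / emp["walk"]))
  w <- w_class[as.character(labels)]
  unname(w / mean(w))
}

# Grouped holdout: participants are shuffled and moved into the validation
# side until it holds ~val_fraction of the epochs; both sides keep >= 1
# participant.
grouped_holdout <- function(group_ids, val_fraction) {
  parts <- sample(unique(group_ids))
  if (length(parts) < 2L)
    stop("training error: grouped split impossible with a single participant")
  sizes <- table(group_ids)[parts]
  target <- val_fraction * length(group_ids)
  cum <- cumsum(sizes)
  n_val <- max(1L, sum(cum <= target))
  n_val <- min(n_val, length(parts) - 1L)
  list(val = parts[seq_len(n_val)], train = parts[-seq_len(n_val)])
}

#' Train the walk classifier
#'
#' Splits the labelled epochs 80/20 into training and validation sets grouped
#' by participant, augments each training window once (random rotation + axis
#' permutation), reweights classes to the target 10/90 balance, and fits the
#' requested backend. Validation-set predictions are recorded in the returned
#' model: they are the training data of the HMM smoother and of detector
#' tuning.
#'
#' Backends: `"logistic"` (default) is a ridge-penalised logistic regression
#' (glmnet) on the hand-crafted features -- deterministic and closed-form, so
#' early stopping does not apply; `"xgboost"` is a gradient-boosted tree
#' backend trained with early stopping at `patience_epochs` rounds (requires
#' the xgboost package).
#'
#' @param epochs a labelled `epoch_set` containing both classes.
#' @param config a [train_config()].
#' @param backend `"logistic"` or `"xgboost"`.
#' @param augment apply rotation/permutation augmentation to training windows.
#' @return an object of class `walk_model` with recorded validation
#'   predictions in `$validation`.
#' @export
train_classifier <- function(epochs, config = train_config(),
                             backend = c("logistic", "xgboost"),
                             augment = TRUE) {
  backend <- match.arg(backend)
  if (is.null(epochs$labels)) stop("training error: epochs must be labelled")
  if (length(unique(epochs$labels)) < 2L)
    stop("training error: both classes must be present")
  if (!is.null(config$seed)) set.seed(config$seed)

  split <- grouped_holdout(epochs$group_ids, config$val_fraction)
  tr_idx <- which(epochs$group_ids %in% split$train)
  va_idx <- which(epochs$group_ids %in% split$val)
  if (length(unique(epochs$labels[tr_idx])) < 2L)
    stop("training error: training side of the split lost a class; ",
         "use more participants")

  x_tr <- epoch_features(subset_epochs(epochs, tr_idx), augment = augment)
  x_va <- epoch_features(subset_epochs(epochs, va_idx), augment = FALSE)
  y_tr <- epochs$labels[tr_idx]
  y_va <- epochs$labels[va_idx]
  w_tr <- class_weights(y_tr, config$target_class_balance)

  model <- list(backend = backend, feature_names = colnames(x_tr),
                sample_rate_hz = epochs$sample_rate_hz,
                epoch_length_s = epochs$epoch_length_s,
                config = config, classes = walk_levels)

  if (backend == "logistic") {
    fit <- glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 0,
                          lambda = 1e-3, weights = w_tr, standardize = TRUE)
    cf <- as.numeric(stats::coef(fit))
    names(cf) <- c("(Intercept)", colnames(x_tr))
    model$coefficients <- cf
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("backend 'xgboost' requires the xgboost package")
    dtr <- xgboost::xgb.DMatrix(x_tr, label = as.integer(y_tr == "walk"),
                                weight = w_tr)
    dva <- xgboost::xgb.DMatrix(x_va, label = as.integer(y_va == "walk"))
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1, max_depth = 4,
                    nthread = 1),
      data = dtr, nrounds = 300, evals = list(val = dva),
      early_stopping_rounds = config$patience_epochs, verbose = 0
    )
    model$xgb_raw <- xgboost::xgb.save.raw(fit)
    model$best_iteration <- as.integer(xgboost::xgb.attributes(fit)$best_iteration)
  }
  class(model) <- "walk_model"

  va_prob <- predict_features(model, x_va)
  model$validation <- data.frame(
    group_id = epochs$group_ids[va_idx],
    start_s = epochs$start_s[va_idx],
    truth = y_va,
    prob = va_prob,
    pred = as_walk_label(va_prob >= 0.5),
    stringsAsFactors = FALSE
  )
  model$split <- split
  model
}

# Predicted walk probability from a feature matrix.
predict_features <- function(model, x) {
  if (model$backend == "logistic") {
    cf <- model$coefficients
    as.numeric(stats::plogis(cf[1] + x %*% cf[-1]))
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("backend 'xgboost' requires the xgboost package")
    fit <- xgboost::xgb.load.raw(model$xgb_raw)
    bi <- model$best_iteration
    if (length(bi) == 1L && is.finite(bi) && bi > 0)
      # use only the rounds up to the best validation loss (early stopping)
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x),
                                iterationrange = c(1, bi + 1)))
    else as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x)))
  }
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf("<walk_model> backend %s, %d features, trained at %.6g Hz\n",
              x$backend, length(x$feature_names), x$sample_rate_hz))
  invisible(x)
}

#' Predict walk probabilities for epochs
#'
#' Deterministic given the fitted model: returns the walk probability and the
#' hard label (`prob >= 0.5`) for every epoch.
#'
#' @param model a fitted `walk_model`.
#' @param epochs an `epoch_set` at the model's sample rate.
#' @return a data.frame with columns `group_id`, `start_s`, `prob`, `label`.
#' @export
predict_epochs <- function(model, epochs) {
  if (!inherits(model, "walk_model")) stop("state error: model is not fitted")
  x <- epoch_features(epochs, augment = FALSE)
  prob <- if (n_epochs(epochs)) predict_features(model, x) else numeric(0)
  data.frame(group_id = epochs$group_ids, start_s = epochs$start_s,
             prob = prob, label = as_walk_label(prob >= 0.5),
             stringsAsFactors = FALSE)
}

#' Grouped, stratified k-fold assignment
#'
#' Partitions participants into `k` folds so that all epochs of one
#' participant share one fold, fold sizes stay within one participant of
#' equal, and the per-fold walking-epoch proportion greedily tracks the
#' global proportion. Participants are processed by descending epoch count
#' (ties shuffled by the current RNG) and each is assigned, among the folds
#' with the fewest participants, to the one whose walking fraction after
#' assignment deviates least from the global fraction.
#'
#' @param epochs a labelled `epoch_set`.
#' @param k number of folds (default 10).
#' @return integer fold index (1..k) per epoch, with the per-participant map
#'   in attribute `"participant_folds"`.
#' @export
grouped_stratified_kfold <- function(epochs, k = 10L) {
  if (is.null(epochs$labels)) stop("epochs must be labelled for stratification")
  parts <- unique(epochs$group_ids)
  if (length(parts) < k)
    stop("parameter error: fewer participants than folds")
  n_ep <- table(epochs$group_ids)[parts]
  n_wk <- vapply(parts, function(p)
    sum(epochs$labels[epochs$group_ids == p] == "walk"), numeric(1))
  ord <- order(-as.numeric(n_ep), sample(length(parts)))
  g_frac <- mean(epochs$labels == "walk")

  fold_parts <- integer(k); fold_ep <- numeric(k); fold_wk <- numeric(k)
  assign_to <- setNames(integer(length(parts)), parts)
  for (i in ord) {
    eligible <- which(fold_parts == min(fold_parts))
    dev <- (fold_wk[eligible] + n_wk[i]) / (fold_ep[eligible] + n_ep[i]) - g_frac
    sel <- eligible[order(abs(dev), fold_ep[eligible], eligible)][1]
    assign_to[parts[i]] <- sel
    fold_parts[sel] <- fold_parts[sel] + 1L
    fold_ep[sel] <- fold_ep[sel] + n_ep[i]
    fold_wk[sel] <- fold_wk[sel] + n_wk[i]
  }
  out <- assign_to[epochs$group_ids]
  attr(out, "participant_folds") <- assign_to
  out
}
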