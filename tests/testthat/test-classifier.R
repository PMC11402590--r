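make_epochs <- function(n_ep = 3, fs = 25, len = 10, id = "P01") {
  epoch_set(array(0, c(n_ep, round(fs * len), 3)), fs, len,
            group_ids = rep(id, n_ep), start_s = (seq_len(n_ep) - 1) * len)
}

test_that("epochs are walking iff they contain at least four steps", {
  ep <- make_epochs(3)
  # epoch 1: 3 steps; epoch 2: 4 steps; epoch 3: none
  steps <- c(1, 2, 3, 10.0, 12, 15, 19.99)
  expect_equal(as.character(label_epochs_from_steps(steps, ep)),
               c("nonwalk", "walk", "nonwalk"))
  # boundary is half-open: a step at exactly the epoch end belongs to the next
  expect_equal(as.character(label_epochs_from_steps(c(10, 11, 12, 13), ep))[2],
               "walk")
})

test_that("augmentation is an isometry and rotation matrices are exact", {
  expect_equal(rotation_matrix(c(0, 0, 1), pi / 2) %*% c(1, 0, 0),
               matrix(c(0, 1, 0)), tolerance = 1e-12)
  set.seed(8)
  w <- matrix(rnorm(750), ncol = 3)
  for (i in 1:5) {
    aug <- augment_epoch(w)
    expect_equal(rowSums(aug^2), rowSums(w^2), tolerance = 1e-9)
  }
})

test_that("features are deterministic, rotation invariant, and track frequency", {
  fs <- 25; t <- (0:249) / fs
  w <- cbind(0, 0, 1 + 0.3 * sin(2 * pi * 2 * t))
  f <- extract_features(w, fs)
  expect_equal(unname(f["dom_freq_hz"]), 2, tolerance = 1e-9)

  zero <- extract_features(matrix(0, 250, 3), fs)
  varying <- setdiff(names(zero), c("vm_mean", "vm_q10", "vm_q25", "vm_q50",
                                    "vm_q75", "vm_q90"))
  expect_lt(max(abs(zero[varying])), 1e-9)
  expect_equal(unname(zero["dom_freq_hz"]), 0)

  set.seed(9)
  R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
  w2 <- matrix(rnorm(750, sd = 0.3), ncol = 3)
  expect_equal(extract_features(w2, fs), extract_features(w2 %*% t(R), fs),
               tolerance = 1e-8)
})

test_that("class weights rescale the empirical balance to the 10/90 target", {
  # already at target: all weights 1
  lab <- c(rep("walk", 10), rep("nonwalk", 90))
  expect_equal(class_weights(lab), rep(1, 100))
  # 50/50 empirical: walk/nonwalk weight ratio 1/9
  lab <- c(rep("walk", 50), rep("nonwalk", 50))
  w <- class_weights(lab)
  expect_equal(w[1] / w[100], 1 / 9, tolerance = 1e-12)
  expect_equal(mean(w), 1)
  # total weighted class contribution ratio is invariant to duplicating the
  # majority class
  lab2 <- c(rep("walk", 50), rep("nonwalk", 100))
  w2 <- class_weights(lab2)
  ratio <- function(l, w) sum(w[l == "walk"]) / sum(w[l == "nonwalk"])
  expect_equal(ratio(lab, w), ratio(lab2, w2), tolerance = 1e-12)
  expect_error(class_weights(rep("walk", 5)), "both classes")
})

test_that("the classifier separates synthetic gait and predicts deterministically", {
  set.seed(11)
  recs <- lapply(1:6, function(i) {
    simulate_participant(list(
      list(kind = "sedentary", duration_s = 100),
      list(kind = "walk", duration_s = 100),
      list(kind = "fidget", duration_s = 100)),
      participant_id = sprintf("S%02d", i), seed = 100 + i)
  })
  eps <- combine_epoch_sets(lapply(recs, function(sr) {
    ep <- epoch_split(sr$recording)
    ep$labels <- sr$truth_labels
    ep
  }))
  model <- train_classifier(eps, train_config(seed = 1))
  # held-out validation predictions are recorded and accurate
  val <- model$validation
  expect_true(nrow(val) > 0)
  km <- classification_metrics(val$truth, val$pred)
  expect_gte(km$cohens_kappa, 0.9)
  # prediction is pure: identical across repeated calls, probabilities valid
  p1 <- predict_epochs(model, eps)
  p2 <- predict_epochs(model, eps)
  expect_identical(p1, p2)
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_equal(as.character(p1$label),
               ifelse(p1$prob >= 0.5, "walk", "nonwalk"))
  # training labels essentially recovered on this separable set
  expect_gte(classification_metrics(eps$labels, p1$label)$cohens_kappa, 0.9)
})

test_that("the gradient-boosted backend trains with early stopping", {
  skip_if_not_installed("xgboost")
  set.seed(13)
  recs <- lapply(1:4, function(i) {
    simulate_participant(list(
      list(kind = "sedentary", duration_s = 100),
      list(kind = "walk", duration_s = 100)),
      participant_id = sprintf("X%02d", i), seed = 200 + i)
  })
  eps <- combine_epoch_sets(lapply(recs, function(sr) {
    ep <- epoch_split(sr$recording)
    ep$labels <- sr$truth_labels
    ep
  }))
  m <- train_classifier(eps, train_config(seed = 2), backend = "xgboost")
  expect_true(is.integer(m$best_iteration) && m$best_iteration >= 1L)
  p <- predict_epochs(m, eps)
  expect_gte(classification_metrics(eps$labels, p$label)$cohens_kappa, 0.9)
  # archive round trip reproduces probabilities exactly
  f <- tempfile(fileext = ".json")
  save_model_archive(m, fit_hmm(list(m$validation$truth),
                                list(m$validation$pred)),
                     detector_params(0.2, 0.4, 1), f)
  expect_identical(predict_epochs(load_model_archive(f)$model, eps)$prob,
                   p$prob)
})

test_that("training requires both classes", {
  ep <- make_epochs(4)
  ep$labels <- as_walk_label(rep("nonwalk", 4))
  expect_error(train_classifier(ep), "both classes")
})

test_that("grouped stratified folds partition participants and balance walk fraction", {
  # 10 participants, k = 10: one per fold
  set.seed(12)
  labs <- setNames(lapply(1:10, function(i)
    rep(c("walk", "nonwalk"), c(3, 7))), sprintf("P%02d", 1:10))
  ep <- label_only_epochs(labs)
  f <- grouped_stratified_kfold(ep, 10)
  pf <- attr(f, "participant_folds")
  expect_equal(sort(unname(pf)), 1:10)
  # all epochs of a participant share a fold
  expect_true(all(tapply(f, ep$group_ids, function(x) length(unique(x))) == 1))

  # 20 participants with alternating walk fractions 0.1 / 0.5
  labs2 <- setNames(lapply(1:20, function(i) {
    nw <- if (i %% 2) 1 else 5
    rep(c("walk", "nonwalk"), c(nw, 10 - nw))
  }), sprintf("Q%02d", 1:20))
  ep2 <- label_only_epochs(labs2)
  f2 <- grouped_stratified_kfold(ep2, 10)
  g <- mean(ep2$labels == "walk")
  fr <- tapply(ep2$labels == "walk", f2, mean)
  expect_true(all(abs(fr - g) <= 0.1))
  pf2 <- attr(f2, "participant_folds")
  expect_true(all(table(pf2) == 2))
  expect_error(grouped_stratified_kfold(ep, 11), "fewer participants")
})
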