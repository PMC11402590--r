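# Shared synthetic fixtures, generated once per test run and cached in the
# session tempdir so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

shared_cohort_dir <- function(n = 4, seed = 42) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    dir <- file.path(tempdir(), paste0("ws_", key))
    if (!dir.exists(dir))
      make_fixture_cohort(n, "oxwalk_like", seed = seed, dir = dir)
    .fixtures[[key]] <- dir
  }
  .fixtures[[key]]
}

shared_model_archive <- function() {
  if (is.null(.fixtures$archive)) {
    arc <- file.path(tempdir(), "ws_model.json")
    if (!file.exists(arc))
      suppressMessages(cmd_train(shared_cohort_dir(), arc, seed = 3))
    .fixtures$archive <- arc
  }
  .fixtures$archive
}

plan_week_for_test <- function(days) {
  set.seed(4242)
  wriststep:::plan_week(days)
}

# A small epoch set with given per-participant labels and trivial samples,
# for fold-assignment tests that do not touch the signal path.
label_only_epochs <- function(labels_per_participant, fs = 25, len = 10) {
  n_per <- round(fs * len)
  n_tot <- sum(lengths(labels_per_participant))
  epoch_set(array(0, c(n_tot, n_per, 3)), fs, len,
            group_ids = rep(names(labels_per_participant),
                            lengths(labels_per_participant)),
            start_s = unlist(lapply(labels_per_participant, function(l)
              (seq_along(l) - 1) * len)),
            labels = unlist(lapply(labels_per_participant, as.character)))
}
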