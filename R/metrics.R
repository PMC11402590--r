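# Validation metrics: step-count agreement at the participant level (MAPE,
# signed percent bias, Spearman correlation, Bland-Altman limits of
# agreement) and epoch classification quality (precision, recall, F1,
# accuracy, Cohen's kappa).

check_counts <- function(true_counts, pred_counts) {
  stopifnot(length(true_counts) == length(pred_counts))
  bad <- !(true_counts > 0)
  if (any(bad)) {
    warning(sprintf("%d subject(s) with zero/negative true count excluded",
                    sum(bad)))
    true_counts <- true_counts[!bad]
    pred_counts <- pred_counts[!bad]
  }
  if (!length(true_counts))
    stop("undefined: no subjects with positive true counts")
  list(true = true_counts, pred = pred_counts)
}

#' Mean absolute percent error (per subject)
#'
#' `mean(|pred - true| / true) * 100`, averaged over subjects. Subjects with
#' a non-positive true count are excluded with a warning.
#'
#' @param true_counts,pred_counts aligned per-subject step counts.
#' @return MAPE in percent.
#' @export
mape <- function(true_counts, pred_counts) {
  d <- check_counts(true_counts, pred_counts)
  mean(abs(d$pred - d$true) / d$true) * 100
}

#' Mean signed percent bias (per subject)
#'
#' `mean((pred - true) / true) * 100`; negative values indicate
#' undercounting.
#'
#' @inheritParams mape
#' @return signed percent bias.
#' @export
mean_bias_percent <- function(true_counts, pred_counts) {
  d <- check_counts(true_counts, pred_counts)
  mean((d$pred - d$true) / d$true) * 100
}

#' Spearman's rank correlation
#'
#' Pearson correlation of ranks with average ranks on ties.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("spearman_rho requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined: constant input vector")
  stats::cor(x, y, method = "spearman")
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = pred - true`; returns the mean difference and the 95%
#' limits of agreement `mean(d) +/- 1.96 * sd(d)` (sample SD, n - 1; no
#' small-sample t correction).
#'
#' @inheritParams mape
#' @return a list with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(true_counts, pred_counts) {
  stopifnot(length(true_counts) == length(pred_counts),
            length(true_counts) >= 2L)
  d <- pred_counts - true_counts
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_diff = s)
}

#' Bland-Altman plot
#'
#' Mean of the two measurements against their difference, with the mean
#' difference (solid) and 95% limits of agreement (dotted).
#'
#' @inheritParams mape
#' @param ... further arguments passed to [graphics::plot()].
#' @return the [bland_altman()] statistics, invisibly.
#' @export
plot_bland_altman <- function(true_counts, pred_counts, ...) {
  ba <- bland_altman(true_counts, pred_counts)
  graphics::plot((true_counts + pred_counts) / 2, pred_counts - true_counts,
                 xlab = "Mean of methods (steps)",
                 ylab = "Difference (predicted - truth, steps)", ...)
  graphics::abline(h = ba$mean_diff, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 3)
  invisible(ba)
}

#' Classification metrics for walk/nonwalk labels
#'
#' Standard confusion-matrix definitions with `walk` as the positive class;
#' Cohen's kappa is `(p_o - p_e) / (1 - p_e)` with the chance agreement from
#' marginal products. Metrics whose denominator is zero are reported as `NA`
#' with a warning, not as 0.
#'
#' @param true_labels,pred_labels aligned label vectors (factor/character
#'   `walk`/`nonwalk` or logical).
#' @param positive positive class (default `"walk"`).
#' @return an object of class `classification_report`: a list with
#'   `precision`, `recall`, `f1`, `accuracy`, `cohens_kappa`, and the 2x2
#'   `confusion` matrix.
#' @export
classification_metrics <- function(true_labels, pred_labels, positive = "walk") {
  tr <- as_walk_label(true_labels)
  pr <- as_walk_label(pred_labels)
  stopifnot(length(tr) == length(pr), length(tr) >= 1L)
  neg <- setdiff(walk_levels, positive)
  tp <- sum(tr == positive & pr == positive)
  fp <- sum(tr == neg & pr == positive)
  fn <- sum(tr == positive & pr == neg)
  tn <- sum(tr == neg & pr == neg)
  n <- tp + fp + fn + tn
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall))
    NA_real_ else safe_div(2 * precision * recall, precision + recall, "F1")
  accuracy <- (tp + tn) / n
  p_o <- accuracy
  p_e <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps) {
    if (abs(p_o - p_e) < .Machine$double.eps) 0
    else { warning("kappa undefined (chance agreement = 1)"); NA_real_ }
  } else (p_o - p_e) / (1 - p_e)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, cohens_kappa = kappa,
                 confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                                    dimnames = list(truth = walk_levels,
                                                    predicted = walk_levels))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  accuracy %.3f  Cohen's kappa %.3f\n",
              x$accuracy, x$cohens_kappa))
  invisible(x)
}

#' Step-count agreement report
#'
#' Bundles the per-subject agreement metrics into one object: MAPE, signed
#' mean percent bias, Spearman's rho (NA when n < 3), and Bland-Altman
#' statistics.
#'
#' @inheritParams mape
#' @return an object of class `agreement_report`.
#' @export
agreement_report <- function(true_counts, pred_counts) {
  structure(list(
    mape_percent = mape(true_counts, pred_counts),
    mean_bias_percent = mean_bias_percent(true_counts, pred_counts),
    spearman_rho = if (length(true_counts) >= 3L &&
                       stats::sd(true_counts) > 0 && stats::sd(pred_counts) > 0)
      spearman_rho(true_counts, pred_counts) else NA_real_,
    bland_altman = bland_altman(true_counts, pred_counts),
    n_subjects = length(true_counts)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d subjects\n", x$n_subjects))
  cat(sprintf("  MAPE %.2f%%  bias %+.2f%%  Spearman rho %.3f\n",
              x$mape_percent, x$mean_bias_percent, x$spearman_rho))
  cat(sprintf("  Bland-Altman: mean %.1f steps, LoA [%.1f, %.1f]\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}
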