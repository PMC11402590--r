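# Two-state hidden Markov model smoother: fitted from validation-set
# predictions against ground truth, applied to predicted epoch label
# sequences by Viterbi decoding. State 1 = nonwalk, state 2 = walk; all
# tie-breaks prefer nonwalk (no steps are fabricated on ties).

#' Two-state HMM parameters
#'
#' Initial, transition and emission probabilities over the hidden true states
#' (nonwalk, walk); the emission matrix is `P(predicted label | true state)`.
#' Rows are validated to sum to 1 (within 1e-8) and renormalised exactly.
#'
#' @param initial length-2 probability vector over (nonwalk, walk).
#' @param transition 2x2 row-stochastic matrix over true states.
#' @param emission 2x2 row-stochastic matrix, rows = true state, columns =
#'   predicted label.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(initial, transition, emission) {
  initial <- as.numeric(initial)
  transition <- matrix(as.numeric(transition), 2, 2,
                       dimnames = list(walk_levels, walk_levels))
  emission <- matrix(as.numeric(emission), 2, 2,
                     dimnames = list(walk_levels, walk_levels))
  check_rows <- function(m, what) {
    if (any(m < 0)) stop(what, " must be non-negative")
    s <- if (is.matrix(m)) rowSums(m) else sum(m)
    if (any(abs(s - 1) > 1e-8)) stop(what, " rows must sum to 1")
    if (is.matrix(m)) m / s else m / s
  }
  structure(list(initial = check_rows(initial, "initial"),
                 transition = check_rows(transition, "transition"),
                 emission = check_rows(emission, "emission")),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> two-state walk/nonwalk smoother\n")
  cat(sprintf("  initial    : nonwalk %.3f, walk %.3f\n", x$initial[1], x$initial[2]))
  cat(sprintf("  transition : stay-nonwalk %.3f, stay-walk %.3f\n",
              x$transition[1, 1], x$transition[2, 2]))
  cat(sprintf("  emission   : P(pred=true) nonwalk %.3f, walk %.3f\n",
              x$emission[1, 1], x$emission[2, 2]))
  invisible(x)
}

#' Fit the label smoother from validation predictions
#'
#' Estimates the two-state HMM by counting: transitions are add-one-smoothed
#' bigram frequencies of the true labels within each sequence (sequences,
#' e.g. participants, are never bridged); emissions are the add-one-smoothed
#' confusion of predicted given true; the initial distribution is the
#' smoothed marginal of first labels.
#'
#' @param true_sequences list of true label sequences (factor/character
#'   `walk`/`nonwalk` or logical), one per participant.
#' @param predicted_sequences list of aligned predicted label sequences.
#' @return an [hmm_params()] object.
#' @export
fit_hmm <- function(true_sequences, predicted_sequences) {
  if (!is.list(true_sequences)) true_sequences <- list(true_sequences)
  if (!is.list(predicted_sequences)) predicted_sequences <- list(predicted_sequences)
  if (length(true_sequences) != length(predicted_sequences))
    stop("data error: different numbers of true and predicted sequences")
  trans <- matrix(0, 2, 2)
  emis <- matrix(0, 2, 2)
  init <- c(0, 0)
  for (s in seq_along(true_sequences)) {
    tr <- as.integer(as_walk_label(true_sequences[[s]]))
    pr <- as.integer(as_walk_label(predicted_sequences[[s]]))
    if (length(tr) != length(pr))
      stop("data error: misaligned sequence lengths in sequence ", s)
    if (!length(tr)) stop("data error: empty sequence ", s)
    init[tr[1]] <- init[tr[1]] + 1
    for (t in seq_len(length(tr) - 1L))
      trans[tr[t], tr[t + 1L]] <- trans[tr[t], tr[t + 1L]] + 1
    for (t in seq_along(tr)) emis[tr[t], pr[t]] <- emis[tr[t], pr[t]] + 1
  }
  smooth_rows <- function(m) {
    m <- m + 1
    m / rowSums(m)
  }
  hmm_params(initial = (init + 1) / sum(init + 1),
             transition = smooth_rows(trans),
             emission = smooth_rows(emis))
}

#' Smooth a predicted label sequence by Viterbi decoding
#'
#' Returns the maximum a posteriori hidden state path under the fitted HMM,
#' computed in log space with a probability floor of 1e-12. Exact score ties
#' are broken toward nonwalk at every step.
#'
#' @param params an [hmm_params()] object.
#' @param predicted_sequence predicted labels (factor/character or logical).
#' @return smoothed labels as a factor with levels `nonwalk`, `walk`.
#' @export
viterbi_smooth <- function(params, predicted_sequence) {
  stopifnot(inherits(params, "hmm_params"))
  obs <- as.integer(as_walk_label(predicted_sequence))
  T_ <- length(obs)
  if (!T_) stop("data error: empty sequence")
  lg <- function(p) log(pmax(p, 1e-12))
  li <- lg(params$initial)
  lt <- lg(params$transition)
  le <- lg(params$emission)
  delta <- matrix(-Inf, T_, 2)
  psi <- matrix(1L, T_, 2)
  delta[1, ] <- li + le[, obs[1]]
  if (T_ > 1L) for (t in 2:T_) {
    for (s in 1:2) {
      cand <- delta[t - 1L, ] + lt[, s]
      psi[t, s] <- which.max(cand)      # ties -> state 1 (nonwalk)
      delta[t, s] <- cand[psi[t, s]] + le[s, obs[t]]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])    # ties -> nonwalk
  if (T_ > 1L) for (t in (T_ - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  factor(walk_levels[path], levels = walk_levels)
}
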