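walk_levels <- c("nonwalk", "walk")
as_walk_label <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "walk", "nonwalk")
  factor(as.character(x), levels = walk_levels)
}

# Independent brute-force oracles used to verify the peak detector and the
# Viterbi decoder. These re-derive the definitions from scratch (plain scans
# and exhaustive enumeration); they never call the implementation under test.

# Brute-force peak search: enumerate strict local maxima, compute topographic
# prominence by explicit left/right searches for the nearest higher point and
# the minima in between, width at half prominence by locating the last/first
# crossing of the reference height inside the base segments, then apply the
# prominence and width constraints and greedy tallest-first distance
# suppression.
oracle_find_peaks <- function(v, fs, prominence_g, distance_s, width_s,
                              width_mode = "max") {
  n <- length(v)
  cand <- data.frame(index = integer(0), height = numeric(0),
                     prom = numeric(0), width = numeric(0))
  for (i in seq_len(n)) {
    if (i <= 1L || i >= n) next
    if (!(v[i] > v[i - 1L] && v[i] > v[i + 1L])) next
    hi_l <- which(v[seq_len(i - 1L)] > v[i])
    lb <- if (length(hi_l)) max(hi_l) else 0L
    lmin <- min(v[(lb + 1L):i])
    hi_r <- which(v[(i + 1L):n] > v[i])
    rb <- if (length(hi_r)) i + min(hi_r) else n + 1L
    rmin <- min(v[i:(rb - 1L)])
    prom <- v[i] - max(lmin, rmin)
    ref <- v[i] - prom / 2
    # left crossing: last index at/below ref in the left base segment
    seg <- (lb + 1L):(i - 1L)
    below <- seg[v[seg] <= ref]
    if (length(below)) {
      j <- max(below)
      xl <- if (v[j] < ref) j + (ref - v[j]) / (v[j + 1L] - v[j]) else j
    } else xl <- lb + 1L
    seg <- (i + 1L):(rb - 1L)
    below <- seg[v[seg] <= ref]
    if (length(below)) {
      j <- min(below)
      xr <- if (v[j] < ref) j - (ref - v[j]) / (v[j - 1L] - v[j]) else j
    } else xr <- rb - 1L
    cand <- rbind(cand, data.frame(index = i, height = v[i], prom = prom,
                                   width = (xr - xl) / fs))
  }
  ok <- cand$prom >= prominence_g
  ok <- ok & if (width_mode == "max") cand$width <= width_s
             else cand$width >= width_s
  cand <- cand[ok, , drop = FALSE]
  d_samp <- distance_s * fs
  kept <- integer(0)
  for (r in order(-cand$height, cand$index)) {
    if (!length(kept) || all(abs(cand$index[r] - kept) >= d_samp))
      kept <- c(kept, cand$index[r])
  }
  sort(kept)
}

# Exhaustive Viterbi oracle: scores every state path of length T for every
# requested observation sequence (vectorised over paths via indicator-matrix
# products) and returns the set of argmax paths per observation sequence.
# States and observations are integers 1 (nonwalk) / 2 (walk).
oracle_viterbi_sets <- function(params, T_) {
  lg <- function(p) log(pmax(p, 1e-12))
  li <- lg(params$initial); lt <- lg(params$transition)
  le <- lg(params$emission)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))[, T_:1, drop = FALSE]
  dimnames(paths) <- NULL
  obs <- paths  # same enumeration for observation sequences
  tscore <- li[paths[, 1]]
  if (T_ > 1L) for (t in 2:T_)
    tscore <- tscore + lt[cbind(paths[, t - 1L], paths[, t])]
  A <- paths == 1L; B <- obs == 1L
  escore <- le[1, 1] * (A %*% t(B)) + le[1, 2] * (A %*% t(!B)) +
            le[2, 1] * ((!A) %*% t(B)) + le[2, 2] * ((!A) %*% t(!B))
  list(paths = paths, obs = obs,
       scores = sweep(escore, 1, tscore, `+`))  # rows paths, cols obs
}

random_hmm_params <- function() {
  rrow <- function() { p <- runif(2, 0.05, 1); p / sum(p) }
  hmm_params(rrow(), rbind(rrow(), rrow()), rbind(rrow(), rrow()))
}
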