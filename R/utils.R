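# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#: labels are binary everywhere; state 1 = nonwalk so that all argmax
#: tie-breaks default toward "no steps fabricated".
walk_levels <- c("nonwalk", "walk")

as_walk_label <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "walk", "nonwalk")
  f <- factor(as.character(x), levels = walk_levels)
  if (anyNA(f)) stop("walk labels must be 'walk'/'nonwalk' (or logical)", call. = FALSE)
  f
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Used to give every participant (and every simulated bout stream) its own
#' deterministic random substream while keeping all randomness traceable to a
#' single master seed. A polynomial rolling hash keeps the result well below
#' `2^31` so it is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param key character scalar (e.g. a participant id).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2038074743
  as.integer((h + (abs(as.numeric(seed)) %% 97651) * 9973) %% 2038074743) + 1L
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Maximal runs of equal values in a vector: data.frame(start, end, value).
label_runs <- function(x) {
  r <- rle(as.vector(x))
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, end = ends, value = r$values,
             stringsAsFactors = FALSE)
}

# Atomic-ish file write: write to a temp file in the same directory, rename.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
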