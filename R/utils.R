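#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish failure modes.
np_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "np_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

np_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "np_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Logistic activation of a normalized threshold margin
#'
#' Concepts expose a graded activation alongside the binary firing rule:
#' `plogis((value - threshold) / scale)`. The scale defaults to 10% of the
#' threshold so that a value exactly at threshold maps to 0.5.
#'
#' @param value observed feature value
#' @param threshold firing threshold in the feature's native units
#' @param scale margin scale; default `0.1 * abs(threshold)`
#' @return activation in (0, 1)
#' @export
margin_activation <- function(value, threshold, scale = 0.1 * abs(threshold)) {
  if (scale <= 0) scale <- 1e-6
  stats::plogis((value - threshold) / scale)
}

# Run code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

concept_ids <- function() paste0("C", 1:12)

# Sliding-window maximum over the trailing `w` samples, O(n) via the
# block prefix/suffix cummax trick. NAs are ignored (treated as -Inf).
rolling_max <- function(x, w) {
  n <- length(x)
  x[is.na(x)] <- -Inf
  if (w >= n) return(cummax(x))
  nb <- ceiling(n / w)
  xp <- c(x, rep(-Inf, nb * w - n))
  mat <- matrix(xp, nrow = w)
  left <- as.numeric(apply(mat, 2, cummax))[seq_len(n)]
  right <- as.numeric(apply(mat[w:1, , drop = FALSE], 2, cummax)[w:1, ])
  prev <- c(rep(-Inf, w - 1L), right[seq_len(n - w + 1L)])
  pmax(prev, left)
}

# Modality owning each concept: C1-C4 facial/video, C5-C8 audio, C9-C12 physio.
concept_modality <- function() {
  rep(c("video", "audio", "physio"), each = 4L)
}
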