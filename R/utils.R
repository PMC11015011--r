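# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; each stochastic
#' stage (schedule, membership, spikes, noise, behavior, ...) draws from its
#' own substream so that changing one stage's draws never perturbs another's.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return an integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483563)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Maximal runs of ones in a binary vector; returns data.frame(start, end),
# 1-based inclusive frame indices. Zero rows when x has no ones.
runs_of_ones <- function(x) {
  r <- rle(as.integer(x != 0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

# Centered moving-window filter with window truncation at the boundaries.
# k is forced odd upstream.
roll_filter <- function(x, k, fun) {
  n <- length(x)
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    out[i] <- fun(x[lo:hi])
  }
  out
}

odd_window_frames <- function(window_s, frame_period_s) {
  k <- max(1L, round(window_s / frame_period_s))
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

# direction (0..360) -> orientation in [0, 180)
direction_to_orientation <- function(direction_deg) direction_deg %% 180

is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}
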