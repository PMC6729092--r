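# internal numeric helpers

# centred moving average; window clipped at the edges so length is preserved
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# cumulative trapezoidal integral, same length as x, starting at 0
cumtrapz_ <- function(x, dt) {
  c(0, cumsum((x[-length(x)] + x[-1]) / 2 * dt))
}

# trapezoidal integral of y over x
trapz_ <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Tukey (tapered-cosine) window of n samples with taper fraction a in [0, 1];
# a = 1 is a Hann window, a = 0 a rectangle
tukey_window <- function(n, a = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- a / 2
  lo <- t < edge
  hi <- t > 1 - edge
  if (a > 0) {
    w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / a - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / a - 1)))
  }
  w
}

# contiguous runs of TRUE as a two-column matrix of first/last indices
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# subtract the line through the means of the first and last w samples,
# pinning both ends of a series to zero baseline
anchor_detrend <- function(x, w = 50L) {
  n <- length(x)
  w <- max(1L, min(as.integer(w), n %/% 2))
  a <- mean(x[seq_len(w)])
  b <- mean(x[(n - w + 1L):n])
  t0 <- (1 + w) / 2
  t1 <- n - (w - 1) / 2
  slope <- if (t1 > t0) (b - a) / (t1 - t0) else 0
  x - (a + slope * (seq_len(n) - t0))
}

# derive a sub-seed without 32-bit integer overflow
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483646) + 1L
}

# evaluate expr under a temporary RNG seed, restoring global RNG state after
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_fmt <- function(class, ...) {
  abort(paste0(...), class = paste0("sparctug_", class))
}
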