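# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# cumulative trapezoidal integral of y over t, same length as t, starts at 0
cumtrapz <- function(t, y) {
  n <- length(t)
  stopifnot(length(y) == n, n >= 1)
  if (n == 1) return(0)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# indices of strict local minima of x (plateau-tolerant on the right)
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

# zero-phase filtering with odd-reflection edge padding: the input is
# extended at both ends by its point-reflection, filtered forward-backward,
# and the extensions dropped. Constants pass exactly; edge transients of
# narrow-band IIR filters are strongly reduced.
filtfilt_pad <- function(filt, x, pad = 450L) {
  n <- length(x)
  p <- min(n - 1L, pad)
  if (p < 1) return(signal::filtfilt(filt, x))
  head_ext <- 2 * x[1] - x[(p + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(filt, c(head_ext, x, tail_ext))
  y[(p + 1):(p + n)]
}

# linear interpolation with constant extension outside the node span
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2, ties = "ordered")$y
}

# bounded random walk: reflects at [lo, hi]
bounded_walk <- function(n, start, step_sd, lo, hi) {
  x <- numeric(n)
  x[1] <- start
  if (n > 1) {
    steps <- stats::rnorm(n - 1, 0, step_sd)
    for (i in 2:n) {
      v <- x[i - 1] + steps[i - 1]
      if (v > hi) v <- 2 * hi - v
      if (v < lo) v <- 2 * lo - v
      x[i] <- min(max(v, lo), hi)
    }
  }
  x
}
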