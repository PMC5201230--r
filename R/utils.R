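# Internal helpers: classed conditions, filtering, extrema, small numerics.

jt_error <- function(class, message, ...) {
  structure(
    class = c(class, "jt_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

jt_stop <- function(class, message, ...) stop(jt_error(class, message, ...))

#' @noRd
is_finite_number <- function(x) is.numeric(x) && all(is.finite(x))

# Zero-phase Butterworth low-pass with reflective padding.  signal::filtfilt
# alone shows visible end transients; padding by reflection keeps the
# interior response intact and removes the edge artefact.
lowpass_zerophase <- function(x, cutoff_hz, fs, order = 4) {
  n <- length(x)
  if (cutoff_hz >= fs / 2) return(x)
  m <- mean(x)
  xc <- x - m                      # de-mean: a constant passes through exactly
  if (max(abs(xc)) == 0) return(x)
  b <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- min(n - 1L, max(50L, ceiling(3 * fs / cutoff_hz)))
  xp <- c(2 * xc[1] - rev(xc[2:(pad + 1L)]), xc, 2 * xc[n] - rev(xc[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(b, xp)
  y[(pad + 1L):(pad + n)] + m
}

bandpass_zerophase <- function(x, band_hz, fs, order = 2) {
  n <- length(x)
  b <- signal::butter(order, band_hz / (fs / 2), type = "pass")
  pad <- min(n - 1L, max(50L, ceiling(3 * fs / band_hz[1])))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(b, xp)
  y[(pad + 1L):(pad + n)]
}

# Central-difference derivative; one-sided at the ends.  For a series
# sampled at 1 kHz in uV the output is in uV/ms.
central_diff <- function(x, dt = 1) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Strict interior local maxima/minima (both neighbours strictly lower/higher).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] > x[i + 1]]
}

local_minima <- function(x) local_maxima(-x)

# Least-squares line fit; returns c(intercept, slope) of y ~ t.
fit_line <- function(t, y) {
  tm <- mean(t); ym <- mean(y)
  den <- sum((t - tm)^2)
  if (den == 0) return(c(NA_real_, NA_real_))
  slope <- sum((t - tm) * (y - ym)) / den
  c(ym - slope * tm, slope)
}

# Intersection of two lines given as c(intercept, slope); NULL if parallel.
line_intersection <- function(l1, l2) {
  if (any(!is.finite(c(l1, l2)))) return(NULL)
  dslope <- l1[2] - l2[2]
  if (abs(dslope) < 1e-12) return(NULL)
  x <- (l2[1] - l1[1]) / dslope
  c(x = x, y = l1[1] + l1[2] * x)
}

# Inverse tangent in degrees.
atand <- function(x) atan(x) * 180 / pi

# Running maximum over a centred window, block-decomposed so it stays O(n).
running_max <- function(x, half_window) {
  n <- length(x)
  block <- max(1L, as.integer(half_window %/% 2))
  nb <- ceiling(n / block)
  bmax <- vapply(seq_len(nb), function(b) {
    max(x[((b - 1L) * block + 1L):min(n, b * block)])
  }, numeric(1))
  span <- ceiling(half_window / block)
  out <- numeric(n)
  for (b in seq_len(nb)) {
    lo <- max(1L, b - span); hi <- min(nb, b + span)
    m <- max(bmax[lo:hi])
    out[((b - 1L) * block + 1L):min(n, b * block)] <- m
  }
  out
}

# Row-wise median of a matrix via a single vectorized sort (much faster
# than apply(m, 1, median) for the many short rows of a beat stack).
row_medians <- function(m) {
  l <- nrow(m); k <- ncol(m)
  if (k == 1L) return(as.numeric(m))
  s <- matrix(m[order(row(m), m)], nrow = l, byrow = TRUE)
  if (k %% 2L == 1L) s[, (k + 1L) %/% 2L]
  else (s[, k %/% 2L] + s[, k %/% 2L + 1L]) / 2
}

ms_to_index <- function(t_ms, fs) as.integer(round(t_ms * fs / 1000)) + 1L

index_to_ms <- function(i, fs) (i - 1L) * 1000 / fs
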