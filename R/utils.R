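#' Derive a reproducible substream seed
#'
#' One top-level seed drives every stochastic stage (subject effects,
#' trial effects, sensor noise, bootstraps). Each stage draws from its own
#' named substream so that sources can be zeroed or replayed independently
#' without perturbing the others.
#'
#' @param seed integer master seed.
#' @param name character substream label.
#' @return integer in `[0, 2^31 - 2]`, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid 32-bit integers
  s <- as.numeric(seed) %% m
  for (ch in utf8ToInt(as.character(name)))
    s <- (s * 31 + ch) %% m
  as.integer(s)
}

# Minimum-jerk normalized position profile s(tau), tau in [0,1]:
# s(0)=0, s(1)=1, zero velocity and acceleration at both ends.
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Centered moving average with edge shrinkage; width must be odd.
moving_average <- function(x, width = 5) {
  if (width <= 1 || length(x) < width) return(x)
  k <- rep(1 / width, width)
  pad <- (width - 1) / 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  stats::filter(xp, k, sides = 2)[(pad + 1):(pad + length(x))]
}

# Central-difference derivative honoring the actual time stamps;
# one-sided differences at the ends so the result has the input length.
central_diff <- function(x, t) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

# Centered rolling maximum, window w frames (clamped at edges).
rolling_max <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  vapply(seq_len(n), function(i)
    max(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

# Runs of TRUE in a logical vector -> matrix with columns start, end
# (1-based, inclusive).
true_runs <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Angle between two 3D vectors, in degrees
#'
#' @param v1,v2 numeric length-3 vectors, or n x 3 matrices of row vectors.
#' @return numeric vector of angles in `[0, 180]` degrees; `NaN` where a
#'   vector has zero length.
#' @export
angle_deg <- function(v1, v2) {
  if (is.null(dim(v1))) v1 <- matrix(v1, nrow = 1)
  if (is.null(dim(v2))) v2 <- matrix(v2, nrow = 1)
  dot <- rowSums(v1 * v2)
  nn <- sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2))
  cosang <- ifelse(nn > 0, pmin(pmax(dot / nn, -1), 1), NA_real_)
  acos(cosang) * 180 / pi
}

# Symmetric percent difference between paired left/right values:
# 100 * |L - R| / ((L + R) / 2); zero when both are zero.
symmetric_pct_diff <- function(l, r) {
  denom <- (l + r) / 2
  ifelse(denom == 0, 0, 100 * abs(l - r) / abs(denom))
}
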