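# Internal numeric helpers shared across modules.

# Round half away from zero (round() rounds half to even, which would make the
# fovea column depend on parity of the image width).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

# Running mean with replicate padding at the edges; w is forced odd upstream.
run_mean <- function(v, w) {
  if (w <= 1L) return(v)
  h <- w %/% 2L
  n <- length(v)
  vp <- c(rep(v[1L], h), v, rep(v[n], h))
  cs <- cumsum(vp)
  (cs[w:(n + w - 1L)] - c(0, cs[seq_len(n - 1L)])) / w
}

# Separable box blur, rows then columns.
box_blur <- function(m, w_row = 3L, w_col = 3L) {
  if (w_row > 1L) m <- apply(m, 2L, run_mean, w = w_row)
  if (w_col > 1L) m <- t(apply(m, 1L, run_mean, w = w_col))
  m
}

# Smoothed zero-mean noise rescaled to the requested sd, so that the
# column-to-column correlation length and the marginal sd can be set
# independently.
smooth_noise <- function(n, sd, window) {
  if (sd <= 0) return(numeric(n))
  z <- stats::rnorm(n)
  if (window > 1L) z <- run_mean(z, window)
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) return(numeric(n))
  (z - mean(z)) * sd / s
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
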