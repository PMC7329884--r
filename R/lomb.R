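# Classic least-squares (Lomb) periodogram, used by the diurnal-movement
# phenotype.  Implemented with the time-offset tau so that the power at a
# frequency equals half the reduction in residual sum of squares obtained
# by least-squares fitting a sinusoid of that frequency to the centered
# series -- the property the test suite checks against a direct lm() fit.

# t_s: sample times in seconds; x: series (NA allowed, dropped);
# freq_hz: frequencies to evaluate. Returns unnormalized power per freq.
lomb_scargle_power <- function(t_s, x, freq_hz) {
  ok <- is.finite(x) & is.finite(t_s)
  t_s <- t_s[ok]
  x <- x[ok]
  if (length(x) < 3) return(rep(NA_real_, length(freq_hz)))
  x <- x - mean(x)
  vapply(freq_hz, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t_s)), sum(cos(2 * w * t_s))) / (2 * w)
    ct <- cos(w * (t_s - tau))
    st <- sin(w * (t_s - tau))
    cc <- sum(ct^2)
    ss <- sum(st^2)
    pc <- if (cc > 1e-12) sum(x * ct)^2 / cc else 0
    ps <- if (ss > 1e-12) sum(x * st)^2 / ss else 0
    0.5 * (pc + ps)
  }, numeric(1))
}

# Frequency grid covering a period band [band_h[1], band_h[2]] (hours) for
# a series of total span span_s seconds, oversampled 4x relative to the
# natural Fourier spacing 1/span; always contains at least one frequency.
band_frequencies <- function(band_h, span_s) {
  f_lo <- 1 / (band_h[2] * 3600)
  f_hi <- 1 / (band_h[1] * 3600)
  df <- 1 / (4 * span_s)
  n <- max(1L, floor((f_hi - f_lo) / df))
  seq(f_lo, f_hi, length.out = n + 1L)
}
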