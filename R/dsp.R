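# Low-level signal-processing primitives used by the acoustic front-end.

# Slice a signal into overlapping frames. Returns a list with the frame
# matrix (win_n x n_frames) and the frame-center times in seconds.
frame_signal <- function(samples, rate, win = 0.025, hop = 0.010) {
  win_n <- round(win * rate)
  hop_n <- round(hop * rate)
  n <- length(samples)
  if (n < win_n) samples <- c(samples, numeric(win_n - n))
  n <- length(samples)
  n_frames <- 1L + (n - win_n) %/% hop_n
  starts <- (seq_len(n_frames) - 1L) * hop_n
  idx <- outer(seq_len(win_n), starts, `+`)
  list(frames = matrix(samples[idx], nrow = win_n),
       time = starts / rate + win / 2,
       win_n = win_n, hop_n = hop_n)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank matrix: n_filters x (nfft/2 + 1).
mel_filterbank <- function(n_filters, nfft, rate, f_lo = 0, f_hi = rate / 2) {
  mel_pts <- seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_filters + 2L)
  bin_f <- (0:(nfft %/% 2L)) * rate / nfft
  fb <- matrix(0, n_filters, nfft %/% 2L + 1L)
  f_pts <- mel_to_hz(mel_pts)
  for (m in seq_len(n_filters)) {
    lo <- f_pts[m]; ce <- f_pts[m + 1L]; hi <- f_pts[m + 2L]
    up <- bin_f >= lo & bin_f <= ce
    dn <- bin_f > ce & bin_f <= hi
    fb[m, up] <- (bin_f[up] - lo) / (ce - lo)
    fb[m, dn] <- (hi - bin_f[dn]) / (hi - ce)
  }
  # unit-area filters: a flat spectrum yields equal energy in every band
  sums <- rowSums(fb)
  fb / ifelse(sums > 0, sums, 1)
}

# Orthonormal DCT-II basis (n_out x n_in), rows 1..n_out are coefficients
# c1..c_n_out (c0 excluded).
dct_basis <- function(n_out, n_in) {
  k <- seq_len(n_out)
  j <- seq_len(n_in)
  b <- sqrt(2 / n_in) * cos(outer(k, (j - 0.5), function(k, j) pi * k * j / n_in))
  b
}

# Levinson-Durbin recursion: autocorrelation r[0..p] -> LPC coefficients
# a = (1, a1..ap) of the prediction-error filter A(z).
levinson_durbin <- function(r, p) {
  a <- c(1, numeric(p))
  e <- r[1]
  if (e <= 0) return(list(a = a, err = 0))
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1L) acc <- acc + sum(a[2:i] * r[i:2])
    k <- -acc / e
    a_new <- a
    a_new[i + 1L] <- k
    if (i > 1L) a_new[2:i] <- a[2:i] + k * a[i:2]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  list(a = a, err = e)
}

# Line spectral frequencies of an LPC polynomial, in (0, pi), sorted.
# P(z) = A(z) + z^-(p+1) A(1/z), Q(z) = A(z) - z^-(p+1) A(1/z); the LSFs are
# the angles of the unit-circle roots of P and Q excluding z = +/-1.
lpc_to_lsf <- function(a) {
  p <- length(a) - 1L
  pa <- c(a, 0) + c(0, rev(a))
  qa <- c(a, 0) - c(0, rev(a))
  ang <- function(poly) {
    rt <- polyroot(rev(poly))
    th <- Arg(rt)
    th <- th[th > 1e-6 & th < pi - 1e-6]
    sort(th)
  }
  lsf <- sort(c(ang(pa), ang(qa)))
  if (length(lsf) != p) {
    # numerically degenerate frame: fall back to evenly spaced frequencies
    lsf <- pi * seq_len(p) / (p + 1L)
  }
  lsf
}

# FFT-based autocorrelation of a vector, lags 0..max_lag. An optional
# low-pass cutoff (fraction of the sampling rate) is applied to the power
# spectrum first; band-limiting widens the autocorrelation peaks so that
# 3-point parabolic interpolation of a peak position is reliable.
autocorr_fft <- function(x, max_lag, lp_frac = NULL) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2L * n))
  sp <- Mod(stats::fft(c(x, numeric(nfft - n))))^2
  if (!is.null(lp_frac)) {
    fr <- c(0:(nfft %/% 2L), -((nfft - nfft %/% 2L - 1L):1)) / nfft
    sp <- sp * exp(-(fr / lp_frac)^4)
  }
  ac <- Re(stats::fft(sp, inverse = TRUE)) / nfft
  ac[seq_len(max_lag + 1L)]
}

# Parabolic interpolation of an extremum at integer index i of vector v.
# Returns list(pos, val) with fractional position.
parabolic_peak <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(list(pos = i, val = v[i]))
  y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < 1e-12) return(list(pos = i, val = y2))
  d <- 0.5 * (y1 - y3) / denom
  list(pos = i + d, val = y2 - 0.25 * (y1 - y3) * d)
}
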