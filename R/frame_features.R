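#' Acoustic front-end configuration
#'
#' Defaults for the frame-level feature extractor: 25 ms Hamming window,
#' 10 ms hop, 26-filter mel bank for MFCCs c1-c15 (c0 excluded as redundant
#' with intensity), 8-band mel bank for the log filterbank energies, order-8
#' linear prediction for the line spectral frequencies, and an
#' autocorrelation pitch tracker searching 75-500 Hz (spanning both sexes)
#' with an octave-cost penalty.
#'
#' @param win,hop analysis window and hop in seconds.
#' @param n_mfcc number of cepstral coefficients (c1..c_n).
#' @param n_mel mel filters behind the MFCCs (and the loudness estimate).
#' @param n_mfb mel bands for the log filterbank energy features.
#' @param lpc_order linear-prediction order (= number of LSFs).
#' @param f_min,f_max pitch search range in Hz.
#' @param voicing_threshold minimum normalized autocorrelation for voicing.
#' @param octave_cost per-octave penalty on longer period candidates.
#' @param pitch_win pitch analysis window in seconds.
#' @param energy_floor_db floor for log-energy-type features.
#' @return a list of configuration values.
#' @export
features_config <- function(win = 0.025, hop = 0.010, n_mfcc = 15, n_mel = 26,
                            n_mfb = 8, lpc_order = 8, f_min = 75, f_max = 500,
                            voicing_threshold = 0.45, octave_cost = 0.02,
                            pitch_win = 0.040, energy_floor_db = -120) {
  if (f_min >= f_max)
    dv_stop("dyadvox_config_error", "pitch search range degenerate: f_min >= f_max")
  as.list(environment())
}

# Canonical ordered names of the 37 base features; derivatives append "_de".
base_feature_names <- function(cfg = features_config()) {
  c(paste0("mfcc", seq_len(cfg$n_mfcc)),
    paste0("mfb", seq_len(cfg$n_mfb)),
    paste0("lsf", seq_len(cfg$lpc_order)),
    "intensity", "pitch", "loudness",
    "jitter", "shimmer", "hnr")
}

#' Canonical names of the 74 frame-level features
#' @param cfg a [features_config()].
#' @return character vector of length 74.
#' @export
frame_feature_names <- function(cfg = features_config()) {
  b <- base_feature_names(cfg)
  c(b, paste0(b, "_de"))
}

#' Frame track container
#'
#' Per-speaker matrix of the 74 frame-level features on the analysis grid.
#' Unvoiced frames carry `NA` (never 0) in the pitch, jitter, shimmer and
#' HNR columns and their derivatives.
#'
#' @param values frames x 74 numeric matrix with canonical column names.
#' @param time frame-center times in seconds.
#' @param voiced logical per-frame voicing mask.
#' @param hop frame hop in seconds.
#' @return an object of class `frame_track`.
#' @export
frame_track <- function(values, time, voiced, hop = 0.010) {
  values <- as.matrix(values)
  if (ncol(values) != 74L)
    dv_stop("dyadvox_validation_error", "frame track must have 74 columns, got %d", ncol(values))
  stopifnot(length(time) == nrow(values), length(voiced) == nrow(values))
  structure(list(values = values, time = as.numeric(time),
                 voiced = as.logical(voiced), hop = hop,
                 feature_names = colnames(values)),
            class = "frame_track")
}

#' @export
print.frame_track <- function(x, ...) {
  cat(sprintf("<frame_track: %d frames x %d features, %.0f%% voiced>\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$voiced)))
  invisible(x)
}

#' Spectral frame features: MFCCs, log mel-band energies, LSFs
#'
#' Extracts, per 25 ms Hamming-windowed frame at a 10 ms hop: 15 mel-frequency
#' cepstral coefficients (c1-c15 from a 26-filter bank), 8 log mel filterbank
#' energies, and 8 line spectral frequencies from order-8 linear prediction.
#' LSFs are strictly increasing in (0, pi) for every frame.
#'
#' @param audio an `audio_signal`.
#' @param cfg a [features_config()].
#' @return list with `values` (frames x 31 matrix), `time`, and `mel_energy`
#'   (frames x n_mel linear-scale band energies, reused for loudness).
#' @export
extract_spectral <- function(audio, cfg = features_config()) {
  fr <- frame_signal(audio$samples, audio$rate, cfg$win, cfg$hop)
  w <- signal::hamming(fr$win_n)
  xw <- fr$frames * w
  nfft <- 2^ceiling(log2(fr$win_n))
  n_frames <- ncol(xw)
  pad <- rbind(xw, matrix(0, nfft - fr$win_n, n_frames))
  sp <- stats::mvfft(pad)
  pw <- Mod(sp[seq_len(nfft %/% 2L + 1L), , drop = FALSE])^2

  floor_lin <- 10^(cfg$energy_floor_db / 10)
  fb_big <- mel_filterbank(cfg$n_mel, nfft, audio$rate)
  mel_e <- t(fb_big %*% pw)                       # frames x n_mel
  log_mel <- log(pmax(mel_e, floor_lin))
  mfcc <- log_mel %*% t(dct_basis(cfg$n_mfcc, cfg$n_mel))

  fb_small <- mel_filterbank(cfg$n_mfb, nfft, audio$rate)
  mfb <- log(pmax(t(fb_small %*% pw), floor_lin))

  lsf <- matrix(NA_real_, n_frames, cfg$lpc_order)
  max_lag <- cfg$lpc_order
  for (i in seq_len(n_frames)) {
    xi <- xw[, i]
    r <- autocorr_fft(xi, max_lag)
    r[1] <- r[1] + 1e-9 + 1e-6 * r[1]             # white-noise regularization
    a <- levinson_durbin(r, cfg$lpc_order)$a
    lsf[i, ] <- lpc_to_lsf(a)
  }

  values <- cbind(mfcc, mfb, lsf)
  colnames(values) <- c(paste0("mfcc", seq_len(cfg$n_mfcc)),
                        paste0("mfb", seq_len(cfg$n_mfb)),
                        paste0("lsf", seq_len(cfg$lpc_order)))
  list(values = values, time = fr$time, mel_energy = mel_e)
}

#' Prosodic and voice-quality frame features
#'
#' Per frame: pitch (Hz, autocorrelation method with octave-cost penalty,
#' voiced frames only), intensity (dB, full scale at 91 dB), perceptual
#' loudness (sum of compressed mel-band energies, exponent 0.3), and --
#' over a sliding window of about five glottal periods centered on the
#' frame -- relative jitter, relative shimmer, and harmonics-to-noise
#' ratio (dB). Unvoiced frames carry `NA` for pitch, jitter, shimmer, HNR.
#'
#' @param audio an `audio_signal`.
#' @param cfg a [features_config()].
#' @param mel_energy optional frames x n_mel energy matrix from
#'   [extract_spectral()] (recomputed if missing).
#' @return list with `values` (frames x 6 matrix: intensity, pitch, loudness,
#'   jitter, shimmer, hnr), `time`, and `voiced` mask.
#' @export
extract_prosody_voicequality <- function(audio, cfg = features_config(),
                                         mel_energy = NULL) {
  if (cfg$f_min >= cfg$f_max)
    dv_stop("dyadvox_config_error", "pitch search range degenerate: f_min >= f_max")
  x <- audio$samples
  rate <- audio$rate
  fr <- frame_signal(x, rate, cfg$win, cfg$hop)
  n_frames <- length(fr$time)
  w <- signal::hamming(fr$win_n)
  xw <- fr$frames * w

  pow <- colMeans(fr$frames^2)
  intensity <- 10 * log10(pmax(pow, 1e-12)) + 91

  if (is.null(mel_energy)) {
    nfft <- 2^ceiling(log2(fr$win_n))
    pad <- rbind(xw, matrix(0, nfft - fr$win_n, n_frames))
    pwspec <- Mod(stats::mvfft(pad)[seq_len(nfft %/% 2L + 1L), , drop = FALSE])^2
    mel_energy <- t(mel_filterbank(cfg$n_mel, nfft, rate) %*% pwspec)
  }
  loudness <- rowSums(pmax(mel_energy, 0)^0.3)

  # ---- pitch: autocorrelation over a wider centered window --------------
  lag_min <- max(2L, floor(rate / cfg$f_max))
  lag_max <- ceiling(rate / cfg$f_min)
  pw_n <- round(cfg$pitch_win * rate)
  half <- pw_n %/% 2L
  centers <- round(fr$time * rate)
  pitch <- rep(NA_real_, n_frames)
  voic_r <- numeric(n_frames)
  silence_floor <- max(pow) * 1e-4
  for (i in seq_len(n_frames)) {
    if (pow[i] <= max(silence_floor, 1e-10)) next
    lo <- max(1L, centers[i] - half)
    hi <- min(length(x), centers[i] + half)
    seg <- x[lo:hi]
    if (length(seg) < 2L * lag_min + 2L) next
    seg <- seg - mean(seg)
    ml <- min(lag_max, length(seg) - 2L)
    if (ml <= lag_min) next
    ac <- autocorr_fft(seg, ml, lp_frac = 1200 / rate)
    if (ac[1] <= 0) next
    rn <- ac / ac[1]
    # unbias the energy taper of the finite segment
    taper <- 1 - (0:ml) / length(seg)
    rn <- rn / pmax(taper, 0.25)
    lags <- lag_min:ml
    score <- rn[lags + 1L] - cfg$octave_cost * log2(lags / lag_min)
    j <- which.max(score)
    best_lag <- lags[j]
    r_best <- rn[best_lag + 1L]
    voic_r[i] <- r_best
    if (r_best >= cfg$voicing_threshold) {
      pk <- parabolic_peak(rn, best_lag + 1L)
      pitch[i] <- rate / (pk$pos - 1)
      if (pitch[i] < cfg$f_min || pitch[i] > cfg$f_max) pitch[i] <- rate / best_lag
    }
  }
  voiced <- !is.na(pitch)

  # ---- cycle-level jitter / shimmer over ~5 periods ---------------------
  jitter <- shimmer <- hnr <- rep(NA_real_, n_frames)
  for (i in which(voiced)) {
    t0 <- rate / pitch[i]
    half_jw <- round(5 * t0)
    lo <- max(1L, centers[i] - half_jw)
    hi <- min(length(x), centers[i] + half_jw)
    js <- jitter_shimmer(x[lo:hi], t0)
    jitter[i] <- js$jitter
    shimmer[i] <- js$shimmer
    r <- voic_r[i]
    r <- min(max(r, 1e-6), 1 - 1e-6)
    hnr[i] <- 10 * log10(r / (1 - r))
  }

  values <- cbind(intensity = intensity, pitch = pitch, loudness = loudness,
                  jitter = jitter, shimmer = shimmer, hnr = hnr)
  list(values = values, time = fr$time, voiced = voiced)
}

# Relative jitter and shimmer of a short voiced segment with expected
# period t0 (samples). The segment is matched-filtered with a zero-phase
# Hann-windowed cosine kernel at the expected period, giving a smooth
# fundamental-band signal. Local periods are estimated at one-period
# spacing by parabolic interpolation of the Hann-unbiased autocorrelation
# of that band; jitter is the mean absolute difference of consecutive
# local periods over the mean period. Cycle anchors (band peaks) give
# per-cycle RMS amplitudes over one median period for shimmer.
jitter_shimmer <- function(seg, t0) {
  n <- length(seg)
  none <- list(jitter = NA_real_, shimmer = NA_real_)
  if (n < round(7 * t0)) return(none)
  kl <- 2L * round(0.75 * t0) + 1L
  kt <- seq_len(kl) - (kl + 1L) / 2
  kern <- cos(2 * pi * kt / t0) * (0.5 + 0.5 * cos(2 * pi * kt / kl))
  s <- as.numeric(stats::filter(seg - mean(seg), kern / sum(kern^2), sides = 2))
  kh <- (kl - 1L) %/% 2L
  lo_v <- kh + 1L; hi_v <- n - kh
  if (hi_v - lo_v < round(5.5 * t0)) return(none)
  s[is.na(s)] <- 0

  margin <- round(2.3 * t0)
  centers <- seq(lo_v + margin, hi_v - margin, by = max(1L, round(t0)))
  if (length(centers) < 3L) return(none)
  periods <- vapply(centers, function(ct) local_period(s, ct, t0, n), numeric(1))
  periods <- periods[is.finite(periods) & periods > 0.5 * t0 & periods < 1.5 * t0]
  if (length(periods) < 3L) return(none)
  jit <- mean(abs(diff(periods))) / mean(periods)

  # cycle anchors: band peaks one period apart, for amplitude tracking
  i0 <- lo_v - 1L + which.max(abs(s[lo_v:hi_v]))
  sgn <- sign(s[i0]); if (sgn == 0) sgn <- 1
  sa <- s * sgn
  anchors <- integer(0)
  cur <- i0
  while (cur - t0 - t0 / 4 >= lo_v) {
    lo <- max(lo_v, round(cur - t0 - t0 / 4)); hi <- round(cur - t0 + t0 / 4)
    cur <- lo - 1L + which.max(sa[lo:hi])
    anchors <- c(cur, anchors)
  }
  anchors <- c(anchors, i0)
  cur <- i0
  while (cur + t0 + t0 / 4 <= hi_v) {
    lo <- round(cur + t0 - t0 / 4); hi <- min(hi_v, round(cur + t0 + t0 / 4))
    cur <- lo - 1L + which.max(sa[lo:hi])
    anchors <- c(anchors, cur)
  }
  tl <- stats::median(periods)
  fl <- floor(tl); frc <- tl - fl
  amps <- vapply(anchors, function(a) {
    if (a + fl > n) return(NA_real_)
    sqrt((sum(seg[a:(a + fl - 1L)]^2) + frc * seg[a + fl]^2) / tl)
  }, numeric(1))
  amps <- amps[is.finite(amps)]
  shim <- if (length(amps) >= 3L && all(amps > 0))
    mean(abs(diff(amps))) / mean(amps) else NA_real_
  list(jitter = jit, shimmer = shim)
}

# Local pitch period around `center` (samples): parabolic interpolation of
# the Hann-windowed, window-autocorrelation-unbiased autocorrelation of the
# fundamental-band signal.
local_period <- function(s, center, t0, n) {
  hw <- round(2.2 * t0)
  lo <- max(1L, center - hw); hi <- min(n, center + hw)
  w <- s[lo:hi]
  w <- w - mean(w)
  L <- length(w)
  lmin <- round(0.7 * t0); lmax <- min(round(1.4 * t0), L - 3L)
  if (lmax - lmin < 3L) return(NA_real_)
  han <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L))
  nfft <- 2^ceiling(log2(2L * L))
  acf_of <- function(v)
    Re(stats::fft(Mod(stats::fft(c(v, numeric(nfft - L))))^2,
                  inverse = TRUE))[seq_len(lmax + 1L)]
  acn <- acf_of(w * han) / pmax(acf_of(han), 1e-12)
  j <- lmin + which.max(acn[(lmin:lmax) + 1L]) - 1L
  pk <- parabolic_peak(acn, j + 1L)
  (pk$pos - 1)
}

#' Append first-order regression derivatives to a base feature matrix
#'
#' Computes 5-point local regression slopes (window of +/- 2 frames) for each
#' of the 37 base columns and appends them with a `_de` suffix, giving the
#' full 74-column frame track. Derivatives are missing-aware: slopes are
#' computed from the non-missing frames within the window, so voiced-only
#' features get derivatives over voiced runs and `NA` elsewhere; a frame
#' whose own value is missing has a missing derivative.
#'
#' @param base frames x 37 matrix in canonical base order.
#' @param time frame times (seconds).
#' @param voiced per-frame voicing mask.
#' @param hop frame hop in seconds.
#' @return a [frame_track()] with 74 columns.
#' @export
append_derivatives <- function(base, time, voiced, hop = 0.010) {
  base <- as.matrix(base)
  if (ncol(base) != 37L)
    dv_stop("dyadvox_validation_error", "expected 37 base columns, got %d", ncol(base))
  n <- nrow(base)
  if (n < 5L) dv_log("append_derivatives: only %d frames; shrinking windows", n)
  de <- regression_delta(base)
  de[is.na(base)] <- NA_real_
  colnames(de) <- paste0(colnames(base), "_de")
  frame_track(cbind(base, de), time, voiced, hop)
}

# Missing-aware moving regression slope over a +/- 2 frame window, applied
# column-wise to a matrix. Slope units: feature units per frame.
regression_delta <- function(m) {
  n <- nrow(m); p <- ncol(m)
  shifts <- -2:2
  S1 <- Sx <- Sy <- Sxx <- Sxy <- matrix(0, n, p)
  for (s in shifts) {
    shifted <- matrix(NA_real_, n, p)
    if (s >= 0) {
      if (n - s >= 1) shifted[seq_len(n - s), ] <- m[(1 + s):n, , drop = FALSE]
    } else {
      shifted[(1 - s):n, ] <- m[seq_len(n + s), , drop = FALSE]
    }
    present <- !is.na(shifted)
    v <- ifelse(present, shifted, 0)
    S1 <- S1 + present
    Sx <- Sx + s * present
    Sy <- Sy + v
    Sxx <- Sxx + s^2 * present
    Sxy <- Sxy + s * v
  }
  denom <- S1 * Sxx - Sx^2
  out <- (S1 * Sxy - Sx * Sy) / ifelse(denom == 0, NA_real_, denom)
  out
}

#' Extract the full 74-feature frame track from audio
#'
#' Convenience wrapper: spectral features, prosody/voice quality, and the
#' appended derivatives.
#'
#' @param audio an `audio_signal`.
#' @param cfg a [features_config()].
#' @return a [frame_track()].
#' @export
extract_frame_track <- function(audio, cfg = features_config()) {
  sp <- extract_spectral(audio, cfg)
  pr <- extract_prosody_voicequality(audio, cfg, mel_energy = sp$mel_energy)
  base <- cbind(sp$values, pr$values)
  append_derivatives(base, sp$time, pr$voiced, cfg$hop)
}
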