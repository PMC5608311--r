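test_that("VAD finds tone bursts, returns nothing on silence, is deterministic", {
  expect_equal(nrow(detect_voice(audio_signal(numeric(RATE), RATE))), 0L)

  sig <- c(make_tone(300, dur = 1)$samples, numeric(RATE),
           make_tone(300, dur = 1)$samples)
  v <- detect_voice(audio_signal(sig, RATE))
  expect_equal(nrow(v), 2L)
  expect_lt(abs(v$start[1] - 0), 0.05)
  expect_lt(abs(v$end[1] - 1), 0.05)
  expect_lt(abs(v$start[2] - 2), 0.05)
  expect_lt(abs(v$end[2] - 3), 0.05)

  set.seed(9)
  wn <- audio_signal(0.1 * rnorm(RATE), RATE)
  expect_identical(detect_voice(wn), detect_voice(wn))
})

test_that("VAD commutes with time shift on padded signals", {
  sig <- c(make_tone(250, dur = 0.8)$samples, numeric(round(0.5 * RATE)),
           make_tone(250, dur = 0.8)$samples)
  shift <- 0.5
  padded <- c(numeric(round(shift * RATE)), sig)
  v0 <- detect_voice(audio_signal(sig, RATE))
  v1 <- detect_voice(audio_signal(padded, RATE))
  expect_equal(nrow(v0), nrow(v1))
  expect_equal(v1$start, v0$start + shift, tolerance = 0.06)
  expect_equal(v1$end, v0$end + shift, tolerance = 0.06)
})

test_that("GLR is quiet under a stationary null and sharp at a 5 SD junction", {
  set.seed(31)
  false_alarms <- sum(vapply(1:20, function(i) {
    f <- matrix(rnorm(2500 * 15), 2500, 15)
    length(glr_change_points(f)) > 0
  }, logical(1)))
  expect_lte(false_alarms, 3L)      # threshold calibrated at 5% false alarm

  set.seed(32)
  f2 <- rbind(matrix(rnorm(1200 * 15), 1200, 15),
              matrix(rnorm(1200 * 15, mean = 5), 1200, 15))
  cps <- glr_change_points(f2)
  expect_length(cps, 1L)
  expect_lt(abs(cps - 12.0), 0.25)

  # region shorter than two analysis windows
  expect_length(glr_change_points(matrix(rnorm(150 * 15), 150, 15)), 0L)
})

test_that("GLR statistic vanishes for identical windows and is symmetric", {
  set.seed(33)
  m <- matrix(rnorm(200 * 5), 200, 5)
  expect_lt(abs(dyadvox:::glr_stat(rbind(m, m), 200L)), 1e-6)
  a <- matrix(rnorm(100 * 5), 100, 5)
  b <- matrix(rnorm(100 * 5, 1), 100, 5)
  expect_equal(dyadvox:::glr_stat(rbind(a, b), 100L),
               dyadvox:::glr_stat(rbind(b, a), 100L), tolerance = 1e-8)
})

test_that("agglomerative clustering separates two Gaussian speakers", {
  purities <- vapply(1:5, function(sd) {
    set.seed(sd)
    n_seg <- 12
    segs <- speech_segments(start = (0:(n_seg - 1)) * 2,
                            end = (0:(n_seg - 1)) * 2 + 1.5)
    truth <- rep(1:2, length.out = n_seg)
    frames <- list(); times <- list()
    for (i in seq_len(n_seg)) {
      nf <- 100
      mu <- if (truth[i] == 1) 0 else 3
      frames[[i]] <- matrix(rnorm(nf * 5, mu), nf, 5)
      times[[i]] <- seq(segs$start[i], segs$end[i], length.out = nf)
    }
    cl <- cluster_speakers(segs, do.call(rbind, frames), unlist(times))
    max(mean(cl$assignment == truth), mean(cl$assignment == 3 - truth))
  }, numeric(1))
  expect_gte(mean(purities), 0.9)

  expect_error(cluster_speakers(speech_segments(0, 1), matrix(0, 5, 2),
                                seq(0, 1, length.out = 5)),
               class = "dyadvox_degenerate_error")
  # exactly 2 segments: one per cluster
  segs2 <- speech_segments(c(0, 2), c(1, 3))
  f2 <- rbind(matrix(rnorm(50 * 3), 50, 3), matrix(rnorm(50 * 3, 4), 50, 3))
  t2 <- c(seq(0, 1, length.out = 50), seq(2, 3, length.out = 50))
  expect_setequal(cluster_speakers(segs2, f2, t2)$assignment, 1:2)
})

test_that("roles follow average pitch with a deterministic tie-break", {
  segs <- speech_segments(c(0, 2), c(1, 3))
  cl <- list(assignment = c(1L, 2L),
             segments = within(segs, label <- c("1", "2")))
  time <- seq(0, 3, by = 0.01)
  pitch <- ifelse(time < 1, 120, ifelse(time >= 2, 210, NA))
  dia <- assign_roles(cl, pitch, time)
  stats <- dia$cluster_stats
  expect_equal(stats$role[stats$mean_pitch > 200], "W")
  expect_equal(stats$role[stats$mean_pitch < 200], "H")

  pitch_tie <- ifelse(time < 1 | time >= 2, 150, NA)
  expect_warning(dia_tie <- assign_roles(cl, pitch_tie, time), "tie-break")
  expect_equal(dia_tie$cluster_stats$role, c("H", "W"))

  pitch_none <- ifelse(time < 1, 120, NA)   # cluster 2 has no voiced frames
  expect_error(assign_roles(cl, pitch_none, time),
               class = "dyadvox_role_error")
})

test_that("DER is zero for perfect output, permutation-invariant, and exact on a toy", {
  ref <- data.frame(role = c("H", "W"), start = c(0, 4), end = c(4, 8))
  expect_equal(diarization_error_rate(ref, ref), 0)
  swapped <- within(ref, role <- c("W", "H"))
  expect_equal(diarization_error_rate(swapped, ref), 0)

  hyp <- data.frame(role = c("H", "W"), start = c(0, 6), end = c(6, 8))
  expect_equal(diarization_error_rate(hyp, ref), 0.25)

  expect_error(diarization_error_rate(ref, ref[0, ]),
               class = "dyadvox_input_error")
})

test_that("rendered dyadic audio diarizes with correct roles and low DER", {
  cfg <- sim_config(turn_dur = c(1.2, 2.5), gap_dur = c(0.4, 0.7))
  ders <- vapply(1:3, function(sd) {
    plan <- simulate_turn_plan(cfg, seed = sd, n_turns = 8)
    ra <- render_audio(plan, cfg, seed = sd)
    dia <- diarize(ra$audio)
    stats <- dia$cluster_stats
    expect_gt(stats$mean_pitch[stats$role == "W"],
              stats$mean_pitch[stats$role == "H"])
    diarization_error_rate(dia, ra$reference)
  }, numeric(1))
  expect_lt(max(ders), 0.15)
})
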