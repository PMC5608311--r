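test_that("WAV round trips preserve content within 16-bit quantization", {
  f <- withr::local_tempfile(fileext = ".wav")

  write_audio(audio_signal(numeric(RATE), RATE), f)
  a <- load_audio(f)
  expect_equal(length(a$samples), RATE)
  expect_true(all(a$samples == 0))
  expect_equal(a$rate, RATE)

  tone <- make_tone(440)
  write_audio(tone, f)
  b <- load_audio(f)
  expect_lt(max(abs(b$samples - tone$samples)), 2^-14)
})

test_that("stereo input is downmixed by channel averaging", {
  f <- withr::local_tempfile(fileext = ".wav")
  x <- make_tone(200, dur = 0.2)$samples
  # hand-write a 2-channel file with identical channels
  pcm <- as.integer(round(pmin(pmax(x, -1), 32767 / 32768) * 32768))
  inter <- as.vector(rbind(pcm, pcm))
  con <- file(f, "wb")
  data_size <- length(inter) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(RATE, con, 4L, endian = "little")
  writeBin(RATE * 4L, con, 4L, endian = "little")
  writeBin(4L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4L, endian = "little")
  writeBin(inter, con, 2L, endian = "little")
  close(con)

  mono <- load_audio(f)
  expect_equal(mono$samples, pcm / 32768, tolerance = 1e-12)
})

test_that("audio loading errors name the offending input", {
  expect_error(load_audio(file.path(tempdir(), "nope.wav")),
               class = "dyadvox_input_error")
  f <- withr::local_tempfile(fileext = ".wav")
  writeLines("not a wav", f)
  expect_error(load_audio(f), class = "dyadvox_format_error")
})

test_that("RTTM segments round-trip, sort on read, and report bad lines", {
  f <- withr::local_tempfile(fileext = ".rttm")
  s <- speech_segments(c(2.5, 0.125, 5), c(3, 1, 6.25), c("H", "W", "H"))
  write_segments(s, f)
  s2 <- read_segments(f)
  expect_equal(s2$start, sort(c(2.5, 0.125, 5)), tolerance = 1e-3)
  expect_equal(s2$end - s2$start, c(0.875, 0.5, 1.25), tolerance = 1e-3)
  expect_equal(s2$label, c("W", "H", "H"))

  writeLines(character(0), f)
  expect_equal(nrow(read_segments(f)), 0L)

  writeLines(c("SPEAKER a 1 1.0 2.0 <NA> <NA> H <NA> <NA>",
               "SPEAKER a 1 5.0 -1.0 <NA> <NA> H <NA> <NA>"), f)
  expect_error(read_segments(f), "line 2", class = "dyadvox_parse_error")
})

test_that("outcome samples assemble per table row with shared pre sessions", {
  sessions <- dummy_sessions("C1", c("pre", "26wk", "2yr"))
  tab <- data.frame(couple_id = "C1", horizon = c("26wk", "2yr"),
                    rating = c(3, 4))
  corp <- assemble_outcome_samples(sessions, tab)
  expect_length(corp$samples, 2L)
  # both samples reference identical pre-session objects
  expect_identical(corp$samples[[1]]$pre, corp$samples[[2]]$pre)
  expect_equal(corpus_ratings(corp), c("C1:26wk" = 3L, "C1:2yr" = 4L))

  # couple with pre only contributes nothing
  corp2 <- assemble_outcome_samples(dummy_sessions("C2", "pre"),
                                    data.frame(couple_id = "C2",
                                               horizon = "26wk", rating = 2))
  expect_length(corp2$samples, 0L)
})

test_that("assembled sample count and class histogram match the row set", {
  # brute-force enumeration oracle over a mixed row set
  sessions <- c(dummy_sessions(c("A", "B"), c("pre", "26wk", "2yr")),
                dummy_sessions("C", c("pre", "26wk")),
                dummy_sessions("D", "26wk"))   # D lacks pre
  tab <- data.frame(
    couple_id = c("A", "A", "B", "C", "C", "D"),
    horizon = c("26wk", "2yr", "26wk", "26wk", "2yr", "26wk"),
    rating = c(1, 2, 3, 4, 4, 2))
  valid <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cid <- tab$couple_id[i]
    have <- vapply(sessions, function(s)
      paste(s$couple_id, s$timepoint), "")
    valid[i] <- sum(have == paste(cid, "pre")) == 2L &&
      sum(have == paste(cid, tab$horizon[i])) == 2L
  }
  corp <- assemble_outcome_samples(sessions, tab)
  expect_length(corp$samples, sum(valid))
  expect_equal(unname(class_counts(corp)),
               as.integer(table(factor(tab$rating[valid], levels = 1:4))))
})

test_that("the reference outcome mix yields 139 samples with exact counts", {
  counts <- c(12, 26, 34, 67)
  ratings <- rep(1:4, counts)
  cids <- sprintf("C%03d", seq_along(ratings))
  sessions <- dummy_sessions(cids, c("pre", "26wk"))
  tab <- data.frame(couple_id = cids, horizon = "26wk", rating = ratings)
  corp <- assemble_outcome_samples(sessions, tab)
  expect_length(corp$samples, 139L)
  expect_equal(unname(class_counts(corp)), counts)
})

test_that("outcome table validation rejects bad ratings and duplicates", {
  sessions <- dummy_sessions("C1")
  expect_error(assemble_outcome_samples(
    sessions, data.frame(couple_id = "C1", horizon = "26wk", rating = 5)),
    class = "dyadvox_validation_error")
  expect_error(assemble_outcome_samples(
    sessions, data.frame(couple_id = c("C1", "C1"),
                         horizon = c("26wk", "26wk"), rating = c(1, 2))),
    class = "dyadvox_validation_error")
})
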