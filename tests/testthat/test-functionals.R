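test_that("turn means are missing-aware frame averages", {
  v <- matrix(5, 20, 74)
  v[, 2] <- rep(1:2, 10)
  tr <- toy_track(v, hop = 0.1)           # frames at 0.05, 0.15, ...
  turns <- data.frame(role = c("H", "W"), start = c(0, 1), end = c(1, 2))
  tm <- turn_means(tr, turns)
  expect_equal(nrow(tm$means), 2L)
  expect_true(all(tm$means[, 1] == 5))

  # {1,2,3} -> 2
  v2 <- matrix(0, 3, 74); v2[, 1] <- 1:3
  tm2 <- turn_means(toy_track(v2, time = c(0.1, 0.2, 0.3)),
                    data.frame(role = "H", start = 0, end = 1))
  expect_equal(unname(tm2$means[1, 1]), 2)

  # pitch missing over an unvoiced turn, intensity present
  v3 <- matrix(1, 5, 74)
  v3[, match("pitch", frame_feature_names())] <- NA
  tm3 <- turn_means(toy_track(v3, time = (1:5) / 10),
                    data.frame(role = "H", start = 0, end = 1))
  expect_true(is.na(tm3$means[1, "pitch"]))
  expect_equal(unname(tm3$means[1, "intensity"]), 1)

  # turns with < 3 frames are dropped
  tm4 <- turn_means(toy_track(v2, time = c(0.1, 0.2, 0.3)),
                    data.frame(role = c("H", "W"), start = c(0, 2), end = c(1, 3)))
  expect_equal(length(tm4$role), 1L)
})

test_that("turn deltas follow the within/across-speaker rules", {
  mk_series <- function(roles, vals) {
    m <- matrix(0, length(roles), 74)
    m[, 1] <- vals
    colnames(m) <- frame_feature_names()
    structure(list(role = roles, start = seq_along(roles), means = m),
              class = "turn_mean_series")
  }
  d <- turn_deltas(mk_series(c("H", "W", "H", "W"), c(2, 5, 4, 1)))
  expect_equal(unname(d$HW[, 1]), c(3, -3))
  expect_equal(unname(d$HH[, 1]), 2)
  expect_equal(unname(d$WW[, 1]), -4)

  d2 <- turn_deltas(mk_series(c("H", "H"), c(3, 7)))
  expect_equal(unname(d2$HH[, 1]), 4)
  expect_equal(nrow(d2$HW), 0L)
  expect_equal(nrow(d2$WW), 0L)

  # identical consecutive turns: all deltas 0
  d3 <- turn_deltas(mk_series(c("H", "W", "H", "W"), c(1, 1, 1, 1)))
  expect_true(all(unlist(lapply(d3, function(m) m == 0))))
})

test_that("short-term functionals summarize delta sequences", {
  m <- matrix(0, 2, 74); colnames(m) <- frame_feature_names()
  m[, 1] <- c(4, -4)
  empty <- matrix(numeric(0), 0, 74,
                  dimnames = list(NULL, frame_feature_names()))
  st <- short_term_functionals(structure(list(HH = m, HW = empty, WW = empty),
                                         class = "turn_delta_set"))
  f1 <- frame_feature_names()[1]
  expect_equal(unname(st[paste0("HH_", f1, "_mean")]), 0)
  expect_equal(unname(st[paste0("HH_", f1, "_min")]), -4)
  expect_equal(unname(st[paste0("HH_", f1, "_max")]), 4)
  expect_true(all(is.na(st[grep("^HW_", names(st))])))

  # single-element sequence: population-convention SD 0
  one <- m[1, , drop = FALSE]
  st1 <- short_term_functionals(structure(list(HH = one, HW = empty, WW = empty),
                                          class = "turn_delta_set"))
  expect_equal(unname(st1[paste0("HH_", f1, "_sd")]), 0)
})

test_that("static functionals match hand arithmetic and order statistics", {
  v <- matrix(7, 8, 74)
  sf <- static_functionals(toy_track(v))
  f1 <- frame_feature_names()[1]
  expect_equal(unname(sf[paste0(f1, c("_mean", "_median"))]), c(7, 7))
  expect_equal(unname(sf[paste0(f1, c("_sd", "_iqr"))]), c(0, 0))

  v2 <- matrix(0, 4, 74); v2[, 1] <- c(1, 2, 3, 4)
  sf2 <- static_functionals(toy_track(v2))
  expect_equal(unname(sf2[paste0(f1, c("_mean", "_median", "_min", "_max"))]),
               c(2.5, 2.5, 1, 4))
  expect_length(sf2, 444L)

  # permutation invariance
  v3 <- matrix(rnorm(74 * 30), 30, 74)
  sf_a <- static_functionals(toy_track(v3))
  sf_b <- static_functionals(toy_track(v3[sample(30), ]))
  expect_equal(sf_a, sf_b)
})

test_that("long-term functionals are quarter deltas of session z-scores", {
  mk_inter <- function(tp, vals) {
    v <- matrix(0, length(vals), 74); v[, 1] <- vals
    colnames(v) <- frame_feature_names()
    tr <- frame_track(v, time = seq_along(vals), voiced = rep(TRUE, length(vals)))
    dyad_interaction("C1", tp, "husband_chosen", tracks = list(H = tr))
  }
  pre <- mk_inter("pre", c(1, 2, 3, 4))
  post_same <- mk_inter("26wk", c(1, 2, 3, 4))
  lt0 <- long_term_functionals(pre, post_same)
  expect_length(lt0, 592L)
  expect_true(all(lt0[!is.na(lt0)] == 0))

  # z-score arithmetic oracle: post quarters reversed
  post_rev <- mk_inter("26wk", c(4, 3, 2, 1))
  lt <- long_term_functionals(pre, post_rev)
  f1 <- frame_feature_names()[1]
  got <- unname(lt[paste0("q", 1:4, "_H_", f1)])
  expect_equal(got, c(2.32, 0.77, -0.77, -2.32), tolerance = 0.01)

  # antisymmetry under pre/post swap
  lt_swap <- long_term_functionals(post_rev, pre)
  expect_equal(unname(lt_swap), unname(-lt), tolerance = 1e-12)

  # constant feature: degenerate SD maps to 0, deltas 0
  pre_c <- mk_inter("pre", rep(5, 4))
  post_c <- mk_inter("26wk", rep(9, 4))
  ltc <- long_term_functionals(pre_c, post_c)
  expect_equal(unname(ltc[paste0("q", 1:4, "_H_", f1)]), rep(0, 4))
})

test_that("long-term deltas ignore per-session affine feature rescaling", {
  sim <- shared_sim()
  s <- sim$corpus$samples[[1]]
  lt1 <- long_term_functionals(s$pre$husband_chosen, s$post$husband_chosen)
  rescale <- function(inter, gain, offset) {
    for (r in names(inter$tracks)) {
      inter$tracks[[r]]$values <- inter$tracks[[r]]$values * gain + offset
    }
    inter
  }
  lt2 <- long_term_functionals(rescale(s$pre$husband_chosen, 3.7, -12),
                               rescale(s$post$husband_chosen, 0.4, 99))
  expect_equal(lt1, lt2, tolerance = 1e-8)
})

test_that("feature vectors assemble to the documented dimensions", {
  sim <- shared_sim()
  s <- sim$corpus$samples[[1]]
  expect_length(assemble_feature_vector(s, "codes"), 264L)
  expect_length(assemble_feature_vector(s, "static"), 3552L)
  dyn <- assemble_feature_vector(s, "dynamic")
  aa <- assemble_feature_vector(s, "acoustic_all")
  al <- assemble_feature_vector(s, "all")
  expect_length(aa, 3552L + length(dyn))
  expect_length(al, length(aa) + 264L)
})

test_that("feature matrices round-trip through the delimited format", {
  sim <- shared_sim()
  m <- assemble_feature_matrix(sim$corpus, "codes")
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(m, f)
  expect_true(file.exists(paste0(f, ".registry")))
  m2 <- read_feature_matrix(f)
  expect_equal(m2, m, tolerance = 1e-9)
})
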