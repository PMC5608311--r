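#' Synthetic dyadic-corpus configuration
#'
#' Defaults define the simulated study conditions: couples with a pre-therapy
#' session and one or two post-therapy sessions (26 weeks / 2 years), two
#' 10-minute-style topic interactions per session with alternating
#' husband/wife turns, a 4-class outcome mix proportional to the reference
#' counts 12/26/34/67, role baselines of 110 Hz (husband) and 210 Hz (wife)
#' fundamental frequency, AR(1) within-speaker drift of per-turn feature
#' means with a cross-speaker coupling term (vocal entrainment), and
#' class-conditioned effects whose signs mirror the strongest reported
#' feature-outcome associations: recovered couples get an elevated mean
#' pitch-delta and elevated loudness variability, declined couples the
#' reverse, and jitter shifts in the opposite direction.
#'
#' @param n_couples number of couples.
#' @param class_probs 4-vector of outcome-class probabilities (sums to 1).
#' @param p_both_horizons probability a couple has both 26wk and 2yr
#'   outcomes (else one horizon at random).
#' @param turns_per_interaction integer range of turns per interaction.
#' @param turn_dur turn duration range (s).
#' @param gap_dur inter-turn gap range (s).
#' @param base_f0 named Hz baselines for roles `H` and `W`.
#' @param effect_size d >= 0 scaling all class-conditioned effects.
#' @param noise_sd within-turn frame-level noise SD.
#' @param between_sd SD of per-turn AR(1) innovations.
#' @param couple_sd SD of the per-couple, per-role random feature offsets.
#' @param ar AR(1) coefficient of within-speaker turn-mean drift.
#' @param coupling cross-speaker coupling of turn means (entrainment).
#' @param trend_amp amplitude of the post-session within-session trend
#'   (drives the long-term quarter deltas).
#' @param sim_hop frame spacing of the simulated tracks (s).
#' @param annotators integer range of annotators per rated cell.
#' @param code_effect class effect on behavioral-code levels (1-9 scale).
#' @param code_noise annotator noise SD on the 1-9 scale.
#' @return a list of configuration values.
#' @export
sim_config <- function(n_couples = 88L,
                       class_probs = c(12, 26, 34, 67) / 139,
                       p_both_horizons = 0.6,
                       turns_per_interaction = c(14L, 20L),
                       turn_dur = c(0.5, 1.5),
                       gap_dur = c(0.2, 0.6),
                       base_f0 = c(H = 110, W = 210),
                       effect_size = 1,
                       noise_sd = 1,
                       between_sd = 0.5,
                       couple_sd = 1,
                       ar = 0.6,
                       coupling = 0.3,
                       trend_amp = 1,
                       sim_hop = 0.05,
                       annotators = c(2L, 4L),
                       code_effect = 1.2,
                       code_noise = 1) {
  if (length(class_probs) != 4L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8)
    dv_stop("dyadvox_config_error", "class_probs must be 4 non-negative values summing to 1")
  if (any(turn_dur <= 0) || any(gap_dur < 0) || sim_hop <= 0 ||
      any(turns_per_interaction < 2L))
    dv_stop("dyadvox_config_error", "ranges must be positive")
  if (effect_size < 0)
    dv_stop("dyadvox_config_error", "effect_size must be >= 0")
  as.list(environment())
}

# Class score in [-1, 1]: deteriorated -1 ... recovered +1.
class_score <- function(rating) (rating - 2.5) / 1.5

# Effect channels (canonical feature names) and their loadings. Signs follow
# the association structure the analysis is designed to recover: positive
# for mean pitch-delta and loudness variability, negative for jitter.
sim_effect_channels <- function() {
  list(pitch_de_shift = 0.5,     # additive shift of pitch_de turn means
       loudness_sd_gain = 0.35,  # multiplicative gain on loudness variability
       jitter_shift = -0.4)      # additive shift of jitter turn means
}

#' Simulate a feature-level dyadic therapy corpus
#'
#' Draws, per couple, an outcome class and one or two horizons; generates
#' per session and topic an alternating-turn plan; evolves 74-dimensional
#' per-turn latent feature means as role baseline + couple offset + AR(1)
#' within-speaker drift + cross-speaker coupling + class effects; and emits
#' frame-level values (turn mean + white noise) as per-role frame tracks
#' plus class-shifted 1-9 behavioral-code ratings from multiple simulated
#' annotators. Post-therapy sessions additionally carry a class-dependent
#' within-session trend so the long-term quarter deltas are informative.
#' Everything is driven by `seed`; the same seed reproduces the corpus
#' exactly.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `corpus` (a `dyad_corpus`, tracks and codes attached),
#'   `truth` (per-couple classes, turn plans, latent turn means),
#'   `outcome_table`, and `ratings` (long-format code-rating table).
#' @export
simulate_feature_corpus <- function(cfg = sim_config(), seed = 1L) {
  with_seed(seed, simulate_feature_corpus_impl(cfg))
}

simulate_feature_corpus_impl <- function(cfg) {
  feats <- frame_feature_names()
  nf <- length(feats)
  i_pitch <- match("pitch", feats)
  i_pitch_de <- match("pitch_de", feats)
  i_loud <- match("loudness", feats)
  i_jit <- match("jitter", feats)
  i_trend <- c(match("loudness", feats), match("mfcc1", feats))
  eff <- sim_effect_channels()
  d <- cfg$effect_size

  sessions <- list()
  truth <- list()
  outcome_rows <- list()
  ratings_rows <- list()
  codes <- code_inventory()
  code_sign <- rep(c(1, -1), length.out = length(codes))

  for (c_i in seq_len(cfg$n_couples)) {
    cid <- sprintf("C%03d", c_i)
    rating <- sample.int(4L, 1L, prob = cfg$class_probs)
    s <- class_score(rating)
    horizons <- if (stats::runif(1) < cfg$p_both_horizons) c("26wk", "2yr")
                else sample(c("26wk", "2yr"), 1L)
    u <- list(H = stats::rnorm(nf, 0, cfg$couple_sd),
              W = stats::rnorm(nf, 0, cfg$couple_sd))
    couple_truth <- list(class = rating, interactions = list())

    for (tp in c("pre", horizons)) {
      for (topic in c("husband_chosen", "wife_chosen")) {
        n_turns <- sample(seq(cfg$turns_per_interaction[1],
                              cfg$turns_per_interaction[2]), 1L)
        first <- sample(c("H", "W"), 1L)
        role_seq <- rep(c(first, setdiff(c("H", "W"), first)),
                        length.out = n_turns)
        durs <- stats::runif(n_turns, cfg$turn_dur[1], cfg$turn_dur[2])
        gaps <- stats::runif(n_turns, cfg$gap_dur[1], cfg$gap_dur[2])
        starts <- cumsum(c(gaps[1], durs[-n_turns] + gaps[-1]))
        ends <- starts + durs
        turns <- data.frame(role = role_seq, start = starts, end = ends,
                            stringsAsFactors = FALSE)

        loud_gain <- max(0.1, 1 + eff$loudness_sd_gain * d * s)
        # per-turn latent means: AR(1) within speaker + cross-speaker coupling
        mu <- matrix(0, n_turns, nf)
        last <- list(H = stats::rnorm(nf, 0, cfg$between_sd),
                     W = stats::rnorm(nf, 0, cfg$between_sd))
        for (t in seq_len(n_turns)) {
          r <- role_seq[t]
          o <- setdiff(c("H", "W"), r)
          innov_sd <- rep(cfg$between_sd, nf)
          innov_sd[i_loud] <- cfg$between_sd * loud_gain
          e_t <- cfg$ar * last[[r]] + cfg$coupling * last[[o]] +
            stats::rnorm(nf, 0, innov_sd)
          last[[r]] <- e_t
          mu[t, ] <- e_t + u[[r]]
        }
        # baselines and class effects (pitch latents scaled to a few Hz)
        mu[, i_pitch] <- mu[, i_pitch] * 3 +
          ifelse(role_seq == "H", cfg$base_f0[["H"]], cfg$base_f0[["W"]])
        mu[, i_pitch_de] <- mu[, i_pitch_de] + eff$pitch_de_shift * d * s
        mu[, i_jit] <- mu[, i_jit] + eff$jitter_shift * d * s
        if (tp != "pre") {
          frac <- (seq_len(n_turns) - 1) / max(1L, n_turns - 1L) - 0.5
          for (j in i_trend)
            mu[, j] <- mu[, j] + cfg$trend_amp * d * s * frac
        }

        # frame-level tracks per role
        tracks <- list()
        for (r in c("H", "W")) {
          t_idx <- which(role_seq == r)
          if (length(t_idx) == 0L) next
          fl <- lapply(t_idx, function(t) {
            tm <- seq(turns$start[t] + cfg$sim_hop / 2, turns$end[t],
                      by = cfg$sim_hop)
            nfr <- length(tm)
            noise <- matrix(stats::rnorm(nfr * nf, 0, cfg$noise_sd), nfr, nf)
            noise[, i_pitch] <- noise[, i_pitch] * 3
            noise[, i_loud] <- noise[, i_loud] * loud_gain
            vals <- sweep(noise, 2L, mu[t, ], `+`)
            list(time = tm, vals = vals)
          })
          vals <- do.call(rbind, lapply(fl, `[[`, "vals"))
          colnames(vals) <- feats
          tracks[[r]] <- frame_track(vals,
                                     unlist(lapply(fl, `[[`, "time")),
                                     voiced = rep(TRUE, nrow(vals)),
                                     hop = cfg$sim_hop)
        }

        # behavioral-code ratings for this interaction
        iid <- paste(cid, tp, topic, sep = ":")
        for (r in c("H", "W")) {
          level <- 5 + cfg$code_effect * d * s * code_sign +
            stats::rnorm(length(codes), 0, 0.7)
          n_ann <- sample(seq(cfg$annotators[1], cfg$annotators[2]), 1L)
          for (a in seq_len(n_ann)) {
            val <- pmin(9, pmax(1, round(level + stats::rnorm(length(codes), 0, cfg$code_noise))))
            ratings_rows[[length(ratings_rows) + 1L]] <-
              data.frame(interaction_id = iid, spouse = r, code = codes,
                         annotator = paste0("ann", a), rating = val,
                         stringsAsFactors = FALSE)
          }
        }

        sessions[[length(sessions) + 1L]] <-
          dyad_interaction(cid, tp, topic, turns = turns, tracks = tracks)
        couple_truth$interactions[[paste(tp, topic, sep = ":")]] <-
          list(turns = turns, turn_means = mu)
      }
    }
    truth[[cid]] <- couple_truth
    for (hz in horizons)
      outcome_rows[[length(outcome_rows) + 1L]] <-
        data.frame(couple_id = cid, horizon = hz, rating = rating,
                   stringsAsFactors = FALSE)
  }

  outcome_table <- do.call(rbind, outcome_rows)
  ratings <- do.call(rbind, ratings_rows)
  corpus <- assemble_outcome_samples(sessions, outcome_table)
  corpus <- attach_codes(corpus, average_annotators(ratings))
  corpus$metadata$sim_config <- cfg
  list(corpus = corpus, truth = truth, outcome_table = outcome_table,
       ratings = ratings)
}

#' Render a turn plan as schematic audio with a reference RTTM
#'
#' Each turn becomes an amplitude-modulated harmonic complex at the
#' speaker's fundamental frequency (with slow vibrato and a small random
#' frequency walk), separated by silence. This is deliberately schematic --
#' harmonic complexes, not speech -- but exercises voice activity
#' detection, diarization, and pitch tracking end to end.
#'
#' @param turns turn `data.frame` (`role`, `start`, `end`), non-overlapping.
#' @param cfg a [sim_config()] (role f0 baselines are taken from it).
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @return list with `audio` (an `audio_signal`) and `reference` (a segment
#'   `data.frame` labeled by role).
#' @export
render_audio <- function(turns, cfg = sim_config(), rate = 16000, seed = 1L) {
  turns <- turns[order(turns$start), , drop = FALSE]
  if (nrow(turns) > 1L && any(turns$start[-1L] < turns$end[-nrow(turns)]))
    dv_stop("dyadvox_validation_error", "turn plan contains overlapping turns")
  total <- if (nrow(turns)) max(turns$end) + 0.2 else 1
  x <- numeric(ceiling(total * rate))
  with_seed(seed, {
    for (i in seq_len(nrow(turns))) {
      f0 <- cfg$base_f0[[turns$role[i]]] * stats::runif(1, 0.96, 1.04)
      n <- round((turns$end[i] - turns$start[i]) * rate)
      if (n < 8L) next
      t <- seq_len(n) / rate
      f_traj <- f0 * (1 + 0.02 * sin(2 * pi * 3.1 * t) +
                        cumsum(stats::rnorm(n, 0, 2e-5)))
      phase <- 2 * pi * cumsum(f_traj) / rate
      sig <- numeric(n)
      for (h in 1:8) sig <- sig + sin(h * phase) / h
      env <- pmin(1, t / 0.05) * pmin(1, rev(t) / 0.05)
      am <- 1 + 0.2 * sin(2 * pi * 1.7 * t + stats::runif(1, 0, 2 * pi))
      sig <- 0.25 * sig / max(abs(sig)) * env * am
      i0 <- round(turns$start[i] * rate)
      x[i0 + seq_len(n)] <- x[i0 + seq_len(n)] + sig
    }
  })
  list(audio = audio_signal(x, rate),
       reference = speech_segments(turns$start, turns$end, turns$role))
}

#' Generate a seeded alternating turn plan
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param n_turns optional fixed number of turns.
#' @return a turn `data.frame` (`role`, `start`, `end`).
#' @export
simulate_turn_plan <- function(cfg = sim_config(), seed = 1L, n_turns = NULL) {
  with_seed(seed, {
    if (is.null(n_turns))
      n_turns <- sample(seq(cfg$turns_per_interaction[1],
                            cfg$turns_per_interaction[2]), 1L)
    first <- sample(c("H", "W"), 1L)
    role_seq <- rep(c(first, setdiff(c("H", "W"), first)), length.out = n_turns)
    durs <- stats::runif(n_turns, cfg$turn_dur[1], cfg$turn_dur[2])
    gaps <- stats::runif(n_turns, cfg$gap_dur[1], cfg$gap_dur[2])
    starts <- cumsum(c(gaps[1], durs[-n_turns] + gaps[-1]))
    data.frame(role = role_seq, start = starts, end = starts + durs,
               stringsAsFactors = FALSE)
  })
}

#' Write a simulated corpus to disk in pipeline-ingestible formats
#'
#' Emits the outcome table and code-rating table as CSV, per-interaction
#' reference turn RTTMs, and a ground-truth sidecar (per-couple class).
#' With `audio = TRUE` each interaction is also rendered to WAV.
#'
#' @param sim output of [simulate_feature_corpus()].
#' @param dir output directory (created).
#' @param audio render schematic audio per interaction (slow; default FALSE).
#' @param rate sampling rate for rendered audio.
#' @return `dir`, invisibly.
#' @export
write_sim_corpus <- function(sim, dir, audio = FALSE, rate = 16000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_outcome_table(sim$outcome_table, file.path(dir, "outcomes.csv"))
  write_code_ratings(sim$ratings, file.path(dir, "code_ratings.csv"))
  gt <- data.frame(couple_id = names(sim$truth),
                   class = vapply(sim$truth, `[[`, 0L, "class"))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- sim$corpus$metadata$sim_config
  for (cid in names(sim$truth)) {
    for (key in names(sim$truth[[cid]]$interactions)) {
      turns <- sim$truth[[cid]]$interactions[[key]]$turns
      stem <- gsub(":", "_", paste(cid, key, sep = "_"))
      write_segments(speech_segments(turns$start, turns$end, turns$role),
                     file.path(dir, paste0(stem, ".rttm")), file_id = stem)
      if (audio) {
        ra <- render_audio(turns, cfg, rate = rate,
                           seed = utils::head(which(names(sim$truth) == cid), 1))
        write_audio(ra$audio, file.path(dir, paste0(stem, ".wav")))
      }
    }
  }
  invisible(dir)
}
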