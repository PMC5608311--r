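# Shared fixtures, all generated in code at test time.

RATE <- 16000

make_saw <- function(f0, dur = 1, amp = 0.4, rate = RATE) {
  audio_signal(amp * (2 * ((f0 * seq_len(round(dur * rate)) / rate) %% 1) - 1), rate)
}

make_tone <- function(f0, dur = 1, amp = 0.3, rate = RATE) {
  audio_signal(amp * sin(2 * pi * f0 * seq_len(round(dur * rate)) / rate), rate)
}

# Minimal session list: pre + requested post sessions, both topics, no audio.
dummy_sessions <- function(couple_ids, timepoints = c("pre", "26wk")) {
  out <- list()
  for (cid in couple_ids)
    for (tp in timepoints)
      for (topic in c("husband_chosen", "wife_chosen"))
        out[[length(out) + 1L]] <- dyad_interaction(cid, tp, topic)
  out
}

# One small simulated corpus shared across test files (computed once).
.fixture_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_feature_corpus(sim_config(n_couples = 12),
                                                seed = 42)
  .fixture_env$sim
}

# Reduced hyperparameter grid for fast experiment runs in tests.
fast_grid <- function() list(cost = c(1, 100), gamma = c(0.01, 0.1))

# A frame track with prescribed values for functional tests.
toy_track <- function(values, time = NULL, hop = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) != 74L) {
    m <- matrix(0, nrow(values), 74L)
    m[, seq_len(ncol(values))] <- values
    values <- m
  }
  colnames(values) <- frame_feature_names()
  if (is.null(time)) time <- (seq_len(nrow(values)) - 0.5) * hop
  frame_track(values, time, voiced = rep(TRUE, nrow(values)), hop = hop)
}
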