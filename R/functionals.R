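#' Per-turn feature means
#'
#' Averages each frame-level feature over the frames of each turn
#' (missing-aware: unvoiced-only pitch within a turn yields a missing pitch
#' mean while intensity stays defined). Turns covering fewer than 3 frames
#' are dropped.
#'
#' @param track a [frame_track()].
#' @param turns turn `data.frame` (`role`, `start`, `end`).
#' @param min_frames minimum frames for a turn to be retained.
#' @return a `turn_mean_series`: list with `role`, `start`, and a
#'   turns x 74 `means` matrix, ordered by time.
#' @export
turn_means <- function(track, turns, min_frames = 3L) {
  turns <- turns[order(turns$start), , drop = FALSE]
  rows <- list(); roles <- character(0); starts <- numeric(0)
  for (i in seq_len(nrow(turns))) {
    idx <- which(track$time >= turns$start[i] & track$time < turns$end[i])
    if (length(idx) < min_frames) {
      dv_log("turn_means: dropped turn %d (%d frames)", i, length(idx))
      next
    }
    rows[[length(rows) + 1L]] <-
      colMeans(track$values[idx, , drop = FALSE], na.rm = TRUE)
    roles <- c(roles, turns$role[i])
    starts <- c(starts, turns$start[i])
  }
  means <- if (length(rows)) do.call(rbind, rows)
           else matrix(numeric(0), 0L, ncol(track$values),
                       dimnames = list(NULL, colnames(track$values)))
  structure(list(role = roles, start = starts, means = means),
            class = "turn_mean_series")
}

# Interleave the per-role tracks of an interaction into one turn-mean series.
interaction_turn_means <- function(inter, min_frames = 3L) {
  stopifnot(inherits(inter, "dyad_interaction"), !is.null(inter$turns))
  parts <- list()
  for (r in c("H", "W")) {
    tr <- inter$tracks[[r]]
    if (is.null(tr)) next
    tt <- inter$turns[inter$turns$role == r, , drop = FALSE]
    parts[[r]] <- turn_means(tr, tt, min_frames)
  }
  role <- unlist(lapply(parts, `[[`, "role"), use.names = FALSE)
  start <- unlist(lapply(parts, `[[`, "start"), use.names = FALSE)
  means <- do.call(rbind, lapply(parts, `[[`, "means"))
  o <- order(start)
  structure(list(role = role[o], start = start[o],
                 means = means[o, , drop = FALSE]),
            class = "turn_mean_series")
}

#' Adjacent-turn delta sequences
#'
#' Differences of per-turn feature means between adjacent turns within and
#' across speakers: HH (successive husband turns, later minus earlier,
#' skipping intervening wife turns), WW (analogous), and HW (wife turn minus
#' the immediately preceding husband turn at each H-to-W adjacency). The WH
#' deltas are intentionally omitted: they carry the same information with the
#' sign reversed.
#'
#' @param series a `turn_mean_series` from [turn_means()].
#' @return a `turn_delta_set`: list of matrices `HH`, `HW`, `WW`
#'   (rows = deltas, 74 columns; possibly 0 rows).
#' @export
turn_deltas <- function(series) {
  m <- series$means
  role <- series$role
  nf <- ncol(m)
  empty <- matrix(numeric(0), 0L, nf, dimnames = list(NULL, colnames(m)))
  within <- function(r) {
    idx <- which(role == r)
    if (length(idx) < 2L) return(empty)
    m[idx[-1L], , drop = FALSE] - m[idx[-length(idx)], , drop = FALSE]
  }
  hw_idx <- which(role[-length(role)] == "H" & role[-1L] == "W")
  hw <- if (length(hw_idx) == 0L) empty
        else m[hw_idx + 1L, , drop = FALSE] - m[hw_idx, , drop = FALSE]
  structure(list(HH = within("H"), HW = hw, WW = within("W")),
            class = "turn_delta_set")
}

#' Short-term dynamic functionals
#'
#' Applies the configured statistic set (mean, median, SD, min, max, IQR) to
#' each feature's HH, HW, and WW delta sequence. Statistics of an empty
#' sequence are missing; a single-element sequence has SD 0 by the
#' population convention.
#'
#' @param deltas a `turn_delta_set` from [turn_deltas()].
#' @return named numeric vector (delta type, feature, statistic; 1332 values
#'   under defaults).
#' @export
short_term_functionals <- function(deltas) {
  parts <- lapply(c("HH", "HW", "WW"), function(type) {
    m <- deltas[[type]]
    nm <- as.vector(t(outer(paste(type, colnames(m), sep = "_"),
                            functional_stat_names(), paste, sep = "_")))
    vals <- if (nrow(m) == 0L) rep(NA_real_, 6L * ncol(m))
            else as.vector(six_stats_matrix(m))
    stats::setNames(vals, nm)
  })
  do.call(c, parts)
}

#' Static functionals of one speaker's frame track
#'
#' Six statistics (mean, median, SD, min, max, IQR) of each of the 74
#' frame-level features over all of the speaker's speech frames in one
#' interaction: 444 values. Missing-aware throughout.
#'
#' @param track a [frame_track()].
#' @return named numeric vector of length 444 (feature, statistic).
#' @export
static_functionals <- function(track) {
  m <- track$values
  nm <- as.vector(t(outer(colnames(m), functional_stat_names(), paste, sep = "_")))
  if (nrow(m) == 0L)
    return(stats::setNames(rep(NA_real_, ncol(m) * 6L), nm))
  stats::setNames(as.vector(six_stats_matrix(m)), nm)
}

#' Long-term dynamic functionals of a pre/post interaction pair
#'
#' For each interaction: silence is already removed (tracks contain speech
#' frames only); each feature is z-normalized over both spouses' speech
#' frames pooled within the session (degenerate SD 0 maps values to 0); the
#' pooled, time-ordered speech frames are split into four equal-count
#' quarters; per-quarter per-spouse feature means are taken. The functional
#' is the post-therapy quarter mean minus the corresponding pre-therapy
#' quarter mean for every (feature, quarter, spouse): 592 values. Swapping
#' pre and post negates every value, and the session-level normalization
#' makes the result invariant to per-session affine re-scaling of a feature
#' (recording-condition mismatch).
#'
#' @param pre,post same-topic `interaction` objects of one couple.
#' @return named numeric vector of length 592 (quarter, spouse, feature).
#' @export
long_term_functionals <- function(pre, post) {
  qp <- lapply(list(pre = pre, post = post), session_quarter_means)
  out <- qp$post$means - qp$pre$means
  nm <- qp$pre$names
  stats::setNames(as.vector(out), nm)
}

# Per-quarter per-spouse means of session-normalized features.
# Returns list(means = numeric vector q x role x feature, names).
session_quarter_means <- function(inter) {
  tracks <- inter$tracks
  stopifnot(!is.null(tracks$H) || !is.null(tracks$W))
  vals <- list(); times <- list(); roles <- list()
  for (r in c("H", "W")) {
    tr <- tracks[[r]]
    if (is.null(tr) || nrow(tr$values) == 0L) next
    vals[[r]] <- tr$values; times[[r]] <- tr$time
    roles[[r]] <- rep(r, nrow(tr$values))
  }
  v <- do.call(rbind, vals)
  tm <- unlist(times, use.names = FALSE)
  rl <- unlist(roles, use.names = FALSE)
  o <- order(tm)
  v <- v[o, , drop = FALSE]; rl <- rl[o]
  n <- nrow(v)
  # session-level z-normalization over both spouses pooled
  mu <- apply(v, 2L, na_mean)
  sdv <- apply(v, 2L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) 0 else stats::sd(x)
  })
  z <- sweep(v, 2L, mu)
  z <- sweep(z, 2L, ifelse(sdv > 0, sdv, Inf), `/`)   # sd 0 -> values 0
  quarter <- ceiling(4L * seq_len(n) / n)
  feats <- colnames(v)
  means <- numeric(0); nms <- character(0)
  for (q in 1:4) {
    for (r in c("H", "W")) {
      idx <- which(quarter == q & rl == r)
      mq <- if (length(idx) == 0L) rep(NA_real_, ncol(z))
            else colMeans(z[idx, , drop = FALSE], na.rm = TRUE)
      means <- c(means, mq)
      nms <- c(nms, paste0("q", q, "_", r, "_", feats))
    }
  }
  list(means = means, names = nms)
}

topic_tag <- c(husband_chosen = "ht", wife_chosen = "wt")

#' Assemble the per-sample feature vector
#'
#' Concatenates the configured fragments in canonical order
#' (timepoint-major, then topic, speaker, feature, statistic):
#' \describe{
#'   \item{codes}{33 behavioral codes x 2 spouses x 2 topics x 2 timepoints
#'     = 264 values.}
#'   \item{static}{six statistics x 74 features x 2 speakers x 2 topics x
#'     2 timepoints = 3552 values.}
#'   \item{dynamic}{short-term turn-delta functionals per (timepoint, topic)
#'     plus long-term pre/post quarter deltas per topic.}
#'   \item{acoustic_all}{static + dynamic.}
#'   \item{all}{acoustic_all + codes.}
#' }
#' Missing fragments propagate as missing entries.
#'
#' @param sample an `outcome_sample`.
#' @param set_id one of `"codes"`, `"static"`, `"dynamic"`,
#'   `"acoustic_all"`, `"all"`.
#' @return named numeric vector with attribute `set_id`.
#' @export
assemble_feature_vector <- function(sample,
                                    set_id = c("codes", "static", "dynamic",
                                               "acoustic_all", "all")) {
  set_id <- match.arg(set_id)
  parts <- switch(set_id,
    codes = code_fragment(sample),
    static = static_fragment(sample),
    dynamic = dynamic_fragment(sample),
    acoustic_all = c(static_fragment(sample), dynamic_fragment(sample)),
    all = c(static_fragment(sample), dynamic_fragment(sample),
            code_fragment(sample)))
  frac_na <- mean(!is.finite(parts))
  if (frac_na > 0)
    dv_log("assemble_feature_vector(%s, %s): %.1f%% missing entries",
           sample$sample_id, set_id, 100 * frac_na)
  structure(parts, set_id = set_id)
}

static_fragment <- function(sample) {
  out <- numeric(0)
  for (tp in c("pre", "post")) {
    for (topic in c("husband_chosen", "wife_chosen")) {
      inter <- sample[[tp]][[topic]]
      for (r in c("H", "W")) {
        tr <- inter$tracks[[r]]
        frag <- if (is.null(tr)) {
          nm <- as.vector(t(outer(frame_feature_names(),
                                  names(functional_stats()), paste, sep = "_")))
          stats::setNames(rep(NA_real_, length(nm)), nm)
        } else static_functionals(tr)
        names(frag) <- paste(tp, topic_tag[[topic]], r, names(frag), sep = "_")
        out <- c(out, frag)
      }
    }
  }
  out
}

dynamic_fragment <- function(sample) {
  out <- numeric(0)
  for (tp in c("pre", "post")) {
    for (topic in c("husband_chosen", "wife_chosen")) {
      inter <- sample[[tp]][[topic]]
      st <- short_term_functionals(turn_deltas(interaction_turn_means(inter)))
      names(st) <- paste(tp, topic_tag[[topic]], names(st), sep = "_")
      out <- c(out, st)
    }
  }
  for (topic in c("husband_chosen", "wife_chosen")) {
    lt <- long_term_functionals(sample$pre[[topic]], sample$post[[topic]])
    names(lt) <- paste("lt", topic_tag[[topic]], names(lt), sep = "_")
    out <- c(out, lt)
  }
  out
}

code_fragment <- function(sample) {
  out <- numeric(0)
  codes <- code_inventory()
  for (tp in c("pre", "post")) {
    for (topic in c("husband_chosen", "wife_chosen")) {
      inter <- sample[[tp]][[topic]]
      for (r in c("H", "W")) {
        vals <- rep(NA_real_, length(codes))
        if (!is.null(inter$codes)) {
          cm <- inter$codes
          vals <- cm[codes, r]
        }
        out <- c(out, stats::setNames(vals, paste(tp, topic_tag[[topic]], r,
                                                  codes, sep = "_")))
      }
    }
  }
  out
}

#' Assemble the feature matrix for a whole corpus
#'
#' @param corpus a `dyad_corpus`.
#' @param set_id feature set id (see [assemble_feature_vector()]).
#' @return numeric matrix, rows = samples (named by sample id), columns in
#'   canonical order.
#' @export
assemble_feature_matrix <- function(corpus, set_id = "static") {
  rows <- lapply(corpus$samples, assemble_feature_vector, set_id = set_id)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(corpus$samples, `[[`, "", "sample_id")
  m
}

#' Write / read a per-sample feature matrix with a sidecar name registry
#'
#' The matrix is written as a comma-delimited table whose first column is the
#' sample id; the registry file lists the canonical column order, one name
#' per line.
#'
#' @param m feature matrix from [assemble_feature_matrix()].
#' @param path output CSV path; the registry is written to
#'   `paste0(path, ".registry")`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(colnames(m), paste0(path, ".registry"))
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  reg <- paste0(path, ".registry")
  if (file.exists(reg)) m <- m[, readLines(reg), drop = FALSE]
  m
}
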