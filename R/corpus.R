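#' Interaction, outcome-sample, and corpus containers
#'
#' An interaction is one 10-minute problem-solving conversation of one couple
#' at one timepoint (`pre`, `26wk`, or `2yr`), on the topic chosen by one
#' spouse. A session (timepoint) always comprises two interactions, one per
#' topic. An outcome sample pairs the pre-therapy session with one
#' post-therapy session and carries a 4-level outcome rating
#' (1 deteriorated, 2 no change, 3 improved, 4 recovered).
#'
#' @param couple_id couple identifier.
#' @param timepoint one of `"pre"`, `"26wk"`, `"2yr"`.
#' @param topic one of `"husband_chosen"`, `"wife_chosen"`.
#' @param audio optional `audio_signal`.
#' @param turns optional turn table (`data.frame` with `role`, `start`, `end`).
#' @param tracks optional named list of per-role frame tracks (`H`, `W`).
#' @param codes optional averaged behavioral-code ratings for this interaction
#'   (named list or data.frame, see [code_feature_vector()]).
#' @return an object of class `dyad_interaction`.
#' @export
dyad_interaction <- function(couple_id, timepoint, topic, audio = NULL,
                        turns = NULL, tracks = NULL, codes = NULL) {
  timepoint <- match.arg(timepoint, c("pre", "26wk", "2yr"))
  topic <- match.arg(topic, c("husband_chosen", "wife_chosen"))
  if (!is.null(turns)) {
    stopifnot(is.data.frame(turns), all(c("role", "start", "end") %in% names(turns)))
    turns <- turns[order(turns$start), , drop = FALSE]
  }
  structure(list(couple_id = as.character(couple_id), timepoint = timepoint,
                 topic = topic, audio = audio, turns = turns,
                 tracks = tracks, codes = codes),
            class = "dyad_interaction")
}

#' @rdname dyad_interaction
#' @param pre,post named lists of two interactions each
#'   (`husband_chosen`, `wife_chosen`).
#' @param rating integer outcome rating in 1..4.
#' @param horizon `"26wk"` or `"2yr"`.
#' @export
outcome_sample <- function(couple_id, pre, post, rating, horizon) {
  horizon <- match.arg(horizon, c("26wk", "2yr"))
  rating <- as.integer(rating)
  if (is.na(rating) || rating < 1L || rating > 4L)
    dv_stop("dyadvox_validation_error", "outcome rating must be in 1..4, got %s", rating)
  structure(list(couple_id = as.character(couple_id), pre = pre, post = post,
                 rating = rating, horizon = horizon,
                 sample_id = paste(couple_id, horizon, sep = ":")),
            class = "outcome_sample")
}

#' @rdname dyad_interaction
#' @param samples list of `outcome_sample` objects.
#' @param metadata free-form provenance list.
#' @export
dyad_corpus <- function(samples, metadata = list()) {
  structure(list(samples = samples, metadata = metadata), class = "dyad_corpus")
}

#' @export
print.dyad_corpus <- function(x, ...) {
  cat(sprintf("<dyad_corpus: %d outcome samples, %d couples>\n",
              length(x$samples),
              length(unique(vapply(x$samples, `[[`, "", "couple_id")))))
  tab <- class_counts(x)
  cat("  ratings:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Outcome-class histogram of a corpus
#' @param corpus a `dyad_corpus`.
#' @return named integer vector of counts for ratings 1..4.
#' @export
class_counts <- function(corpus) {
  r <- vapply(corpus$samples, `[[`, 0L, "rating")
  tab <- table(factor(r, levels = 1:4))
  stats::setNames(as.integer(tab), names(tab))
}

#' Ratings vector of a corpus
#' @param corpus a `dyad_corpus`.
#' @return named integer vector of ratings, names = sample ids.
#' @export
corpus_ratings <- function(corpus) {
  stats::setNames(vapply(corpus$samples, `[[`, 0L, "rating"),
                  vapply(corpus$samples, `[[`, "", "sample_id"))
}

#' Assemble outcome samples from sessions and an outcome table
#'
#' Pairs the pre-therapy session of each couple with the post-therapy session
#' named by each outcome-table row. A couple can contribute at most two
#' samples (one per horizon), and both share the identical pre-session data
#' (stored by reference, not copied). Rows whose couple lacks a complete
#' pre session or the referenced post session (both topic interactions)
#' are dropped with a logged reason.
#'
#' @param sessions a flat list of `interaction` objects.
#' @param outcome_table `data.frame` with columns `couple_id`, `horizon`
#'   (`"26wk"`/`"2yr"`), `rating` (1..4).
#' @return a `dyad_corpus`.
#' @export
assemble_outcome_samples <- function(sessions, outcome_table) {
  stopifnot(is.list(sessions),
            all(c("couple_id", "horizon", "rating") %in% names(outcome_table)))
  rating <- as.integer(outcome_table$rating)
  if (any(is.na(rating) | rating < 1L | rating > 4L))
    dv_stop("dyadvox_validation_error", "outcome table contains ratings outside 1..4")
  key <- paste(outcome_table$couple_id, outcome_table$horizon)
  if (anyDuplicated(key))
    dv_stop("dyadvox_validation_error", "duplicate (couple_id, horizon) rows: %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))

  idx_key <- vapply(sessions, function(s)
    paste(s$couple_id, s$timepoint, s$topic), "")
  session_pair <- function(cid, tp) {
    h <- sessions[idx_key == paste(cid, tp, "husband_chosen")]
    w <- sessions[idx_key == paste(cid, tp, "wife_chosen")]
    if (length(h) != 1L || length(w) != 1L) return(NULL)
    list(husband_chosen = h[[1]], wife_chosen = w[[1]])
  }

  pre_cache <- new.env(parent = emptyenv())
  samples <- list()
  dropped <- character()
  for (i in seq_len(nrow(outcome_table))) {
    cid <- as.character(outcome_table$couple_id[i])
    hz <- as.character(outcome_table$horizon[i])
    pre <- if (!is.null(pre_cache[[cid]])) pre_cache[[cid]]
           else { p <- session_pair(cid, "pre"); if (!is.null(p)) pre_cache[[cid]] <- p; p }
    post <- session_pair(cid, hz)
    if (is.null(pre) || is.null(post)) {
      dropped <- c(dropped, sprintf("%s:%s (missing %s session data)", cid, hz,
                                    if (is.null(pre)) "pre" else hz))
      next
    }
    samples[[length(samples) + 1L]] <-
      outcome_sample(cid, pre, post, rating[i], hz)
  }
  for (d in dropped) dv_log("assemble_outcome_samples: dropped %s", d)
  dyad_corpus(samples, metadata = list(n_table_rows = nrow(outcome_table),
                                       dropped = dropped))
}

#' Read / write the outcome table
#'
#' UTF-8 comma-delimited with header `couple_id,horizon,rating`.
#' @param path file path.
#' @return `read_outcome_table`: the table as a `data.frame`.
#' @export
read_outcome_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_outcome_table
#' @param outcome_table the table to write.
#' @export
write_outcome_table <- function(outcome_table, path) {
  utils::write.csv(outcome_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
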