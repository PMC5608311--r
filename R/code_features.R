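#' The 33-code behavioral inventory
#'
#' Short slugs for the 33 behavioral dimensions rated by trained annotators
#' on a 1-9 scale: 20 codes from the Social Support Interaction Rating
#' System (SSIRS) and 13 from the Couples Interaction Rating System (CIRS).
#'
#' @return character vector of 33 code names.
#' @export
code_inventory <- function() {
  c(# SSIRS (20)
    "global_positive", "global_negative", "use_of_humor", "humor_influence",
    "sadness", "anger", "belligerence", "contempt", "anxiety",
    "defensiveness", "affection", "satisfaction", "solicits_suggestions",
    "instrumental_support", "emotional_support", "dominance",
    "topic_relationship", "topic_personal", "discuss_husband",
    "discuss_wife",
    # CIRS (13)
    "acceptance", "blame", "responsibility", "solicits_perspective",
    "external_origins", "discussion", "defines_problem", "offers_solutions",
    "negotiates", "makes_agreements", "pressures_change", "withdraws",
    "avoidance")
}

validate_code_ratings <- function(ratings) {
  need <- c("interaction_id", "spouse", "code", "annotator", "rating")
  if (!all(need %in% names(ratings)))
    dv_stop("dyadvox_validation_error", "ratings table needs columns: %s",
            paste(need, collapse = ", "))
  if (any(ratings$rating < 1 | ratings$rating > 9))
    dv_stop("dyadvox_validation_error", "ratings must lie in [1, 9]")
  invisible(ratings)
}

#' Average multi-annotator code ratings
#'
#' Arithmetic mean per (interaction, spouse, code) cell; cells with no
#' annotator are missing.
#'
#' @param ratings long-format `data.frame` with columns `interaction_id`,
#'   `spouse` (`"H"`/`"W"`), `code`, `annotator`, `rating` (1-9).
#' @return `data.frame` with columns `interaction_id`, `spouse`, `code`,
#'   `rating` (the cell mean).
#' @export
average_annotators <- function(ratings) {
  validate_code_ratings(ratings)
  agg <- stats::aggregate(rating ~ interaction_id + spouse + code,
                          data = ratings, FUN = mean)
  agg[order(agg$interaction_id, agg$spouse, agg$code), , drop = FALSE]
}

# Averaged long table -> 33 x 2 matrix (rows = code inventory, cols H/W)
# for one interaction.
codes_matrix <- function(averaged, interaction_id) {
  codes <- code_inventory()
  m <- matrix(NA_real_, length(codes), 2L, dimnames = list(codes, c("H", "W")))
  sub <- averaged[averaged$interaction_id == interaction_id, , drop = FALSE]
  for (i in seq_len(nrow(sub)))
    m[sub$code[i], sub$spouse[i]] <- sub$rating[i]
  m
}

#' Krippendorff's alpha (interval metric)
#'
#' Inter-annotator agreement for interval-scale ratings, tolerant of missing
#' cells (units rated by different subsets of annotators). Computed from the
#' unit-wise pairwise squared-difference form:
#' \deqn{\alpha = 1 - D_o / D_e}
#' where the observed disagreement averages within-unit pairable squared
#' differences and the expected disagreement averages squared differences
#' over all pairs of pairable values. Alpha is 1 for perfect agreement,
#' near 0 for chance-level rating, and is invariant to affine rescaling of
#' all ratings.
#'
#' @param ratings long-format table as in [average_annotators()]; units are
#'   (interaction, spouse, code) cells.
#' @param by_code if `TRUE`, also return the per-code alphas and their mean.
#' @return pooled alpha (numeric), or if `by_code` a list with `pooled`,
#'   `per_code`, and `mean_per_code`.
#' @export
krippendorff_alpha <- function(ratings, by_code = FALSE) {
  validate_code_ratings(ratings)
  unit <- paste(ratings$interaction_id, ratings$spouse, ratings$code, sep = "\r")
  a <- alpha_from_units(split(ratings$rating, unit))
  if (!by_code) return(a)
  per <- vapply(split(ratings, ratings$code), function(sub) {
    u <- paste(sub$interaction_id, sub$spouse, sep = "\r")
    tryCatch(alpha_from_units(split(sub$rating, u)), error = function(e) NA_real_)
  }, numeric(1))
  list(pooled = a, per_code = per, mean_per_code = mean(per, na.rm = TRUE))
}

# alpha over a list of units (each a numeric vector of values by different
# annotators); units with < 2 values are unpairable and excluded.
alpha_from_units <- function(units) {
  units <- units[vapply(units, length, 0L) >= 2L]
  if (length(units) == 0L)
    dv_stop("dyadvox_input_error", "no co-rated units; alpha undefined")
  all_vals <- unlist(units, use.names = FALSE)
  if (length(unique(all_vals)) < 2L)
    return(1)                                   # zero disagreement anywhere
  n <- length(all_vals)
  d_o <- 0
  for (u in units) {
    m <- length(u)
    diffs <- outer(u, u, `-`)^2
    d_o <- d_o + sum(diffs) / (m - 1L)          # sum over ordered pairs
  }
  d_o <- d_o / n
  d_e <- sum(outer(all_vals, all_vals, `-`)^2) / (n * (n - 1L))
  1 - d_o / d_e
}

#' Behavioral-code feature vector of one outcome sample
#'
#' 33 codes x 2 spouses x 2 topics x 2 timepoints = 264 values in canonical
#' order (timepoint, topic, spouse, code). Equivalent to
#' `assemble_feature_vector(sample, "codes")`.
#'
#' @param sample an `outcome_sample` whose interactions carry averaged code
#'   matrices (see [attach_codes()]).
#' @return named numeric vector of length 264.
#' @export
code_feature_vector <- function(sample) {
  assemble_feature_vector(sample, "codes")
}

#' Attach averaged code ratings to the interactions of a corpus
#'
#' @param corpus a `dyad_corpus`.
#' @param averaged averaged long table from [average_annotators()];
#'   interaction ids follow `couple:timepoint:topic`.
#' @return the corpus with per-interaction 33 x 2 code matrices attached.
#' @export
attach_codes <- function(corpus, averaged) {
  for (i in seq_along(corpus$samples)) {
    s <- corpus$samples[[i]]
    for (tp in c("pre", "post")) {
      for (topic in c("husband_chosen", "wife_chosen")) {
        inter <- s[[tp]][[topic]]
        iid <- paste(inter$couple_id, inter$timepoint, inter$topic, sep = ":")
        s[[tp]][[topic]]$codes <- codes_matrix(averaged, iid)
      }
    }
    corpus$samples[[i]] <- s
  }
  corpus
}

#' Read / write long-format code-rating tables
#' @param path CSV path (columns `interaction_id`, `spouse`, `code`,
#'   `annotator`, `rating`).
#' @return the table as a `data.frame`.
#' @export
read_code_ratings <- function(path) {
  validate_code_ratings(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_code_ratings
#' @param ratings the table to write.
#' @export
write_code_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
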