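# Macro-averaged F1 over the classes present in the truth vector.
macro_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# Per-fold accuracy (%) and macro F-score of a cv_result.
per_fold_stats <- function(result) {
  fids <- sort(unique(result$fold))
  rows <- lapply(fids, function(f) {
    idx <- result$fold == f & !is.na(result$predictions)
    if (!any(idx)) {
      dv_log("per_fold_stats: fold %d has no test samples; excluded", f)
      return(NULL)
    }
    tr <- result$truth[idx]; pr <- result$predictions[idx]
    data.frame(fold = f, n = sum(idx),
               accuracy = 100 * mean(pr == tr),
               f_score = macro_f1(tr, pr))
  })
  do.call(rbind, rows)
}

#' Cross-validation accuracy and F-score summaries
#'
#' Mean and standard deviation of the per-fold accuracy (percent) and of the
#' per-fold macro-averaged F1 score.
#'
#' @param result a `cv_result` from [run_experiment()].
#' @return named numeric vector `c(mean, sd)`.
#' @export
accuracy_summary <- function(result) {
  fs <- if (!is.null(result$fold_stats)) result$fold_stats else per_fold_stats(result)
  c(mean = mean(fs$accuracy), sd = if (nrow(fs) > 1L) stats::sd(fs$accuracy) else 0)
}

#' @rdname accuracy_summary
#' @export
f_summary <- function(result) {
  fs <- if (!is.null(result$fold_stats)) result$fold_stats else per_fold_stats(result)
  c(mean = mean(fs$f_score), sd = if (nrow(fs) > 1L) stats::sd(fs$f_score) else 0)
}

#' Majority-class chance accuracy of an experiment
#'
#' 100 x (largest mapped-class count) / (domain size), reported to one
#' decimal, i.e. the accuracy of always predicting the largest class.
#'
#' @param corpus a `dyad_corpus` (or a vector of ratings 1..4).
#' @param experiment experiment id or [experiment_spec()].
#' @return chance accuracy in percent (1 decimal).
#' @export
chance_rate <- function(corpus, experiment = 1L) {
  spec <- if (is.list(experiment)) experiment else experiment_spec(experiment)
  ratings <- if (inherits(corpus, "dyad_corpus")) corpus_ratings(corpus)
             else as.integer(corpus)
  keep <- spec$domain(ratings)
  if (!any(keep))
    dv_stop("dyadvox_input_error", "empty experiment domain")
  y <- spec$map(ratings[keep])
  round(100 * max(table(y)) / length(y), 1)
}

#' Exact binomial comparison of two classifiers' pooled predictions
#'
#' Among the samples where exactly one of the two systems is correct (the
#' discordant samples), tests the split against P = 0.5 with a two-tailed
#' exact binomial test (the exact McNemar construction), and reports the
#' 95% Clopper-Pearson interval for the proportion of discordant samples
#' favoring system A. With zero discordant samples p = 1 and the interval
#' degenerates to [0, 1].
#'
#' @param res_a,res_b `cv_result` objects over the same sample domain.
#' @return list with `p`, `n_discordant`, `n_favor_a`, and `ci`.
#' @export
compare_feature_sets <- function(res_a, res_b) {
  ids <- names(res_a$truth)
  if (!setequal(ids, names(res_b$truth)))
    dv_stop("dyadvox_input_error", "results cover different sample domains")
  ids <- intersect(ids, names(res_b$truth))
  ca <- res_a$predictions[ids] == res_a$truth[ids]
  cb <- res_b$predictions[ids] == res_b$truth[ids]
  disc <- ca != cb
  n <- sum(disc)
  k <- sum(ca & disc)
  if (n == 0L) {
    dv_log("compare_feature_sets: no discordant samples")
    return(list(p = 1, n_discordant = 0L, n_favor_a = 0L, ci = c(0, 1)))
  }
  p <- stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  list(p = p, n_discordant = n, n_favor_a = k,
       ci = clopper_pearson(k, n))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles; the lower bound is 0
#' when k = 0 and the upper bound is 1 when k = n.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1L || k < 0L || k > n)
    dv_stop("dyadvox_validation_error", "need 0 <= k <= n with n >= 1")
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Tabulate experiment results across feature sets
#'
#' Builds the summary table of mean/SD accuracy and F-score per feature set
#' and experiment, with the chance row, in report formatting (1 decimal for
#' percentages, 2 for F-scores).
#'
#' @param results nested list: `results[[feature_set]][[as.character(expt)]]`
#'   holding `cv_result` objects.
#' @param corpus the corpus (for the chance row).
#' @return a `data.frame` report.
#' @export
results_table <- function(results, corpus) {
  expts <- sort(unique(unlist(lapply(results, names))))
  rows <- list()
  chance <- vapply(expts, function(e)
    chance_rate(corpus, as.integer(e)), numeric(1))
  rows[["Chance"]] <- c(Featureset = "Chance", Dim = "-",
                        unlist(lapply(seq_along(expts), function(i)
                          c(sprintf("%.1f", chance[i]), "-", "-", "-"))))
  for (fs in names(results)) {
    vals <- character(0)
    dim_fs <- "-"
    for (e in expts) {
      r <- results[[fs]][[e]]
      if (is.null(r)) { vals <- c(vals, rep("-", 4)); next }
      acc <- accuracy_summary(r); f <- f_summary(r)
      vals <- c(vals, sprintf("%.1f", acc[["mean"]]), sprintf("%.1f", acc[["sd"]]),
                sprintf("%.2f", f[["mean"]]), sprintf("%.2f", f[["sd"]]))
    }
    rows[[fs]] <- c(Featureset = fs, Dim = dim_fs, vals)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(out) <- c("Featureset", "Dim",
                     unlist(lapply(expts, function(e)
                       paste0("Expt", e, c("_acc_mean", "_acc_sd",
                                           "_F_mean", "_F_sd")))))
  rownames(out) <- NULL
  out
}
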