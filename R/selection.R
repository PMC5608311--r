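#' Binarize the 4-level outcome rating
#'
#' Recovery (rating 4) maps to 1; deteriorated / no change / improved
#' (ratings 1-3) map to 0.
#'
#' @param ratings integer vector of ratings in 1..4.
#' @return integer 0/1 vector.
#' @export
binarize_outcome <- function(ratings) {
  r <- as.integer(ratings)
  if (any(is.na(r) | r < 1L | r > 4L))
    dv_stop("dyadvox_validation_error", "ratings must be in 1..4")
  as.integer(r == 4L)
}

#' Pearson correlation with two-tailed significance test
#'
#' Pearson's r between a feature and (typically binary) labels, with the
#' two-tailed p-value from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}
#' on n-2 degrees of freedom. Zero-variance features yield missing values.
#'
#' @param x numeric feature values.
#' @param y numeric labels (same length, n >= 3).
#' @return list with `r` and `p`.
#' @export
pearson_with_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    dv_stop("dyadvox_input_error", "need n >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    dv_log("pearson_with_test: zero variance; r undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  r2 <- min(r^2, 1 - 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Correlation report for a feature matrix against binarized outcomes
#'
#' Computes Pearson's r and its two-tailed p for every column, and for each
#' base acoustic feature reports the functional (column) with the largest
#' absolute correlation, sorted by |r| descending.
#'
#' @param X samples x features matrix with canonical column names.
#' @param ratings outcome ratings 1..4 (binarized internally).
#' @param base_features optional character vector; for each entry the best
#'   matching column (by substring match on the canonical names) is
#'   reported. Default: all columns individually.
#' @return `data.frame` with `feature`, `functional`, `r`, `p`, sorted by
#'   |r| descending.
#' @export
correlation_report <- function(X, ratings, base_features = NULL) {
  y <- binarize_outcome(ratings)
  rp <- apply(X, 2L, function(col) {
    if (sum(is.finite(col)) < 3L || stats::sd(col, na.rm = TRUE) == 0)
      return(c(NA_real_, NA_real_))
    res <- pearson_with_test(col, y)
    c(res$r, res$p)
  })
  all_r <- rp[1L, ]; all_p <- rp[2L, ]
  if (is.null(base_features)) {
    out <- data.frame(feature = colnames(X), functional = colnames(X),
                      r = all_r, p = all_p, stringsAsFactors = FALSE)
  } else {
    rows <- lapply(base_features, function(bf) {
      hits <- grep(bf, colnames(X), fixed = TRUE)
      if (length(hits) == 0L)
        return(data.frame(feature = bf, functional = NA_character_,
                          r = NA_real_, p = NA_real_))
      best <- hits[which.max(abs(all_r[hits]))]
      data.frame(feature = bf, functional = colnames(X)[best],
                 r = all_r[best], p = all_p[best], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Equal-frequency discretization via order-statistic quantile breaks
# (type 1), so the binning is invariant under strictly monotone transforms.
equal_freq_bins <- function(x, bins) {
  ok <- is.finite(x)
  if (sum(ok) == 0L) return(rep(1L, length(x)))
  ux <- unique(x[ok])
  out <- rep(NA_integer_, length(x))
  if (length(ux) <= bins) {
    # few distinct values: each value is its own bin
    out[ok] <- as.integer(factor(x[ok], levels = sort(ux)))
  } else {
    br <- unique(stats::quantile(x[ok], probs = seq(0, 1, length.out = bins + 1L),
                                 type = 1, names = FALSE))
    out[ok] <- as.integer(cut(x[ok], breaks = br, include.lowest = TRUE))
  }
  out[!ok] <- 0L                                     # own bin for missing
  out
}

# Plug-in mutual information (bits) between two discrete vectors.
plugin_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  if (n == 0L) return(0)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Mutual-information maximization (MIM) scores
#'
#' Scores every feature X_k by its plug-in mutual information I(X_k; Y) with
#' the class label, in bits, after equal-frequency discretization of X_k
#' into `bins` bins. Constant columns score 0; scores are always >= 0.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param bins number of equal-frequency bins (default 10).
#' @return named numeric vector of scores.
#' @export
mim_scores <- function(X, y, bins = 10L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L)
    dv_stop("dyadvox_input_error", "need >= 2 classes for MIM scoring")
  scores <- apply(X, 2L, function(col) {
    b <- equal_freq_bins(col, bins)
    if (length(unique(b)) < 2L) return(0)
    plugin_mi(b, y)
  })
  pmax(scores, 0)
}

#' Select the top-k features by score
#'
#' Ties are broken toward the lower canonical (column) index.
#'
#' @param scores numeric score vector.
#' @param k number of features to keep (`k <= length(scores)`).
#' @return integer indices of the selected features, highest score first.
#' @export
select_top_k <- function(scores, k) {
  if (k > length(scores))
    dv_stop("dyadvox_config_error", "k = %d exceeds dimension %d", k, length(scores))
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Choose the number of selected features by inner cross-validation
#'
#' For each candidate k (by default 5/10/15/20/25% of the dimension), selects
#' the top-k MIM features on the training data and estimates accuracy by
#' inner k-fold cross-validation with an RBF SVM; returns the k maximizing
#' inner accuracy (ties toward smaller k).
#'
#' @param X training feature matrix (already imputed/normalized).
#' @param y training labels.
#' @param k_grid candidate k values; default `k_grid_default(ncol(X))`.
#' @param scores optional precomputed MIM scores.
#' @param inner_folds inner CV folds (default 5).
#' @param cost,gamma SVM parameters used during k selection; `gamma = NULL`
#'   means 1/k for each candidate.
#' @param seed RNG seed for the inner fold split.
#' @return list with `k` (chosen), `accuracy` (per candidate), `scores`.
#' @export
choose_k_by_cv <- function(X, y, k_grid = NULL, scores = NULL,
                           inner_folds = 5L, cost = 100, gamma = NULL,
                           seed = NULL) {
  if (is.null(k_grid)) k_grid <- k_grid_default(ncol(X))
  k_grid <- sort(unique(pmin(pmax(as.integer(k_grid), 1L), ncol(X))))
  if (length(k_grid) == 0L)
    dv_stop("dyadvox_config_error", "empty k grid")
  if (is.null(scores)) scores <- mim_scores(X, y)
  folds <- with_seed(seed, simple_folds(y, inner_folds))
  acc <- vapply(k_grid, function(k) {
    sel <- select_top_k(scores, k)
    g <- if (is.null(gamma)) 1 / k else gamma
    cv_accuracy(X[, sel, drop = FALSE], y, folds, cost = cost, gamma = g)
  }, numeric(1))
  list(k = k_grid[which.max(acc)], accuracy = stats::setNames(acc, k_grid),
       scores = scores)
}

#' Default k grid: 5-25% of the candidate dimension
#' @param p feature dimension.
#' @return integer vector of candidate k values.
#' @export
k_grid_default <- function(p) {
  unique(pmax(1L, round(p * c(0.05, 0.10, 0.15, 0.20, 0.25))))
}

#' Write a feature-selection report
#'
#' @param scores named score vector.
#' @param selected integer indices of selected features.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(scores, selected, path) {
  df <- data.frame(feature = names(scores), score = as.numeric(scores),
                   rank = rank(-scores, ties.method = "first"),
                   selected = seq_along(scores) %in% selected)
  df <- df[order(df$rank), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
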