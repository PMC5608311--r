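# Internal helpers shared across the pipeline.

#' Evaluate an expression under a local, restorable random seed
#'
#' All stochastic steps in the package accept an explicit seed and run under
#' a locally-scoped RNG state, so a call never disturbs the caller's stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Population standard deviation (n denominator); length-1 input gives 0.
# Used for all functional statistics so that degenerate single-observation
# sequences stay finite.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

# Missing-aware mean/median/iqr over finite entries only.
na_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}
na_median <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else stats::median(x)
}
na_iqr <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25))
}
na_min <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else min(x)
}
na_max <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else max(x)
}

# The six session-level statistics applied throughout the functional layer.
functional_stats <- function() {
  list(mean = na_mean, median = na_median, sd = pop_sd,
       min = na_min, max = na_max, iqr = na_iqr)
}

functional_stat_names <- function() c("mean", "median", "sd", "min", "max", "iqr")

# All six statistics of one vector from a single sorted pass (type-7
# quantiles, population SD). Returns them in functional_stat_names() order.
six_stats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(rep(NA_real_, 6L))
  s <- sort(x)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    fl <- floor(h)
    s[fl] + (h - fl) * (s[min(fl + 1L, n)] - s[fl])
  }
  m <- sum(s) / n
  sdv <- if (n == 1L) 0 else sqrt(sum((s - m)^2) / n)
  c(m, q7(0.5), sdv, s[1L], s[n], q7(0.75) - q7(0.25))
}

# six_stats applied to every column of a matrix: 6 x ncol matrix.
six_stats_matrix <- function(m) {
  vapply(seq_len(ncol(m)), function(j) six_stats(m[, j]), numeric(6L))
}

apply_functionals <- function(x, prefix) {
  out <- six_stats(x)
  names(out) <- paste(prefix, functional_stat_names(), sep = "_")
  out
}

# Lightweight condition helpers with consistent classes for callers/tests.
dv_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "dyadvox_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

dv_log <- function(fmt, ...) {
  if (isTRUE(getOption("dyadvox.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}
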