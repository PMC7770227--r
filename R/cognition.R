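# Cognitive decline: per-subject score slopes, partial Spearman
# correlation with network atrophy rates, and Bonferroni annotation.

#' Per-subject cognitive score slopes
#'
#' Ordinary least-squares slope of score on time for each subject-test
#' series with at least two time points; shorter series are dropped with a
#' message.
#'
#' @param records Long data frame with columns `subject_id`, `test`,
#'   `time`, `score` (as produced by [generate_cohort()]).
#' @return Wide data frame: one row per subject, one slope column per test
#'   (score units per year); NA where a slope could not be computed.
#' @export
cognitive_slopes <- function(records) {
  stopifnot(all(c("subject_id", "test", "time", "score") %in% names(records)))
  key <- interaction(records$subject_id, records$test, drop = TRUE)
  pieces <- split(records, key)
  rows <- lapply(pieces, function(df) {
    df <- df[order(df$time), ]
    if (nrow(df) < 2L || anyDuplicated(df$time)) {
      message(sprintf("dropping %s/%s: fewer than 2 usable time points",
                      df$subject_id[1], df$test[1]))
      return(NULL)
    }
    tc <- df$time - mean(df$time)
    data.frame(subject_id = df$subject_id[1], test = df$test[1],
               slope = sum(tc * df$score) / sum(tc^2),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  wide <- stats::reshape(long, idvar = "subject_id", timevar = "test",
                         direction = "wide")
  names(wide) <- sub("^slope\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms `x`, `y` and every covariate, residualizes the ranked
#' `x` and `y` on the ranked covariates by OLS, and correlates the
#' residuals. The p-value uses the t approximation with
#' `df = n - 2 - n_covariates`. With no covariates this is the ordinary
#' Spearman correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of covariates, or NULL.
#' @return An object of class `partial_corr_result` with `rho`, `p`, `n`,
#'   `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & apply(is.finite(covariates), 1L, all)
    covariates <- covariates[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 3L) stopf("need n > number of covariates + 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant x or y")
  rx <- rank(x); ry <- rank(y)
  if (k > 0) {
    rc <- apply(covariates, 2L, rank)
    X <- cbind(1, rc)
    rx <- stats::lm.fit(X, rx)$residuals
    ry <- stats::lm.fit(X, ry)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  structure(list(rho = rho, p = p, n = n, df = df, n_covariates = k),
            class = "partial_corr_result")
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat(sprintf("partial Spearman rho = %.3f, p = %.4g (n = %d, %d covariates)\n",
              x$rho, x$p, x$n, x$n_covariates))
  invisible(x)
}

#' Bonferroni annotation of correlation results
#'
#' Domain tests are judged at `alpha / n_tests` (default 0.05/6 ~ 0.0083);
#' the global test named in `separate` (MMSE by convention) is judged at
#' the uncorrected `alpha`.
#'
#' @param results Data frame with at least `test` and `p` columns.
#' @param alpha Familywise alpha (default 0.05).
#' @param n_tests Number of corrected domain tests (default 6).
#' @param separate Tests evaluated at the uncorrected alpha.
#' @return The input with `p_threshold` and `significant` columns added.
#' @export
bonferroni_annotate <- function(results, alpha = 0.05, n_tests = 6L,
                                separate = "MMSE") {
  stopifnot(n_tests >= 1L)
  thr <- ifelse(results$test %in% separate, alpha, alpha / n_tests)
  results$p_threshold <- thr
  results$significant <- results$p < thr
  results
}
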