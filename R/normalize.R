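#' Fit a null model to a predictor's score distribution
#'
#' The integration statistics assume each method's scores follow a Gaussian
#' null with method-specific mean. `"gaussian"` fits the bulk robustly
#' (median location, MAD scale) so that a genuine signal tail does not inflate
#' the null; `"empirical"` keeps the full score sample and converts scores via
#' the right-tail ECDF.
#'
#' @param scores Numeric vector of raw scores (>= 30 finite values for the
#'   parametric fit).
#' @param method `"gaussian"` (default) or `"empirical"`.
#' @return A `pg_null_model`: list with `mu`, `sigma`, `fit_method`, `n_fit`
#'   and, for the empirical fit, the sorted score sample.
#' @examples
#' nm <- fit_null(rnorm(1000, 5, 2))
#' score_to_pvalue(5, nm)
#' @export
fit_null <- function(scores, method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < 30) stop("need >= 30 finite scores to fit a null model", call. = FALSE)
  mu <- stats::median(scores)
  sigma <- stats::mad(scores)
  if (stats::sd(scores) == 0) {
    stop("degenerate score distribution: no spread to fit", call. = FALSE)
  }
  if (sigma <= 0) sigma <- stats::sd(scores)  # >50% ties defeat the MAD
  structure(
    list(mu = mu, sigma = sigma, fit_method = method, n_fit = n,
         sorted_scores = if (method == "empirical") sort(scores)),
    class = "pg_null_model"
  )
}

#' @export
print.pg_null_model <- function(x, ...) {
  cat("<pg_null_model> ", x$fit_method, " fit: mu = ", signif(x$mu, 4),
      ", sigma = ", signif(x$sigma, 4), " (n = ", x$n_fit, ")\n", sep = "")
  invisible(x)
}

#' Convert scores to right-tailed p-values
#'
#' High score = strong prediction, so significance is the right tail:
#' `p = 1 - pnorm((score - mu) / sigma)` for the Gaussian fit, or the smoothed
#' empirical right-tail fraction for the ECDF fit. p-values are floored at
#' `1 / (n_fit + 1)` so that `-log(p)` is always finite.
#'
#' @param score Numeric vector of scores.
#' @param null A [fit_null()] model.
#' @return p-values in (0, 1], monotone non-increasing in `score`.
#' @export
score_to_pvalue <- function(score, null) {
  stopifnot(inherits(null, "pg_null_model"))
  floor_p <- 1 / (null$n_fit + 1)
  if (null$fit_method == "gaussian") {
    p <- stats::pnorm((score - null$mu) / null$sigma, lower.tail = FALSE)
    pmax(p, floor_p)
  } else {
    s <- null$sorted_scores
    n_ge <- length(s) - findInterval(score, s, left.open = TRUE)
    pmax(n_ge, 1) / (length(s) + 1)
  }
}

#' Append p-values to a prediction dataset
#'
#' Fits the chosen null to the dataset's scores and adds a `p_value` column.
#'
#' @param predictions Tibble with a `score` column (e.g. from
#'   [generate_predictor_scores()] or [read_pair_tsv()]).
#' @param method Null fit method, see [fit_null()].
#' @param invert_scores Negate scores first, for methods whose raw convention
#'   is "lower is stronger".
#' @return The input with a `p_value` column; the fitted null is attached as
#'   attribute `null_model`.
#' @export
normalize_scores <- function(predictions, method = c("gaussian", "empirical"),
                             invert_scores = FALSE) {
  stopifnot("score" %in% names(predictions))
  s <- if (invert_scores) -predictions$score else predictions$score
  null <- fit_null(s, method)
  predictions$p_value <- score_to_pvalue(s, null)
  attr(predictions, "null_model") <- null
  predictions
}

#' Right-tailed Z-test of scores against a fitted null
#'
#' Tests whether the sample mean exceeds the null mean, the adequacy check for
#' treating the score distribution as the Gaussian null (significant rejection
#' indicates a signal component or a misfitted null).
#'
#' @param scores Numeric vector (>= 30 values).
#' @param null A [fit_null()] model.
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic` (Z), `p_value`, `reject`, `alpha`, `n`.
#' @export
gaussian_adequacy_test <- function(scores, null, alpha = 0.05) {
  stopifnot(inherits(null, "pg_null_model"))
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < 30) stop("need >= 30 scores", call. = FALSE)
  z <- (mean(scores) - null$mu) / (null$sigma / sqrt(n))
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(statistic = z, p_value = p, reject = p < alpha,
                 alpha = alpha, n = n),
            class = "pg_adequacy_test")
}

#' @export
print.pg_adequacy_test <- function(x, ...) {
  cat("<pg_adequacy_test> Z = ", signif(x$statistic, 4), ", p = ",
      signif(x$p_value, 4), " -> ",
      if (x$reject) "reject" else "accept",
      " Gaussian null at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}
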