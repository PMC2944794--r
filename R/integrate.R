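#' Simple integration: most significant prediction wins
#'
#' @param p Numeric vector of per-method p-values for one pair (NAs allowed
#'   for methods that did not score the pair).
#' @return The minimum present p-value.
#' @export
simple_integrate <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values present for this pair", call. = FALSE)
  min(p)
}

#' Weighted Fisher combination score
#'
#' `S = sum over present methods of w_i * (-ln p_i)`. A method that did not
#' score the pair contributes 0 (equivalent to p = 1), so S is monotone in
#' accumulating evidence.
#'
#' @param p Numeric vector (or single-row matrix) of per-method p-values in
#'   (0, 1]; NA marks an absent method.
#' @param weights Non-negative weights, one per method (recycled if scalar).
#' @return The Fisher score S >= 0.
#' @examples
#' fisher_score(c(0.1, 0.1), c(1, 1))  # 2 * -log(0.1)
#' @export
fisher_score <- function(p, weights = 1) {
  if (any(p <= 0, na.rm = TRUE)) stop("p-values must be in (0, 1]", call. = FALSE)
  weights <- rep_len(weights, length(p))
  contrib <- weights * (-log(p))
  sum(contrib[!is.na(contrib)])
}

# Vectorized Fisher scores over a pairs x methods p-value matrix.
fisher_score_matrix <- function(pmat, weights) {
  if (any(pmat <= 0, na.rm = TRUE)) stop("p-values must be in (0, 1]", call. = FALSE)
  nl <- -log(pmat)
  nl[is.na(nl)] <- 0
  as.numeric(nl %*% weights)
}

#' Normalize integrated Fisher scores to p-values
#'
#' The combined-score distribution is itself renormalized: the integrated
#' p-value of a pair is the right-tail ECDF position of its Fisher score among
#' all integrated scores, floored at `1 / (n + 1)`. These are the edge weights
#' of a Predictogram.
#'
#' @param scores Numeric vector of Fisher scores (>= 30).
#' @return p-values in (0, 1].
#' @export
normalize_integrated <- function(scores) {
  null <- fit_null(scores, "empirical")
  score_to_pvalue(scores, null)
}

#' Integrate per-method p-values across prediction datasets
#'
#' Joins the datasets on canonical pairs and combines their p-values by either
#' weighted Fisher summation or simple (minimum-p) integration; the combined
#' scores are then renormalized to integrated p-values via
#' [normalize_integrated()].
#'
#' @param datasets Named list of normalized prediction tibbles (each with
#'   `protein_a`, `protein_b`, `p_value`; see [normalize_scores()]).
#' @param method `"fisher"` (default) or `"simple"`.
#' @param weights A [optimize_weights()] result, a numeric vector (one weight
#'   per dataset), or NULL for uniform weights.
#' @return A `pg_integrated` tibble: `protein_a`, `protein_b`, one p-value
#'   column per method, `fisher_score`, `integrated_pvalue`.
#' @export
integrate_predictions <- function(datasets, method = c("fisher", "simple"),
                                  weights = NULL) {
  method <- match.arg(method)
  stopifnot(length(datasets) >= 1)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("method", seq_along(datasets))
  }
  joined <- join_pvalues(datasets)
  pmat <- as.matrix(joined[, names(datasets), drop = FALSE])
  if (method == "fisher") {
    w <- weight_vector(weights, length(datasets))
    s <- fisher_score_matrix(pmat, w)
  } else {
    s <- -log(apply(pmat, 1, function(r) min(r, na.rm = TRUE)))
  }
  joined$fisher_score <- s
  joined$integrated_pvalue <- normalize_integrated(s)
  structure(joined, integration = method,
            class = c("pg_integrated", class(joined)))
}

weight_vector <- function(weights, k) {
  if (is.null(weights)) return(rep(1 / k, k))
  if (inherits(weights, "pg_weights")) weights <- weights$weights
  stopifnot(length(weights) == k, all(weights >= 0), any(weights > 0))
  weights / sum(weights)
}

# Full join of per-method p-value columns on canonical pairs.
join_pvalues <- function(datasets) {
  tabs <- purrr::imap(datasets, function(d, nm) {
    stopifnot(all(c("protein_a", "protein_b", "p_value") %in% names(d)))
    stats::setNames(
      tibble::as_tibble(d)[, c("protein_a", "protein_b", "p_value")],
      c("protein_a", "protein_b", nm)
    )
  })
  purrr::reduce(tabs, dplyr::full_join, by = c("protein_a", "protein_b"))
}

#' Optimize Fisher integration weights by simulated annealing
#'
#' Searches the weight simplex for the combination that concentrates signal
#' most, without ever seeing experimental evidence: the objective is the
#' excess of significant discoveries over the uniform-null expectation,
#' averaged over a ladder of confidence tails (alpha = 1e-2, 1e-3, 1e-4) and
#' expressed as binomial z-scores. Discovery thresholds come from the exact
#' analytic null of the weighted Fisher score (a weighted sum of Exp(1)
#' variables restricted to the methods present on each pair; see
#' [qwexp_tail()]), so the objective needs no gold standard and never touches
#' evidence data. Candidate moves are drawn as a small batch of stratified
#' Monte-Carlo perturbations per temperature step, with geometric cooling,
#' multiple restarts, and a final greedy coordinate polish.
#'
#' @param datasets Named list of normalized prediction tibbles.
#' @param n_steps Annealing temperature steps (default 200); 0 returns the
#'   uniform weights untouched.
#' @param n_proposals Monte-Carlo proposal draws per step (default 5), each
#'   perturbing one weight coordinate in rotation.
#' @param t0 Initial temperature.
#' @param cooling Geometric cooling factor (default 0.95).
#' @param sample_pairs Maximum number of pairs used to evaluate the objective
#'   (default 100000; small samples starve the tail statistic).
#' @param seed Integer seed; the search is deterministic for a fixed seed.
#' @return A `pg_weights` object: `weights` (named, summing to 1),
#'   `objective_value`, and `trace` (tibble of step, objective of the
#'   accepted-best weights, non-decreasing).
#' @export
optimize_weights <- function(datasets, n_steps = 200, n_proposals = 5,
                             t0 = 1, cooling = 0.95, sample_pairs = 100000,
                             seed = NULL) {
  stopifnot(length(datasets) >= 2)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("method", seq_along(datasets))
  }
  k <- length(datasets)
  joined <- join_pvalues(datasets)
  pmat <- as.matrix(joined[, names(datasets), drop = FALSE])
  if (all(rowSums(!is.na(pmat)) < 2)) {
    stop("datasets have no overlapping pair coverage", call. = FALSE)
  }
  with_seed(seed, {
    if (nrow(pmat) > sample_pairs) {
      pmat <- pmat[sample.int(nrow(pmat), sample_pairs), , drop = FALSE]
    }
    nl <- -log(pmat)
    present <- !is.na(nl)
    nl[!present] <- 0
    # pairs with the same pattern of present methods share one null, so the
    # tail counts need only one quantile per pattern and alpha
    pattern <- apply(present, 1, function(r) paste(which(r), collapse = ","))
    by_pattern <- split(seq_len(nrow(nl)), pattern)
    pattern_sets <- lapply(names(by_pattern), function(p) {
      as.integer(strsplit(p, ",", fixed = TRUE)[[1]])
    })
    alphas <- c(1e-2, 1e-3, 1e-4)
    n <- nrow(nl)
    objective <- function(w) {
      s <- as.numeric(nl %*% w)
      hits <- numeric(length(alphas))
      for (pi in seq_along(pattern_sets)) {
        mset <- pattern_sets[[pi]]
        if (length(mset) == 0) next
        wp <- w[mset]
        wp <- wp[wp > 0]
        if (length(wp) == 0) next
        t_a <- qwexp_tail(alphas, wp)
        sp <- s[by_pattern[[pi]]]
        hits <- hits + vapply(t_a, function(t) sum(sp >= t), numeric(1))
      }
      mean((hits - alphas * n) / sqrt(alphas * (1 - alphas) * n))
    }
    anneal <- function(w0) {
      w <- w0
      obj <- objective(w)
      best_w <- w
      best_obj <- obj
      trace <- tibble::tibble(step = 0L, objective = best_obj)
      temp <- t0
      for (step in seq_len(n_steps)) {
        cands <- lapply(seq_len(n_proposals), function(j) {
          wc <- w
          i <- (step + j - 2) %% k + 1   # stratified: rotate the coordinate
          wc[i] <- wc[i] * exp(stats::rnorm(1, sd = 0.4))
          wc / sum(wc)
        })
        cand_obj <- vapply(cands, objective, numeric(1))
        jbest <- which.max(cand_obj)
        delta <- cand_obj[jbest] - obj
        if (delta > 0 || stats::runif(1) < exp(delta / temp)) {
          w <- cands[[jbest]]
          obj <- cand_obj[jbest]
          if (obj > best_obj) {
            best_obj <- obj
            best_w <- w
          }
        }
        trace <- dplyr::bind_rows(
          trace, tibble::tibble(step = step, objective = best_obj)
        )
        temp <- temp * cooling
      }
      list(w = best_w, obj = best_obj, trace = trace)
    }
    uniform <- rep(1 / k, k)
    if (n_steps == 0) {
      best <- list(w = uniform, obj = objective(uniform),
                   trace = tibble::tibble(step = 0L,
                                          objective = objective(uniform)))
    } else {
      # multi-start: uniform plus random simplex points guard against the
      # chain freezing in a local basin
      starts <- c(list(uniform), lapply(1:2, function(i) {
        d <- stats::rexp(k)
        d / sum(d)
      }))
      runs <- lapply(starts, anneal)
      best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "obj"))]]
      # deterministic polish: greedy coordinate moves until no factor helps
      for (sweep in 1:3) {
        improved <- FALSE
        for (i in seq_len(k)) {
          for (f in c(0.5, 0.8, 1.25, 2)) {
            wc <- best$w
            wc[i] <- wc[i] * f
            wc <- wc / sum(wc)
            oc <- objective(wc)
            if (oc > best$obj) {
              best$w <- wc
              best$obj <- oc
              improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
      best$trace <- dplyr::bind_rows(
        best$trace,
        tibble::tibble(step = max(best$trace$step) + 1L, objective = best$obj)
      )
    }
    structure(
      list(weights = stats::setNames(best$w / sum(best$w), names(datasets)),
           objective_value = best$obj, trace = best$trace),
      class = "pg_weights"
    )
  })
}

#' @export
print.pg_weights <- function(x, ...) {
  cat("<pg_weights> objective =", signif(x$objective_value, 5), "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Upper-tail probability of a weighted sum of unit exponentials
#'
#' Null distribution of a weighted Fisher score under uniform p-values:
#' `S = sum w_i E_i` with `E_i ~ Exp(1)`. Exact for a single weight
#' (exponential) and for equal weights (gamma); otherwise the Lugannani-Rice
#' saddlepoint approximation, which stays accurate deep in the tail where a
#' moment-matched gamma is badly skew-biased for unequal weights.
#'
#' @param q Quantile (score value), scalar or vector.
#' @param w Positive weights.
#' @return `P(S > q)`.
#' @export
pwexp_tail <- function(q, w) {
  stopifnot(all(w > 0), length(w) >= 1)
  vapply(q, function(x) {
    if (x <= 0) return(1)
    if (length(w) == 1) {
      return(exp(-x / w))
    }
    if (max(w) - min(w) < 1e-12) {
      return(stats::pgamma(x, shape = length(w), rate = 1 / w[1],
                           lower.tail = FALSE))
    }
    if (abs(x - sum(w)) < 1e-9 * sum(w)) return(0.5)  # saddle at the mean
    wexp_saddle(x, w)$p
  }, numeric(1))
}

# Lugannani-Rice tail of sum(w_i Exp(1)) at x, with the saddlepoint t_hat.
# K(t) = -sum log(1 - w t); K\'(t) = x is solved by safeguarded Newton.
wexp_saddle <- function(x, w) {
  tmax <- 1 / max(w)
  kp <- function(t) sum(w / (1 - w * t))
  kpp <- function(t) sum(w^2 / (1 - w * t)^2)
  upper <- tmax * (1 - 1e-9)
  lower <- -1e6
  if (kp(lower) >= x) return(list(p = 1, t_hat = lower))
  t_hat <- 0
  for (it in 1:50) {
    delta <- (kp(t_hat) - x) / kpp(t_hat)
    t_new <- t_hat - delta
    if (t_new >= upper || t_new <= lower) {
      t_new <- (t_hat + if (delta < 0) upper else lower) / 2
    }
    if (abs(t_new - t_hat) < 1e-12 * max(1, abs(t_hat))) {
      t_hat <- t_new
      break
    }
    t_hat <- t_new
  }
  k_val <- -sum(log1p(-w * t_hat))
  wh <- sign(t_hat) * sqrt(2 * (t_hat * x - k_val))
  uh <- t_hat * sqrt(kpp(t_hat))
  p <- stats::pnorm(wh, lower.tail = FALSE) -
    stats::dnorm(wh) * (1 / wh - 1 / uh)
  list(p = min(max(p, 1e-300), 1), t_hat = t_hat)
}

#' Upper-tail quantiles of a weighted sum of unit exponentials
#'
#' Inverse of [pwexp_tail()]: the score threshold exceeded with probability
#' `alpha` under the null.
#'
#' @param alpha Tail probabilities.
#' @param w Positive weights.
#' @return Thresholds, one per `alpha`.
#' @export
qwexp_tail <- function(alpha, w) {
  stopifnot(all(w > 0))
  if (length(w) == 1) return(-w * log(alpha))
  if (max(w) - min(w) < 1e-12) {
    return(stats::qgamma(alpha, shape = length(w), rate = 1 / w[1],
                         lower.tail = FALSE))
  }
  mu <- sum(w)
  v <- sum(w^2)
  shape <- mu^2 / v
  vapply(alpha, function(a) {
    # Newton on log P(S > x) = log a; d log P / dx is the saddlepoint -t_hat,
    # warm-started from the moment-matched gamma quantile
    x <- stats::qgamma(a, shape = shape, rate = shape / mu,
                       lower.tail = FALSE)
    for (it in 1:40) {
      sp <- wexp_saddle(x, w)
      step <- (log(sp$p) - log(a)) / sp$t_hat
      x_new <- x + step
      if (x_new <= 0) x_new <- x / 2
      if (abs(x_new - x) < 1e-9 * max(1, x)) {
        x <- x_new
        break
      }
      x <- x_new
    }
    x
  }, numeric(1))
}

#' Mutual information between two prediction datasets
#'
#' Measures statistical dependence between two methods over their shared
#' pairs: p-values are rank-binned into `n_bins` equal-frequency classes and
#' the MI of the joint bin distribution is returned in bits. Rank binning
#' makes the measure invariant to monotone transforms; a dataset against
#' itself yields `log2(n_bins)`.
#'
#' @param a,b Prediction tibbles with `protein_a`, `protein_b`, `p_value`.
#' @param n_bins Equal-frequency bins (default 10).
#' @return MI in bits (>= 0).
#' @export
mutual_information <- function(a, b, n_bins = 10) {
  keys_a <- pair_key(a$protein_a, a$protein_b)
  keys_b <- pair_key(b$protein_a, b$protein_b)
  idx <- match(keys_a, keys_b)
  shared <- !is.na(idx)
  if (sum(shared) < 100) {
    stop("insufficient overlap: < 100 shared pairs", call. = FALSE)
  }
  x <- a$p_value[shared]
  y <- b$p_value[idx[shared]]
  bx <- dplyr::ntile(x, n_bins)
  by <- dplyr::ntile(y, n_bins)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  max(0, sum(terms[joint > 0]))
}

#' Pairwise mutual-information matrix of prediction datasets
#'
#' @param datasets Named list of normalized prediction tibbles.
#' @param n_bins Equal-frequency bins.
#' @return Symmetric matrix of MI values in bits (NA where the overlap is
#'   below 100 pairs).
#' @export
mutual_information_matrix <- function(datasets, n_bins = 10) {
  k <- length(datasets)
  m <- matrix(NA_real_, k, k, dimnames = list(names(datasets), names(datasets)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      mi <- tryCatch(mutual_information(datasets[[i]], datasets[[j]], n_bins),
                     error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- mi
    }
  }
  m
}
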