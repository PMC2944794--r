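#' Precision/recall curve against a random-model false-positive estimator
#'
#' Precision at a threshold is `TP / (TP + FP)` where TP counts predictions in
#' the gold standard and FP is the *average* number of predictions hitting a
#' random pair set of the same size as the gold standard, redrawn
#' `n_random` times uniformly over the node universe (self-pairs excluded).
#' Because the random sets match the gold set's size, a ranking with no signal
#' tends to precision 0.5, and precision 0.9 means nine times more true hits
#' than a random predictor finds by chance. Recall is the cumulative number of
#' predicted hits at the threshold (false-negative rates are not estimable
#' when the true network is unknown).
#'
#' @param predictions Tibble `protein_a`, `protein_b`, `p_value` (canonical,
#'   unique pairs; lower p = stronger prediction). For score-ranked inputs use
#'   `direction = "descending"` with a `score` column.
#' @param gold Tibble of gold-standard pairs (`protein_a`, `protein_b`).
#' @param node_universe Character vector of proteins defining the random-pair
#'   universe; defaults to the union of prediction and gold endpoints.
#' @param n_random Random models per threshold (default 1000).
#' @param seed Integer seed.
#' @param max_points Cap on evaluated thresholds; distinct values beyond the
#'   cap are thinned to uniform quantiles.
#' @param direction `"ascending"` thresholds a `p_value` column at `<= t`;
#'   `"descending"` thresholds a `score` column at `>= t`.
#' @return A `pg_pr_curve` tibble: `threshold`, `recall`, `tp`, `fp_mean`,
#'   `fp_sd`, `precision`; attributes `n_random`, `seed`, `n_gold`.
#' @export
precision_recall <- function(predictions, gold, node_universe = NULL,
                             n_random = 1000, seed = NULL, max_points = 10000,
                             direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  value_col <- if (direction == "ascending") "p_value" else "score"
  stopifnot(value_col %in% names(predictions))
  if (nrow(gold) == 0) stop("gold standard is empty", call. = FALSE)
  pred_keys <- pair_key(predictions$protein_a, predictions$protein_b)
  if (anyDuplicated(pred_keys)) {
    stop("duplicate pairs in predictions", call. = FALSE)
  }
  v <- predictions[[value_col]]
  if (direction == "descending") v <- -v
  if (is.null(node_universe)) {
    node_universe <- sort(unique(c(predictions$protein_a, predictions$protein_b,
                                   gold$protein_a, gold$protein_b)))
  }
  gold_keys <- unique(pair_key(gold$protein_a, gold$protein_b))
  n_gold <- length(gold_keys)
  if (n_gold > n_unordered_pairs(length(node_universe))) {
    stop("gold set larger than the pair universe", call. = FALSE)
  }
  thresholds <- sort(unique(v))
  if (length(thresholds) > max_points) {
    thresholds <- unique(stats::quantile(
      thresholds, probs = seq(0, 1, length.out = max_points), names = FALSE,
      type = 1
    ))
  }
  v_sorted <- sort(v)
  recall <- findInterval(thresholds, v_sorted)
  tp_values <- sort(v[pred_keys %in% gold_keys])
  tp <- findInterval(thresholds, tp_values)
  lookup <- stats::setNames(v, pred_keys)
  hit_counts <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      rnd <- sample_pairs(node_universe, n_gold)
      hits <- lookup[pair_key(rnd$protein_a, rnd$protein_b)]
      hits <- sort(hits[!is.na(hits)])
      findInterval(thresholds, hits)
    }, numeric(length(thresholds)))
  })
  hit_counts <- matrix(hit_counts, nrow = length(thresholds))
  fp_mean <- rowMeans(hit_counts)
  fp_sd <- apply(hit_counts, 1, stats::sd)
  denom <- tp + fp_mean
  out <- tibble::tibble(
    threshold = if (direction == "ascending") thresholds else -thresholds,
    recall = recall, tp = tp, fp_mean = fp_mean, fp_sd = fp_sd,
    precision = ifelse(denom > 0, tp / denom, NA_real_)
  )
  structure(out, n_random = n_random, seed = seed, n_gold = n_gold,
            direction = direction,
            class = c("pg_pr_curve", class(out)))
}

#' Cumulative predicted hits at a threshold
#'
#' @param predictions Tibble with a `p_value` column.
#' @param threshold p-value cutoff.
#' @return Number of predictions with `p_value <= threshold`.
#' @export
recall_count <- function(predictions, threshold) {
  sum(predictions$p_value <= threshold)
}

#' Prediction power: area under the precision-recall curve
#'
#' Trapezoidal area of precision over recall, anchored at recall 0 with the
#' first point's precision and normalized by the maximum recall, so a constant
#' precision of 0.8 over the full recall range has power 0.8. When ranking
#' methods with different coverage against each other, pass a common
#' `max_recall` (e.g. the smallest of the methods' total hit counts) so every
#' curve is integrated over the same recall window; otherwise a short, pure
#' list is favoured over a longer one that is better at every shared depth.
#'
#' @param curve A [precision_recall()] curve.
#' @param max_recall Optional common recall cap and normalizer; defaults to
#'   the curve's own maximum recall.
#' @return The area (a single number); for a degenerate single-point curve,
#'   that point's precision.
#' @export
prediction_power <- function(curve, max_recall = NULL) {
  pts <- curve[!is.na(curve$precision), ]
  if (!is.null(max_recall)) pts <- pts[pts$recall <= max_recall, ]
  if (nrow(pts) == 0) return(NA_real_)
  if (nrow(pts) == 1) return(pts$precision)
  r <- pts$recall / (max_recall %||% max(pts$recall))
  ord <- order(r)
  r <- c(0, r[ord])
  p <- pts$precision[ord]
  p <- c(p[1], p)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Drop unstable curve points
#'
#' Points whose random-model FP standard deviation exceeds one third of the
#' mean FP are removed; these arise from tiny samples at the head of the
#' cumulative distributions. The boundary (sd exactly mean/3) is kept.
#'
#' @param curve A [precision_recall()] curve.
#' @return The filtered curve (attributes preserved).
#' @export
filter_unstable <- function(curve) {
  keep <- !(curve$fp_sd > curve$fp_mean / 3)
  out <- curve[keep, ]
  attributes(out)[c("n_random", "seed", "n_gold", "direction")] <-
    attributes(curve)[c("n_random", "seed", "n_gold", "direction")]
  class(out) <- class(curve)
  out
}
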