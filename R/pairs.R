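#' Canonicalize unordered protein pairs
#'
#' Unordered pairs are stored with the lexicographically smaller identifier
#' first, so that set operations on pair tables are well defined. Self-pairs
#' (a protein paired with itself) are dropped with a warning.
#'
#' @param x A data frame with at least the two identifier columns.
#' @param a,b Names of the two identifier columns.
#' @param quiet Suppress the dropped self-pair warning.
#' @return A tibble with the same columns, pairs canonicalized and self-pairs
#'   removed.
#' @export
canonicalize_pairs <- function(x, a = "protein_a", b = "protein_b", quiet = FALSE) {
  x <- tibble::as_tibble(x)
  stopifnot(a %in% names(x), b %in% names(x))
  pa <- as.character(x[[a]])
  pb <- as.character(x[[b]])
  x[[a]] <- pmin(pa, pb)
  x[[b]] <- pmax(pa, pb)
  self <- x[[a]] == x[[b]]
  if (any(self)) {
    if (!quiet) {
      warning(sum(self), " self-pair(s) dropped during canonicalization",
              call. = FALSE)
    }
    x <- x[!self, , drop = FALSE]
  }
  x
}

#' Canonical key strings for unordered pairs
#'
#' Joins the two identifiers in canonical (sorted) order so that unordered
#' pairs can be compared with plain set operations. Identifiers must not
#' contain the carriage-return separator.
#'
#' @param a,b Character vectors of protein identifiers.
#' @return Character vector of keys, one per pair.
#' @export
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

key_to_pair <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  tibble::tibble(
    protein_a = vapply(parts, `[[`, character(1), 1L),
    protein_b = vapply(parts, `[[`, character(1), 2L)
  )
}

#' Number of unordered pairs over n items
#' @param n Item count.
#' @return `n * (n - 1) / 2` as a double.
#' @keywords internal
n_unordered_pairs <- function(n) n * (n - 1) / 2

# Convert linear pair indices (1..n(n-1)/2) into (i, j) with i < j, where
# pairs are enumerated row-wise: (1,2), (1,3), ..., (1,n), (2,3), ...
# Works in doubles; exact while n(n-1)/2 < 2^53.
unrank_pairs <- function(k, n) {
  k <- as.numeric(k)
  # cumulative pairs up to and including row i: C(i) = i*n - i*(i+1)/2
  i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2) + 1
  # guard floating-point off-by-one
  cum_prev <- function(i) (i - 1) * n - (i - 1) * i / 2
  too_high <- cum_prev(i) >= k
  while (any(too_high)) {
    i[too_high] <- i[too_high] - 1
    too_high <- cum_prev(i) >= k
  }
  too_low <- cum_prev(i + 1) < k
  while (any(too_low)) {
    i[too_low] <- i[too_low] + 1
    too_low <- cum_prev(i + 1) < k
  }
  j <- k - cum_prev(i) + i
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Sample distinct unordered pairs uniformly from a protein universe
#'
#' Draws `size` distinct pairs (no self-pairs by construction) by unranking
#' uniform draws over the pair index space, optionally rejecting an excluded
#' key set.
#'
#' @param proteins Character vector of protein identifiers.
#' @param size Number of pairs to draw.
#' @param exclude_keys Optional [pair_key()] values to avoid.
#' @return A tibble of canonical pairs.
#' @export
sample_pairs <- function(proteins, size, exclude_keys = NULL) {
  n <- length(proteins)
  m <- n_unordered_pairs(n)
  if (m >= 2^31) {
    stop("pair universe too large for exact sampling (", m, " pairs)",
         call. = FALSE)
  }
  if (size > m) stop("requested more pairs than the universe holds", call. = FALSE)
  proteins <- sort(proteins)
  if (is.null(exclude_keys)) {
    idx <- sample.int(m, size)
  } else {
    # rejection sampling against the excluded set
    idx <- integer(0)
    while (length(idx) < size) {
      cand <- sample.int(m, min(m, ceiling((size - length(idx)) * 1.5) + 10))
      ij <- unrank_pairs(cand, n)
      keys <- pair_key(proteins[ij[, 1]], proteins[ij[, 2]])
      keep <- !(keys %in% exclude_keys)
      idx <- unique(c(idx, cand[keep]))
    }
    idx <- idx[seq_len(size)]
  }
  ij <- unrank_pairs(idx, n)
  tibble::tibble(protein_a = proteins[ij[, 1]], protein_b = proteins[ij[, 2]])
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
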