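#' Construct an ontology DAG
#'
#' A minimal is_a ontology: terms with names plus child-to-parent links. The
#' graph must be acyclic and every non-root term must reach a root.
#'
#' @param terms Tibble with columns `id`, `name`.
#' @param edges Tibble with columns `child`, `parent` (is_a links).
#' @return A `pg_ontology` list with `terms`, `edges` and `roots`.
#' @export
new_ontology <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "name") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown) > 0) {
    stop("is_a links reference unknown terms: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  roots <- setdiff(terms$id, edges$child)
  if (length(roots) == 0) stop("ontology has no root (cycle?)", call. = FALSE)
  onto <- structure(list(terms = terms, edges = edges, roots = roots),
                    class = "pg_ontology")
  # cycle check: ancestor closure must terminate
  invisible(ontology_ancestors(onto))
  onto
}

#' @export
print.pg_ontology <- function(x, ...) {
  cat("<pg_ontology> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " is_a links, root(s): ", paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ancestor closure of every term
#'
#' @param ontology A `pg_ontology`.
#' @return Named list: for each term id, the character vector of its ancestors
#'   *including the term itself*.
#' @export
ontology_ancestors <- function(ontology) {
  ids <- ontology$terms$id
  parents <- split(ontology$edges$parent, ontology$edges$child)
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    if (!is.null(visiting[[id]])) stop("cycle detected at term ", id, call. = FALSE)
    visiting[[id]] <- TRUE
    up <- parents[[id]]
    res <- if (is.null(up)) id else unique(c(id, unlist(lapply(up, anc))))
    rm(list = id, envir = visiting)
    memo[[id]] <- res
    res
  }
  out <- lapply(ids, anc)
  names(out) <- ids
  out
}

#' Descendant closure of every term (including the term itself)
#' @param ontology A `pg_ontology`.
#' @return Named list of descendant id vectors.
#' @export
ontology_descendants <- function(ontology) {
  anc <- ontology_ancestors(ontology)
  ids <- ontology$terms$id
  pairs <- tibble::tibble(
    term = rep(names(anc), lengths(anc)),
    ancestor = unlist(anc, use.names = FALSE)
  )
  desc <- split(pairs$term, pairs$ancestor)
  out <- lapply(ids, function(id) unique(desc[[id]]))
  names(out) <- ids
  out
}

# Protein -> set of terms annotating it after upward propagation.
propagate_annotations <- function(annotations, ontology) {
  anc <- ontology_ancestors(ontology)
  unknown <- setdiff(annotations$term, names(anc))
  if (length(unknown) > 0) {
    stop("annotations reference unknown terms: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  expanded <- tibble::tibble(
    protein = rep(annotations$protein, lengths(anc[annotations$term])),
    term = unlist(anc[annotations$term], use.names = FALSE)
  )
  dplyr::distinct(expanded)
}

#' Information content of ontology terms
#'
#' Annotations are propagated upward (a protein annotated to a term is counted
#' for all its ancestors), then `IC(t) = -ln(n_t / n_total)` where `n_t` is the
#' number of proteins annotated to `t` or a descendant and `n_total` the number
#' of annotated proteins. The root therefore has IC 0; rarer terms are more
#' informative.
#'
#' @param annotations Tibble with columns `protein`, `term`.
#' @param ontology A `pg_ontology`.
#' @return Tibble `term`, `n_annotated`, `ic` (nats); terms never reached by
#'   any annotation have `ic = NA`.
#' @export
term_information_content <- function(annotations, ontology) {
  prop <- propagate_annotations(annotations, ontology)
  total <- dplyr::n_distinct(prop$protein)
  counts <- dplyr::count(prop, .data$term, name = "n_annotated")
  out <- dplyr::left_join(ontology$terms["id"], counts,
                          by = c(id = "term"))
  out$n_annotated[is.na(out$n_annotated)] <- 0L
  out$ic <- ifelse(out$n_annotated > 0, -log(out$n_annotated / total), NA_real_)
  stats::setNames(out, c("term", "n_annotated", "ic"))
}

#' Look up a single term's IC
#' @param term Term id.
#' @inheritParams term_information_content
#' @return IC in nats.
#' @export
term_ic <- function(term, annotations, ontology) {
  ic <- term_information_content(annotations, ontology)
  row <- ic[ic$term == term, ]
  if (nrow(row) == 0) stop("unknown term ", term, call. = FALSE)
  if (is.na(row$ic)) stop("term ", term, " has no annotations: IC undefined",
                          call. = FALSE)
  row$ic
}

#' Dense all-vs-all Resnik (max-MICA) similarity matrix
#'
#' Walks terms by decreasing information content; the first term common to two
#' proteins' propagated annotation sets is their most informative common
#' ancestor, so unfilled cells take that term's IC. Cells left `NA` have no
#' common ancestor (score 0 by convention).
#'
#' @param proteins Proteins to score (unannotated ones are dropped).
#' @param annotations Tibble `protein`, `term`.
#' @param ontology A `pg_ontology`.
#' @param ic Optional precomputed [term_information_content()] table.
#' @return A symmetric numeric matrix with protein row/column names.
#' @export
resnik_matrix <- function(proteins, annotations, ontology, ic = NULL) {
  if (is.null(ic)) ic <- term_information_content(annotations, ontology)
  prop <- propagate_annotations(annotations, ontology)
  prop <- prop[prop$protein %in% proteins, ]
  proteins <- sort(intersect(proteins, unique(prop$protein)))
  n <- length(proteins)
  res <- matrix(NA_real_, n, n, dimnames = list(proteins, proteins))
  by_term <- split(prop$protein, prop$term)
  ic <- ic[!is.na(ic$ic), ]
  ord <- order(ic$ic, decreasing = TRUE)
  for (t in ic$term[ord]) {
    members <- by_term[[t]]
    if (is.null(members) || length(members) < 1) next
    idx <- match(members, proteins)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 1) next
    block <- res[idx, idx, drop = FALSE]
    block[is.na(block)] <- ic$ic[match(t, ic$term)]
    res[idx, idx] <- block
  }
  res
}

#' Resnik semantic similarity of two proteins
#'
#' The similarity is the information content of the most informative common
#' ancestor (MICA) over the two proteins' annotation term pairs: with
#' `aggregate = "max"` (default) the best term pair defines the score, with
#' `"avg"` the mean MICA IC over all term pairs is returned.
#'
#' @param protein_1,protein_2 Protein identifiers.
#' @param annotations Tibble `protein`, `term`.
#' @param ontology A `pg_ontology`.
#' @param aggregate `"max"` or `"avg"`.
#' @return Similarity in nats (0 when only a root is shared); `NA` if either
#'   protein is unannotated.
#' @export
resnik_similarity <- function(protein_1, protein_2, annotations, ontology,
                              aggregate = c("max", "avg")) {
  aggregate <- match.arg(aggregate)
  ic <- term_information_content(annotations, ontology)
  ic_of <- stats::setNames(ic$ic, ic$term)
  anc <- ontology_ancestors(ontology)
  terms1 <- annotations$term[annotations$protein == protein_1]
  terms2 <- annotations$term[annotations$protein == protein_2]
  if (length(terms1) == 0 || length(terms2) == 0) return(NA_real_)
  mica <- function(t1, t2) {
    common <- intersect(anc[[t1]], anc[[t2]])
    if (length(common) == 0) return(0)
    max(ic_of[common], 0, na.rm = TRUE)
  }
  grid <- expand.grid(t1 = terms1, t2 = terms2, stringsAsFactors = FALSE)
  vals <- mapply(mica, grid$t1, grid$t2)
  if (aggregate == "max") max(vals) else mean(vals)
}

#' Build the thresholded semantic pair set
#'
#' Scores all pairs of annotated proteins by Resnik similarity and keeps those
#' at or above the threshold. With natural-log IC the conventional 4.0 cutoff
#' retains pairs whose most informative common ancestor annotates at most
#' `exp(-4)` (about 1.8%) of the proteome. The same operation builds both the
#' refined validation gold standard and the ontology-derived evidence sets of
#' a Knowledgegram.
#'
#' @param proteome Character vector of proteins to consider.
#' @param annotations Tibble `protein`, `term`.
#' @param ontology A `pg_ontology`.
#' @param threshold Minimum similarity (nats), default 4.0.
#' @return A tibble `protein_a`, `protein_b`, `goss` (class `pg_pairset`,
#'   attribute `threshold`); unannotated proteins are excluded and reported via
#'   attribute `excluded`.
#' @export
build_semantic_pairset <- function(proteome, annotations, ontology,
                                   threshold = 4.0) {
  annotated <- intersect(proteome, unique(annotations$protein))
  excluded <- setdiff(proteome, annotated)
  if (length(annotated) < 2) {
    stop("need at least two annotated proteins", call. = FALSE)
  }
  m <- resnik_matrix(annotated, annotations, ontology)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  score <- m[idx]
  score[is.na(score)] <- 0
  keep <- score >= threshold
  out <- tibble::tibble(
    protein_a = rownames(m)[idx[keep, 1]],
    protein_b = rownames(m)[idx[keep, 2]],
    goss = score[keep]
  )
  out <- canonicalize_pairs(out, quiet = TRUE)
  out <- dplyr::arrange(out, .data$protein_a, .data$protein_b)
  structure(out, threshold = threshold, excluded = excluded,
            class = c("pg_pairset", class(out)))
}
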