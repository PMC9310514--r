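#' Edge weights for Wang semantic similarity
#'
#' The semantic-contribution factors for the two edge types entering the
#' similarity DAG. The defaults (0.8 for `is_a`, 0.6 for `part_of`) are
#' the values of the original Wang et al. (2007) method.
#'
#' @param is_a Weight of `is_a` edges, in (0,1).
#' @param part_of Weight of `part_of` edges, in (0,1).
#' @return A list of class `semantic_weights`.
#' @export
semantic_weights <- function(is_a = 0.8, part_of = 0.6) {
  if (is_a <= 0 || is_a >= 1 || part_of <= 0 || part_of >= 1)
    stop("weights must lie strictly between 0 and 1")
  structure(list(is_a = is_a, part_of = part_of), class = "semantic_weights")
}

# S-values of a term over its ancestor DAG: S(t)=1 for the term itself;
# for an ancestor a, S(a) = max over child edges (a <- c on a path from t)
# of w_edge * S(c). Computed by relaxation over parent edges, which
# terminates because the graph is acyclic and weights are < 1.
wang_svalues <- function(ont, term, weights = semantic_weights()) {
  .check_id(ont, term)
  s <- stats::setNames(1.0, term)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character()
    for (v in frontier) {
      pe <- ont$parents[[v]]
      if (is.null(pe) || nrow(pe) == 0) next
      for (i in seq_len(nrow(pe))) {
        p <- pe$parent[i]
        w <- if (pe$relation[i] == "is_a") weights$is_a else weights$part_of
        cand <- w * s[[v]]
        if (is.na(s[p]) || cand > s[[p]]) {
          s[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Wang semantic similarity between two GO terms
#'
#' DAG-based similarity of Wang et al. (2007): each term's ancestors
#' receive S-values discounted along the best path by per-edge weights;
#' the similarity is the summed S-values of the shared ancestors (from
#' both sides) over the total semantic values of the two terms. Equals 1
#' for identical terms and 0 when the ancestor sets are disjoint.
#'
#' @param ont A [go_ontology()].
#' @param t1,t2 Term ids in the same namespace.
#' @param weights A [semantic_weights()].
#' @return Similarity in `[0, 1]`.
#' @export
wang_similarity <- function(ont, t1, t2, weights = semantic_weights()) {
  .check_id(ont, t1); .check_id(ont, t2)
  if (ont$namespace[[t1]] != ont$namespace[[t2]])
    stop("terms belong to different namespaces: ", t1, " vs ", t2)
  s1 <- wang_svalues(ont, t1, weights)
  s2 <- wang_svalues(ont, t2, weights)
  shared <- intersect(names(s1), names(s2))
  if (length(shared) == 0) return(0)
  (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
}

#' Coverage of a reference annotation set by predicted terms
#'
#' All predicted x reference similarities are computed; pairs with Wang
#' similarity at or above `threshold` count as matched, and the coverage
#' is the percentage of unique reference terms appearing in at least one
#' matched pair.
#'
#' @param pred_terms Character vector of predicted term ids (may be
#'   empty, giving coverage 0).
#' @param ref_terms Non-empty character vector of reference term ids.
#' @param ont A [go_ontology()].
#' @param threshold Similarity threshold, compared with `>=`.
#' @param weights A [semantic_weights()].
#' @param complex_id Optional id carried on the report.
#' @return A `coverage_report`: list with `complex_id`, `M_ref`,
#'   `N_matched` and `coverage_percent`.
#' @export
go_coverage <- function(pred_terms, ref_terms, ont, threshold = 0.5,
                        weights = semantic_weights(), complex_id = NA_character_) {
  if (length(ref_terms) == 0) stop("reference term set is empty")
  ref_terms <- unique(ref_terms)
  pred_terms <- unique(pred_terms)
  for (t in ref_terms) .check_id(ont, t)
  matched <- logical(length(ref_terms))
  for (j in seq_along(ref_terms)) {
    for (p in pred_terms) {
      if (ont$namespace[[p]] != ont$namespace[[ref_terms[j]]]) next
      if (wang_similarity(ont, p, ref_terms[j], weights) >= threshold) {
        matched[j] <- TRUE
        break
      }
    }
  }
  structure(list(complex_id = complex_id,
                 M_ref = length(ref_terms),
                 N_matched = sum(matched),
                 coverage_percent = 100 * sum(matched) / length(ref_terms)),
            class = "coverage_report")
}
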