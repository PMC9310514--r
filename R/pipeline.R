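#' Annotate one protein complex end to end
#'
#' Convenience wrapper running the whole prediction pipeline for a
#' single complex query: compose the query vector, retrieve the full
#' nearest-neighbour ranking per namespace, score every term with the
#' per-namespace classifiers, and consolidate the two lists via the
#' child-term enrichment test.
#'
#' @param name Complex name (canonical name, or space-separated subunit
#'   names under the subunit scheme).
#' @param scheme `"subunit"` or `"canonical"`.
#' @param model An [embedding_model()].
#' @param indexes Named list (`biological_process`, `molecular_function`,
#'   `cellular_component`) of `nn_index`es over the GO sub-embeddings.
#' @param classifiers Named list of `trained_classifier`s, same names.
#' @param ont A [go_ontology()].
#' @param N_sample Enrichment sample sizes (see [consolidate()]).
#' @param threshold,cap Passed to [predict_rf_list()].
#' @param ... Further arguments passed to [consolidate()] (e.g.
#'   `protein_annotations`, `subunits`, `alpha`).
#' @return A `prediction_bundle`.
#' @export
annotate_complex <- function(name, scheme = c("subunit", "canonical"),
                             model, indexes, classifiers, ont,
                             N_sample = default_sample_sizes(),
                             threshold = 0.5, cap = 10L, ...) {
  scheme <- match.arg(scheme)
  nss <- c("biological_process", "molecular_function", "cellular_component")
  stopifnot(all(nss %in% names(indexes)), all(nss %in% names(classifiers)))
  qv <- compose_query_vector(model, name, scheme)
  nn_rankings <- list(); rf_lists <- list()
  for (ns in nss) {
    idx <- indexes[[ns]]
    nn_rankings[[ns]] <- query_nn(idx, qv, k = length(idx$names))
    sub <- structure(list(scheme = "canonical", names = idx$names,
                          ids = idx$ids, matrix = idx$matrix,
                          skipped = character(0)),
                     class = "sub_embedding")
    rf_lists[[ns]] <- predict_rf_list(classifiers[[ns]], qv, sub,
                                      threshold = threshold, cap = cap)
  }
  consolidate(name, rf_lists, nn_rankings, ont, N_sample = N_sample, ...)
}
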