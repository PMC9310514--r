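#' Build a sub-embedding for a set of names
#'
#' Vectorizes each name with [compose_query_vector()] and stacks the
#' unit-norm vectors into a matrix whose rows align with the names.
#' Names that resolve to no known token are reported in the skip list
#' and omitted from the matrix.
#'
#' @param model An [embedding_model()].
#' @param names Character vector of names (must be unique).
#' @param scheme Naming scheme tag (`"canonical"` or `"subunit"`).
#' @param ids Optional vector of ids (e.g. GO accessions) aligned with
#'   `names`; carried through to query results.
#' @return A `sub_embedding`: list with `scheme`, `names`, `ids`,
#'   unit-norm row `matrix` and `skipped` (names that failed to resolve).
#' @export
build_sub_embedding <- function(model, names, scheme = c("canonical", "subunit"),
                                ids = NULL) {
  scheme <- match.arg(scheme)
  if (length(names) == 0) stop("`names` is empty")
  dup <- names[duplicated(names)]
  if (length(dup) > 0)
    stop("duplicate name(s) in input: ", paste(unique(dup), collapse = ", "))
  if (!is.null(ids) && length(ids) != length(names))
    stop("`ids` must align with `names`")
  vecs <- vector("list", length(names))
  keep <- logical(length(names))
  for (i in seq_along(names)) {
    v <- tryCatch(compose_query_vector(model, names[i], scheme),
                  pcgo_unresolvable = function(e) NULL)
    if (!is.null(v)) {
      vecs[[i]] <- v$vector
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) stop("no resolvable names in input")
  mat <- do.call(rbind, vecs[keep])
  rownames(mat) <- names[keep]
  structure(list(scheme = scheme,
                 names = names[keep],
                 ids = if (is.null(ids)) names[keep] else ids[keep],
                 matrix = mat,
                 skipped = names[!keep]),
            class = "sub_embedding")
}

#' @method print sub_embedding
#' @export
print.sub_embedding <- function(x, ...) {
  cat(sprintf("sub_embedding (%s): %d names, dim %d, %d skipped\n",
              x$scheme, nrow(x$matrix), ncol(x$matrix), length(x$skipped)))
  invisible(x)
}

#' Build an exact nearest-neighbour index over a sub-embedding
#'
#' Stores the unit-norm rows in a k-d tree. Because all rows are unit
#' vectors, Euclidean nearest-neighbour order equals cosine-similarity
#' order, so one Euclidean index serves cosine retrieval exactly.
#' Distance ties are broken lexicographically by name, deterministically.
#'
#' @param sub A [build_sub_embedding()] result.
#' @return An `nn_index`.
#' @export
build_index <- function(sub) {
  stopifnot(inherits(sub, "sub_embedding"))
  mat <- sub$matrix
  if (nrow(mat) == 0) stop("sub-embedding is empty")
  norms <- sqrt(rowSums(mat^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("rows must be unit-norm for the cosine/Euclidean equivalence; ",
         "offending rows: ",
         paste(utils::head(sub$names[abs(norms - 1) > 1e-9], 5), collapse = ", "))
  lexrank <- rank(sub$names, ties.method = "first") # names unique
  tree <- .kd_build(mat, as.integer(lexrank))
  structure(list(tree = tree, names = sub$names, ids = sub$ids,
                 matrix = mat, scheme = sub$scheme),
            class = "nn_index")
}

#' Query an index for the top-k cosine nearest neighbours
#'
#' @param index An `nn_index`.
#' @param q A `query_vector` (or bare unit-norm numeric vector).
#' @param k Number of neighbours; values above the corpus size return
#'   the full ranking (flagged via the `truncated` attribute).
#' @return An `nn_result` data frame with columns `rank`, `name`, `id`
#'   and `cosine`, scores non-increasing.
#' @export
query_nn <- function(index, q, k) {
  stopifnot(inherits(index, "nn_index"))
  if (k < 1) stop("`k` must be >= 1")
  v <- if (inherits(q, "query_vector")) q$vector else as.numeric(q)
  if (length(v) != ncol(index$matrix)) stop("query dimension mismatch")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-9) stop("query vector must be unit-norm")
  n <- length(index$names)
  k_eff <- min(k, n)
  res <- .kd_query(index$tree, v, as.integer(k_eff))
  out <- data.frame(rank = seq_along(res$id),
                    name = index$names[res$id],
                    id = index$ids[res$id],
                    cosine = 1 - res$dist2 / 2,
                    stringsAsFactors = FALSE)
  class(out) <- c("nn_result", "data.frame")
  attr(out, "truncated") <- k > n
  out
}

#' Smallest k whose top-k neighbours contain a full truth set
#'
#' @param ranking Character vector of names/ids in ranked order (e.g.
#'   `query_nn(...)$name` for a full-corpus query).
#' @param truth Character vector of ground-truth members; every member
#'   must be present in `ranking`.
#' @return Integer: 1 + the 0-based rank of the worst-ranked truth
#'   member.
#' @export
recovery_count <- function(ranking, truth) {
  if (length(truth) == 0) stop("`truth` is empty")
  pos <- match(truth, ranking)
  if (anyNA(pos))
    stop("truth member(s) absent from ranking: ",
         paste(truth[is.na(pos)], collapse = ", "))
  max(pos)
}

#' Mean number of neighbours needed to recover each complex's annotations
#'
#' For every complex in the table, queries the namespace index with the
#' complex query vector and records the number of nearest neighbours
#' needed to recover 100% of its annotated terms; returns the
#' per-complex counts and their arithmetic mean. For a newly trained
#' embedding this mean is the enrichment sample size for the namespace.
#'
#' @param db A complex table (see [read_complex_db()]).
#' @param model An [embedding_model()].
#' @param index An `nn_index` over the namespace GO sub-embedding (ids
#'   must be GO accessions).
#' @param namespace Namespace whose annotations are recovered.
#' @param scheme `"canonical"` (canonical complex name) or `"subunit"`
#'   (space-joined subunit names).
#' @return A `recovery_stats`: list with per-complex `counts` and `mean`.
#' @export
mean_recovery <- function(db, model, index, namespace,
                          scheme = c("subunit", "canonical")) {
  scheme <- match.arg(scheme)
  namespace <- expand_namespace(namespace)
  if (nrow(db) == 0) stop("complex table is empty")
  ann <- complex_annotations(db, namespace)
  counts <- integer(0)
  for (i in seq_len(nrow(db))) {
    truth <- ann[[i]]
    if (length(truth) == 0)
      stop("complex without annotations in ", namespace, ": ", db$complex_id[i])
    qname <- if (scheme == "canonical") db$canonical_name[i]
             else paste(subunit_list(db)[[i]], collapse = " ")
    qv <- compose_query_vector(model, qname, scheme)
    full <- query_nn(index, qv, k = length(index$names))
    counts <- c(counts, recovery_count(full$id, truth))
  }
  structure(list(counts = stats::setNames(counts, db$complex_id),
                 mean = mean(counts), namespace = namespace, scheme = scheme),
            class = "recovery_stats")
}

#' Default enrichment sample sizes for the full-scale embedding
#'
#' Mean numbers of nearest neighbours required to recover all annotated
#' terms of a complex under the subunit naming scheme at full scale, as
#' used for the enrichment sample size N when no freshly computed
#' [mean_recovery()] value is supplied. (Recomputations at full scale
#' also circulate as 11044/5214/1894; the defaults here are the
#' conventional values. Either way they are clamped to the vocabulary
#' size on toy ontologies.)
#'
#' @return Named numeric vector with entries `biological_process`,
#'   `molecular_function`, `cellular_component`.
#' @export
default_sample_sizes <- function() {
  c(biological_process = 11044,
    molecular_function = 5213,
    cellular_component = 1896)
}
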