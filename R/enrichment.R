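#' Hypergeometric survival function
#'
#' `hypergeom_sf(q, M, n, N)` returns `P(X > q)` for
#' `X ~ Hypergeometric(M, n, N)`: a population of `M` terms of which `n`
#' are "successes" (the descendants of a supervised term plus the term
#' itself), sampled `N` times without replacement. The enrichment
#' p-value is the survival function evaluated at `x - 1`, i.e.
#' `P(X >= x)`.
#'
#' @param q Quantile (typically `x - 1`).
#' @param M Population size (namespace vocabulary size).
#' @param n Number of successes in the population.
#' @param N Sample size drawn.
#' @return `P(X > q)`, a probability in `[0, 1]`.
#' @export
hypergeom_sf <- function(q, M, n, N) {
  if (M < 0 || n < 0 || N < 0 || n > M || N > M)
    stop("require 0 <= n <= M and 0 <= N <= M")
  stats::phyper(q, m = n, n = M - n, k = N, lower.tail = FALSE)
}

#' Child-term enrichment of one supervised term in the NN ranking
#'
#' Tests whether the descendants of a supervised (e.g. random-forest)
#' GO term are over-represented among the top-`N_sample` nearest
#' neighbours of the complex query. With `M` the namespace vocabulary
#' size, `n` the number of the term's descendants in the vocabulary plus
#' one (the term itself), and `x` the number of descendants found within
#' the top-`N_sample` positions of the NN ranking, the p-value is
#' `hypergeom_sf(x - 1, M, n, N_sample)`. When significant, the ten
#' top-ranked descendant terms (by cosine) are attached as selected
#' children.
#'
#' @param rf_term GO id from the supervised list (must be in the
#'   vocabulary).
#' @param nn_ranking An `nn_result` covering the namespace vocabulary
#'   (full-corpus query), with `id` and `cosine` columns.
#' @param ont A [go_ontology()].
#' @param vocab Character vector: the namespace vocabulary.
#' @param N_sample Sample size (mean-recovery value for the namespace);
#'   clamped to `M` with a warning on toy vocabularies.
#' @param alpha Significance level.
#' @param children_mode `"transitive"` (default: all descendants) or
#'   `"direct"` (direct children only).
#' @param n_children Number of top-cosine children attached when
#'   significant.
#' @return An `enrichment_result`: list with `rf_term`, `p_value`, `M`,
#'   `n`, `N_sample`, `x`, `significant` and `selected_children` (data
#'   frame `go_id`, `cosine`; empty unless significant).
#' @export
enrich_term <- function(rf_term, nn_ranking, ont, vocab, N_sample,
                        alpha = 0.05,
                        children_mode = c("transitive", "direct"),
                        n_children = 10L) {
  children_mode <- match.arg(children_mode)
  if (!rf_term %in% vocab) stop("rf_term not in vocabulary: ", rf_term)
  M <- length(vocab)
  if (N_sample > M) {
    warning("N_sample (", N_sample, ") clamped to vocabulary size ", M)
    N_sample <- M
  }
  N_sample <- as.integer(round(N_sample))
  desc <- if (children_mode == "transitive") go_descendants(ont, rf_term)
          else go_children(ont, rf_term)
  desc <- intersect(desc, vocab)
  n <- length(desc) + 1L # the term itself counts as a success
  top <- utils::head(nn_ranking$id, N_sample)
  x <- length(intersect(desc, top))
  p <- hypergeom_sf(x - 1, M, n, N_sample)
  significant <- p < alpha
  selected <- data.frame(go_id = character(0), cosine = numeric(0),
                         stringsAsFactors = FALSE)
  if (significant && x > 0) {
    in_rank <- nn_ranking[nn_ranking$id %in% desc, , drop = FALSE]
    sel <- utils::head(in_rank, n_children)
    selected <- data.frame(go_id = sel$id, cosine = sel$cosine,
                           stringsAsFactors = FALSE)
  }
  structure(list(rf_term = rf_term, p_value = p, M = M, n = n,
                 N_sample = N_sample, x = x, significant = significant,
                 selected_children = selected),
            class = "enrichment_result")
}

#' Shared cellular-component annotations of a complex's subunits
#'
#' Intersection of the CC term sets across all subunits that carry any
#' CC annotation. Subunits absent from the annotation table (or without
#' CC terms) are flagged and excluded from the intersection; if no
#' subunit has a CC annotation the result is empty and flagged.
#'
#' @param protein_annotations Data frame with columns `protein_id`,
#'   `go_id`, `namespace` (GAF-like per-protein table).
#' @param subunits Character vector of subunit names (matched after
#'   [normalize_text()] on both sides).
#' @return Character vector of shared CC GO ids; attribute
#'   `missing_subunits` lists subunits without CC annotations.
#' @export
subunit_cc_overlap <- function(protein_annotations, subunits) {
  stopifnot(all(c("protein_id", "go_id", "namespace") %in%
                  names(protein_annotations)))
  if (length(subunits) == 0) stop("complex has no subunits")
  cc <- protein_annotations[protein_annotations$namespace ==
                              "cellular_component", , drop = FALSE]
  key <- vapply(cc$protein_id,
                function(p) paste(normalize_text(p), collapse = " "), "")
  sets <- list(); missing <- character()
  for (s in subunits) {
    sk <- paste(normalize_text(s), collapse = " ")
    terms <- unique(cc$go_id[key == sk])
    if (length(terms) == 0) missing <- c(missing, s)
    else sets[[length(sets) + 1L]] <- terms
  }
  out <- if (length(sets) == 0) character(0) else Reduce(intersect, sets)
  attr(out, "missing_subunits") <- missing
  out
}

#' Consolidate supervised and nearest-neighbour predictions
#'
#' For each of the three GO namespaces, runs the child-term enrichment
#' test for every supervised term against the NN ranking and assembles
#' (i) the consolidated list (supervised terms with their enrichment
#' statistics plus, for significant terms, their top-cosine descendant
#' NN terms) and (ii) the top-20 NN-only list - six lists in total. The
#' CC consolidated list is augmented with the subunit CC overlap when a
#' per-protein annotation table is supplied. A DAG plot specification is
#' produced for every significant supervised term.
#'
#' @param complex_id Identifier of the query complex.
#' @param rf_lists Named list (`biological_process`, `molecular_function`,
#'   `cellular_component`) of `rf_prediction_list`s.
#' @param nn_rankings Named list of full-vocabulary `nn_result`s, same
#'   names.
#' @param ont A [go_ontology()].
#' @param N_sample Named numeric vector of enrichment sample sizes per
#'   namespace (defaults to [default_sample_sizes()], clamped to each
#'   vocabulary).
#' @param alpha Significance level for the enrichment test.
#' @param nn_top Length cap of the NN-only lists.
#' @param protein_annotations Optional GAF-like data frame for the CC
#'   subunit overlap.
#' @param subunits Subunit names of the complex (required with
#'   `protein_annotations`).
#' @param children_mode Passed to [enrich_term()].
#' @param p_adjust `"none"` (default) or `"BH"`: optional
#'   Benjamini-Hochberg correction across the supervised terms of each
#'   namespace.
#' @return A `prediction_bundle`: per namespace a `consolidated` data
#'   frame and an `nn_only` data frame, plus `cc_overlap`, `dag_specs`
#'   and `enrichment` (the raw `enrichment_result`s).
#' @export
consolidate <- function(complex_id, rf_lists, nn_rankings, ont,
                        N_sample = default_sample_sizes(), alpha = 0.05,
                        nn_top = 20L, protein_annotations = NULL,
                        subunits = NULL,
                        children_mode = c("transitive", "direct"),
                        p_adjust = c("none", "BH")) {
  children_mode <- match.arg(children_mode)
  p_adjust <- match.arg(p_adjust)
  nss <- c("biological_process", "molecular_function", "cellular_component")
  miss <- setdiff(nss, union(names(rf_lists), character(0)))
  if (length(miss) > 0 || length(setdiff(nss, names(nn_rankings))) > 0)
    stop("rf_lists and nn_rankings must cover all three namespaces")

  lists <- list(); dag_specs <- list(); enr_all <- list()
  for (ns in nss) {
    vocab <- go_vocabulary(ont, ns)
    rk <- nn_rankings[[ns]]
    rf <- rf_lists[[ns]]
    Nns <- unname(N_sample[[ns]])
    if (Nns > length(vocab)) Nns <- length(vocab) # toy-scale clamp

    enr <- list()
    cons <- data.frame(rank = integer(0), go_id = character(0),
                       go_name = character(0), source = character(0),
                       cosine = numeric(0), rf_probability = numeric(0),
                       p_value = numeric(0), stringsAsFactors = FALSE)
    if (nrow(rf) > 0) {
      for (i in seq_len(nrow(rf)))
        enr[[i]] <- enrich_term(rf$go_id[i], rk, ont, vocab, Nns,
                                alpha = alpha, children_mode = children_mode)
      if (p_adjust == "BH") {
        padj <- stats::p.adjust(vapply(enr, `[[`, 0, "p_value"), "BH")
        for (i in seq_along(enr)) {
          enr[[i]]$p_value <- padj[i]
          enr[[i]]$significant <- padj[i] < alpha
          if (!enr[[i]]$significant)
            enr[[i]]$selected_children <- enr[[i]]$selected_children[0, ]
        }
      }
      for (i in seq_len(nrow(rf))) {
        e <- enr[[i]]
        cons <- rbind(cons, data.frame(
          rank = nrow(cons) + 1L, go_id = rf$go_id[i],
          go_name = rf$go_name[i], source = "rf",
          cosine = NA_real_, rf_probability = rf$probability[i],
          p_value = e$p_value, stringsAsFactors = FALSE))
        if (nrow(e$selected_children) > 0) {
          ch <- e$selected_children
          cons <- rbind(cons, data.frame(
            rank = nrow(cons) + seq_len(nrow(ch)), go_id = ch$go_id,
            go_name = unname(ont$name[ch$go_id]), source = "kdtree",
            cosine = ch$cosine, rf_probability = NA_real_,
            p_value = NA_real_, stringsAsFactors = FALSE))
          dag_specs[[length(dag_specs) + 1L]] <-
            dag_plot_spec(ont, rf$go_id[i], ch$go_id)
        }
      }
    }
    nn_only <- utils::head(rk, nn_top)
    nn_only <- data.frame(rank = seq_len(nrow(nn_only)),
                          go_id = nn_only$id, go_name = nn_only$name,
                          source = "kdtree", cosine = nn_only$cosine,
                          rf_probability = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE)
    lists[[ns]] <- list(consolidated = cons, nn_only = nn_only)
    enr_all[[ns]] <- enr
  }

  cc_overlap <- character(0)
  if (!is.null(protein_annotations)) {
    if (is.null(subunits))
      stop("`subunits` required when protein_annotations are supplied")
    cc_overlap <- subunit_cc_overlap(protein_annotations, subunits)
    known <- intersect(cc_overlap, go_vocabulary(ont, "cellular_component"))
    extra <- setdiff(known, lists$cellular_component$consolidated$go_id)
    if (length(extra) > 0) {
      cc <- lists$cellular_component$consolidated
      cc <- rbind(cc, data.frame(
        rank = nrow(cc) + seq_along(extra), go_id = extra,
        go_name = unname(ont$name[extra]), source = "cc_overlap",
        cosine = NA_real_, rf_probability = NA_real_, p_value = NA_real_,
        stringsAsFactors = FALSE))
      lists$cellular_component$consolidated <- cc
    }
  }

  structure(list(complex_id = complex_id, lists = lists,
                 cc_overlap = cc_overlap, dag_specs = dag_specs,
                 enrichment = enr_all),
            class = "prediction_bundle")
}

#' @method print prediction_bundle
#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf("prediction_bundle for %s: %d lists, %d DAG spec(s)\n",
              x$complex_id, 2L * length(x$lists), length(x$dag_specs)))
  invisible(x)
}

#' DAG plot specification for a significant supervised term
#'
#' Nodes are the supervised term (role `rf_term`, drawn green), its
#' selected NN descendant terms (role `nn_term`, drawn purple) and the
#' connecting context: ancestors of the supervised term up to the
#' namespace root and the intermediate terms on paths down to each
#' selected child (role `ancestor`, uncoloured). Edges are the ontology
#' edges among the included nodes.
#'
#' @param ont A [go_ontology()].
#' @param rf_term Supervised GO id.
#' @param nn_terms Selected child GO ids (must be descendants of
#'   `rf_term`).
#' @return A `dag_plot_spec`: list with `nodes` (id, role) and `edges`
#'   (child, parent, relation) data frames.
#' @export
dag_plot_spec <- function(ont, rf_term, nn_terms) {
  desc <- go_descendants(ont, rf_term)
  bad <- setdiff(nn_terms, desc)
  if (length(bad) > 0)
    stop("nn term(s) not descendants of ", rf_term, ": ",
         paste(bad, collapse = ", "))
  context <- go_ancestors(ont, rf_term)
  # intermediate nodes: ancestors of each child that are descendants of rf_term
  for (t in nn_terms)
    context <- union(context, intersect(go_ancestors(ont, t), desc))
  context <- setdiff(context, c(rf_term, nn_terms))
  ids <- c(rf_term, nn_terms, context)
  role <- c("rf_term", rep("nn_term", length(nn_terms)),
            rep("ancestor", length(context)))
  edges <- data.frame(child = character(0), parent = character(0),
                      relation = character(0), stringsAsFactors = FALSE)
  for (id in ids) {
    pe <- ont$parents[[id]]
    if (is.null(pe) || nrow(pe) == 0) next
    keep <- pe$parent %in% ids
    if (any(keep))
      edges <- rbind(edges, data.frame(child = id, parent = pe$parent[keep],
                                       relation = pe$relation[keep],
                                       stringsAsFactors = FALSE))
  }
  structure(list(nodes = data.frame(id = ids, role = role,
                                    stringsAsFactors = FALSE),
                 edges = edges, rf_term = rf_term),
            class = "dag_plot_spec")
}

#' Write a DAG plot specification as a Graphviz DOT file
#'
#' Supervised terms are filled green, NN child terms purple; context
#' nodes stay white. Edges point from child to parent, labelled by
#' relation.
#'
#' @param spec A [dag_plot_spec()].
#' @param ont A [go_ontology()] (for node labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(spec, ont, path) {
  stopifnot(inherits(spec, "dag_plot_spec"))
  esc <- function(x) gsub("\"", "\\\\\"", x)
  col <- c(rf_term = "green", nn_term = "purple", ancestor = "white")
  lines <- c("digraph go_dag {", "  rankdir=BT;",
             "  node [style=filled, shape=box];")
  for (i in seq_len(nrow(spec$nodes))) {
    id <- spec$nodes$id[i]; role <- spec$nodes$role[i]
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\\n%s\", fillcolor=%s];",
                              esc(id), esc(id), esc(ont$name[[id]]),
                              col[[role]]))
  }
  for (i in seq_len(nrow(spec$edges)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                              esc(spec$edges$child[i]),
                              esc(spec$edges$parent[i]),
                              spec$edges$relation[i]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a prediction bundle to disk
#'
#' Emits the six TSV lists (two per namespace, shared column layout), a
#' DOT file per significant supervised term and a JSON manifest.
#'
#' @param bundle A `prediction_bundle`.
#' @param ont A [go_ontology()].
#' @param outdir Output directory (created if needed).
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
write_outputs <- function(bundle, ont, outdir) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  slug <- gsub("[^A-Za-z0-9_.-]+", "_", bundle$complex_id)
  short <- c(biological_process = "bp", molecular_function = "mf",
             cellular_component = "cc")
  tsvs <- character(0)
  for (ns in names(bundle$lists)) {
    for (kind in c("consolidated", "nn_only")) {
      fn <- sprintf("%s_%s_%s.tsv", slug, short[[ns]], kind)
      utils::write.table(bundle$lists[[ns]][[kind]],
                         file.path(outdir, fn), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      tsvs <- c(tsvs, fn)
    }
  }
  dots <- character(0)
  for (i in seq_along(bundle$dag_specs)) {
    spec <- bundle$dag_specs[[i]]
    fn <- sprintf("%s_dag_%s.dot", slug,
                  gsub("[^A-Za-z0-9]+", "_", spec$rf_term))
    write_dot(spec, ont, file.path(outdir, fn))
    dots <- c(dots, fn)
  }
  manifest <- list(complex_id = bundle$complex_id, lists = tsvs,
                   dag_plots = dots,
                   cc_overlap = as.character(bundle$cc_overlap))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
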