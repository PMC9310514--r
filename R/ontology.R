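#' Construct a GO ontology object
#'
#' Internal constructor shared by [parse_obo()] and the synthetic
#' ontology generator. Validates referential integrity and acyclicity.
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param edges Data frame with columns `id`, `parent`,
#'   `relation` (`"is_a"` or `"part_of"`).
#' @return Object of class `go_ontology` with cached child adjacency.
#' @export
go_ontology <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("id", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  ok_ns <- c("biological_process", "molecular_function", "cellular_component")
  if (!all(terms$namespace %in% ok_ns))
    stop("unknown namespace value(s): ",
         paste(setdiff(unique(terms$namespace), ok_ns), collapse = ", "))
  missing <- setdiff(unique(edges$parent), terms$id)
  if (length(missing) > 0)
    stop("parent id(s) not defined as terms: ", paste(missing, collapse = ", "))
  if (any(edges$id == edges$parent)) stop("self-parenting edge")

  ids <- terms$id
  parents <- split(edges[c("parent", "relation")], factor(edges$id, levels = ids))
  children <- split(edges$id, factor(edges$parent, levels = ids))

  # Kahn's algorithm on parent edges to certify acyclicity
  indeg <- vapply(parents, nrow, 0L)
  queue <- ids[indeg == 0]
  seen <- 0L
  indeg_env <- indeg
  names(indeg_env) <- ids
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg_env[[ch]] <- indeg_env[[ch]] - 1L
      if (indeg_env[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) stop("ontology graph contains a cycle")

  structure(list(
    ids = ids,
    name = stats::setNames(terms$name, ids),
    namespace = stats::setNames(terms$namespace, ids),
    parents = parents,
    children = children
  ), class = "go_ontology")
}

#' @method print go_ontology
#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("go_ontology: %d terms (%s)\n", length(x$ids),
              paste(sprintf("%s=%d", sub("_.*", "", names(table(x$namespace))),
                            as.integer(table(x$namespace))), collapse = ", ")))
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Loads all non-obsolete `[Term]` stanzas. `is_a:` lines and
#' `relationship: part_of` lines become typed parent edges; other
#' relationship types (e.g. `regulates`) are ignored, though their terms
#' are still loaded. Errors on cycles or undefined parent ids.
#'
#' @param path Path to an OBO 1.2 file.
#' @return A [go_ontology()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0) stop("no stanzas found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); nms <- character(); nss <- character()
  e_id <- character(); e_par <- character(); e_rel <- character()
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    stanza <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    stanza <- stanza[nzchar(stanza)]
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), stanza, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      sub("\\s*!.*$", "", trimws(sub(paste0("^", tag, ":"), "", hit[1])))
    }
    if (!is.na(get1("is_obsolete")) && get1("is_obsolete") == "true") next
    id <- get1("id"); nm <- get1("name"); ns <- get1("namespace")
    if (is.na(id)) stop("[Term] stanza without id")
    ids <- c(ids, id); nms <- c(nms, nm); nss <- c(nss, ns)
    for (hit in grep("^is_a:", stanza, value = TRUE)) {
      par <- sub("\\s*!.*$", "", trimws(sub("^is_a:", "", hit)))
      e_id <- c(e_id, id); e_par <- c(e_par, par); e_rel <- c(e_rel, "is_a")
    }
    for (hit in grep("^relationship:", stanza, value = TRUE)) {
      body <- strsplit(trimws(sub("^relationship:", "", sub("\\s*!.*$", "", hit))),
                       "\\s+")[[1]]
      if (length(body) >= 2 && body[1] == "part_of") {
        e_id <- c(e_id, id); e_par <- c(e_par, body[2]); e_rel <- c(e_rel, "part_of")
      }
    }
  }
  go_ontology(data.frame(id = ids, name = nms, namespace = nss,
                         stringsAsFactors = FALSE),
              data.frame(id = e_id, parent = e_par, relation = e_rel,
                         stringsAsFactors = FALSE))
}

#' Write a [go_ontology()] to an OBO 1.2 file
#' @param ont A `go_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "go_ontology"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in ont$ids) {
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", ont$name[[id]]),
             paste0("namespace: ", ont$namespace[[id]]))
    pe <- ont$parents[[id]]
    if (!is.null(pe) && nrow(pe) > 0) {
      for (i in seq_len(nrow(pe))) {
        out <- c(out, if (pe$relation[i] == "is_a")
          paste0("is_a: ", pe$parent[i])
          else paste0("relationship: part_of ", pe$parent[i]))
      }
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

.check_id <- function(ont, id) {
  if (!id %in% ont$ids) stop("unknown GO id: ", id)
}

#' Direct children of a term
#' @param ont A `go_ontology`.
#' @param id Term id.
#' @return Character vector of direct child ids (empty for leaves).
#' @export
go_children <- function(ont, id) {
  .check_id(ont, id)
  as.character(ont$children[[id]])
}

#' Transitive descendants of a term
#'
#' All terms reachable by following child edges, excluding the term
#' itself. This is the default reading of "child terms" in the
#' enrichment test; direct-children mode is available there via a flag.
#'
#' @inheritParams go_children
#' @return Character vector of descendant ids.
#' @export
go_descendants <- function(ont, id) {
  .check_id(ont, id)
  seen <- character()
  frontier <- as.character(ont$children[[id]])
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- unique(unlist(ont$children[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, seen)
  }
  unique(seen)
}

#' Ancestors of a term (transitive closure of parent edges)
#' @inheritParams go_children
#' @return Character vector of ancestor ids, excluding the term.
#' @export
go_ancestors <- function(ont, id) {
  .check_id(ont, id)
  seen <- character()
  frontier <- as.character(ont$parents[[id]]$parent)
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- unique(unlist(lapply(ont$parents[frontier], `[[`, "parent"),
                             use.names = FALSE))
    frontier <- setdiff(frontier, seen)
  }
  unique(seen)
}

#' Term ids of one namespace
#' @param ont A `go_ontology`.
#' @param namespace One of `"biological_process"`, `"molecular_function"`,
#'   `"cellular_component"` (abbreviations `"bp"`, `"mf"`, `"cc"` accepted).
#' @return Character vector of term ids.
#' @export
go_vocabulary <- function(ont, namespace) {
  namespace <- expand_namespace(namespace)
  ont$ids[ont$namespace[ont$ids] == namespace]
}

expand_namespace <- function(ns) {
  full <- c(bp = "biological_process", mf = "molecular_function",
            cc = "cellular_component")
  if (ns %in% full) return(ns)
  if (ns %in% names(full)) return(unname(full[[ns]]))
  stop("unknown namespace: ", ns)
}
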