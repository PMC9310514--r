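#' Read a complex-annotation table
#'
#' Tab-separated table with columns `complex_id`, `canonical_name`,
#' `subunits` (";"-separated subunit names) and `go_bp`, `go_mf`,
#' `go_cc` (";"-separated GO ids, possibly empty). This is the schema of
#' curated complex resources such as CORUM exports.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `complex_db`.
#' @export
read_complex_db <- function(path) {
  if (!file.exists(path)) stop("complex table not found: ", path)
  db <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("complex_id", "canonical_name", "subunits",
                "go_bp", "go_mf", "go_cc")
  miss <- setdiff(required, names(db))
  if (length(miss) > 0)
    stop("complex table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(db$complex_id)) stop("duplicate complex ids")
  class(db) <- c("complex_db", "data.frame")
  db
}

#' Write a complex table in the TSV dialect read by [read_complex_db()]
#' @param db A `complex_db` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_db <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

split_semi <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Subunit name lists of a complex table
#' @param db A `complex_db`.
#' @return List (per complex) of character vectors of subunit names.
#' @export
subunit_list <- function(db) split_semi(db$subunits)

#' Per-complex GO annotations of one namespace
#' @param db A `complex_db`.
#' @param namespace Namespace (full name or `bp`/`mf`/`cc`).
#' @return List (per complex) of character vectors of GO ids.
#' @export
complex_annotations <- function(db, namespace) {
  namespace <- expand_namespace(namespace)
  col <- switch(namespace,
                biological_process = "go_bp",
                molecular_function = "go_mf",
                cellular_component = "go_cc")
  split_semi(db[[col]])
}

#' Validate a complex table against an ontology
#'
#' Checks that every complex has at least one subunit and that every
#' annotated GO id exists in the ontology with the namespace of its
#' column.
#'
#' @param db A `complex_db`.
#' @param ont A [go_ontology()].
#' @return `TRUE` invisibly; errors describe all offending entries.
#' @export
validate_complex_db <- function(db, ont) {
  bad <- character()
  subs <- subunit_list(db)
  for (i in seq_len(nrow(db))) {
    if (length(subs[[i]]) == 0)
      bad <- c(bad, paste0(db$complex_id[i], ": no subunits"))
  }
  for (ns in c("biological_process", "molecular_function", "cellular_component")) {
    ann <- complex_annotations(db, ns)
    for (i in seq_len(nrow(db))) {
      unknown <- setdiff(ann[[i]], ont$ids)
      if (length(unknown) > 0)
        bad <- c(bad, paste0(db$complex_id[i], ": unknown ids ",
                             paste(unknown, collapse = ",")))
      known <- intersect(ann[[i]], ont$ids)
      off <- known[ont$namespace[known] != ns]
      if (length(off) > 0)
        bad <- c(bad, paste0(db$complex_id[i], ": wrong namespace for ",
                             paste(off, collapse = ",")))
    }
  }
  if (length(bad) > 0)
    stop("complex table validation failed:\n  ", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}
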