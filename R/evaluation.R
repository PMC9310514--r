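#' Subunit overlap between two complexes
#'
#' Overlap of the two subunit sets after name normalization. The
#' default denominator is the smaller set (overlap coefficient), the
#' strictest common reading; Jaccard is available via `mode`.
#'
#' @param s1,s2 Character vectors of subunit names (non-empty).
#' @param mode `"min"` (overlap coefficient) or `"jaccard"`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
subunit_overlap <- function(s1, s2, mode = c("min", "jaccard")) {
  mode <- match.arg(mode)
  if (length(s1) == 0 || length(s2) == 0) stop("empty subunit set")
  norm <- function(v) unique(vapply(v, function(s)
    paste(normalize_text(s), collapse = " "), ""))
  a <- norm(s1); b <- norm(s2)
  inter <- length(intersect(a, b))
  denom <- switch(mode, min = min(length(a), length(b)),
                  jaccard = length(union(a, b)))
  inter / denom
}

#' Retain query complexes independent of a reference table
#'
#' Computes the maximum subunit overlap of every query complex against
#' all reference complexes and retains those at or below `threshold`
#' (the ">50% overlap removed" filter used to build independent
#' benchmark sets).
#'
#' @param query_db,reference_db `complex_db` tables.
#' @param threshold Maximum allowed overlap (complexes with overlap
#'   strictly greater are removed).
#' @param mode Passed to [subunit_overlap()].
#' @return An `overlap_filter_report`: data frame `pairs` (query id,
#'   best-matching reference id, overlap) and `retained` ids.
#' @export
filter_independent <- function(query_db, reference_db, threshold = 0.5,
                               mode = "min") {
  if (nrow(query_db) == 0 || nrow(reference_db) == 0)
    stop("both complex tables must be non-empty")
  qs <- subunit_list(query_db)
  rs <- subunit_list(reference_db)
  best <- numeric(nrow(query_db)); best_ref <- character(nrow(query_db))
  for (i in seq_len(nrow(query_db))) {
    ov <- vapply(rs, function(r) subunit_overlap(qs[[i]], r, mode), 0)
    j <- which.max(ov)
    best[i] <- ov[j]; best_ref[i] <- reference_db$complex_id[j]
  }
  pairs <- data.frame(query_id = query_db$complex_id,
                      best_reference = best_ref, overlap = best,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 retained = query_db$complex_id[best <= threshold],
                 threshold = threshold, mode = mode),
            class = "overlap_filter_report")
}

#' Histogram of per-complex coverage over ten 10%-wide bins
#'
#' Bins `[0,10), [10,20), ..., [80,90), [90,100]`; the top bin is
#' right-closed so that full coverage lands in it.
#'
#' @param reports List of `coverage_report`s (from [go_coverage()]), or
#'   a numeric vector of coverage percentages.
#' @return A `coverage_binning`: data frame with `bin`, `count` and
#'   `percent` (of complexes) per bin.
#' @export
bin_coverage <- function(reports) {
  cov <- if (is.numeric(reports)) reports
         else vapply(reports, `[[`, 0, "coverage_percent")
  if (length(cov) == 0) stop("no coverage reports supplied")
  if (any(cov < 0 | cov > 100)) stop("coverage must lie in [0, 100]")
  idx <- pmin(floor(cov / 10), 9) + 1L
  counts <- tabulate(idx, nbins = 10L)
  labels <- c(sprintf("[%d,%d)", seq(0, 80, 10), seq(10, 90, 10)),
              "[90,100]")
  structure(data.frame(bin = labels, count = counts,
                       percent = 100 * counts / length(cov),
                       stringsAsFactors = FALSE),
            class = c("coverage_binning", "data.frame"))
}
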