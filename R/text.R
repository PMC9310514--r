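#' Normalize a natural-language name into lowercase alphanumeric tokens
#'
#' Applies the text-preprocessing rules used throughout the package:
#' HTML entities are decoded, a small documented table of common mojibake
#' sequences (UTF-8 text mis-read as Latin-1) is repaired, all punctuation
#' is replaced by whitespace, characters are lower-cased and the result is
#' split on whitespace. The same normalization is applied to corpus lines,
#' query names and subunit symbols, so that all of them live in one shared
#' token space.
#'
#' @param raw A character scalar (the raw name or sentence).
#' @return A character vector of lowercase alphanumeric tokens, in their
#'   original order. A string that reduces to nothing returns
#'   `character(0)`.
#' @examples
#' normalize_text("E3-Ubiquitin Ligase!")
#' normalize_text("DNA&nbsp;synthesis")
#' @export
normalize_text <- function(raw) {
  if (is.null(raw) || length(raw) != 1L || is.na(raw))
    stop("`raw` must be a single non-NA character string")
  x <- as.character(raw)
  x <- decode_html_entities(x)
  x <- repair_mojibake(x)
  x <- tolower(x)
  # every non-alphanumeric character acts as a separator
  x <- gsub("[^a-z0-9]+", " ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

# Named HTML entities seen in biomedical text plus numeric entities.
.html_entities <- c(
  "&nbsp;" = " ", "&amp;" = "&", "&lt;" = "<", "&gt;" = ">",
  "&quot;" = "\"", "&apos;" = "'", "&#39;" = "'",
  "&mdash;" = "-", "&ndash;" = "-", "&micro;" = "u",
  "&alpha;" = "alpha", "&beta;" = "beta", "&gamma;" = "gamma",
  "&delta;" = "delta", "&kappa;" = "kappa"
)

decode_html_entities <- function(x) {
  for (ent in names(.html_entities))
    x <- gsub(ent, .html_entities[[ent]], x, fixed = TRUE)
  # numeric entities: &#160; etc. -> space (they are separators here)
  gsub("&#x?[0-9a-fA-F]+;", " ", x)
}

# Documented mapping of frequent mojibake sequences; deliberately small,
# full heuristic repair is out of scope.
.mojibake_map <- c(
  "\u00e2\u20ac\u2122" = "'",      # right single quote read as Latin-1
  "\u00e2\u20ac\u0153" = "\"",     # left double quote
  "\u00e2\u20ac\u201c" = "-",      # en dash
  "\u00e2\u20ac\u201d" = "-",      # em dash
  "\u00e2\u20ac"        = "\"",     # bare euro-sign pair (longer forms first)
  "\u00c3\u00a9" = "e",             # e acute
  "\u00c3\u00a8" = "e",             # e grave
  "\u00c2\u00b5" = "u",             # micro sign
  "\u00ce\u00b1" = "alpha",
  "\u00ce\u00b2" = "beta"
)

repair_mojibake <- function(x) {
  for (bad in names(.mojibake_map))
    x <- gsub(bad, .mojibake_map[[bad]], x, fixed = TRUE)
  x
}

#' Character bigrams of a token
#'
#' Splits a normalized token into its overlapping adjacent character
#' pairs, the subword units of the embedding. A single-character token
#' yields itself as its only unit (the degenerate fastText-style case),
#' so tokens such as "1" are never dropped.
#'
#' @param token A single normalized token.
#' @return Character vector of bigrams, in order; length
#'   `max(1, nchar(token) - 1)`.
#' @examples
#' char_bigrams("positive")
#' @export
char_bigrams <- function(token) {
  if (is.null(token) || length(token) != 1L || is.na(token) || !nzchar(token))
    stop("`token` must be a single non-empty string")
  n <- nchar(token)
  if (n == 1L) return(token)
  substring(token, seq_len(n - 1L), seq_len(n - 1L) + 1L)
}
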