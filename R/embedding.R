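#' Embedding training configuration
#'
#' @param dim Vector dimension. 500 matches the full-scale literature
#'   embedding; toy corpora use much smaller values.
#' @param window Maximum skip-gram context window (a per-position window
#'   is drawn uniformly from 1..window).
#' @param min_count Minimum corpus frequency for a token to receive a
#'   stored word vector. Rarer tokens remain composable from their
#'   character-bigram subword vectors.
#' @param epochs Passes over the corpus.
#' @param negative Negative samples per positive context pair.
#' @param learning_rate Initial SGD learning rate, linearly decayed.
#' @param seed Integer seed; training is single-threaded and fully
#'   reproducible given the same corpus and seed.
#' @return A list of class `sg_config`.
#' @export
embedding_config <- function(dim = 500L, window = 5L, min_count = 2L,
                             epochs = 10L, negative = 5L,
                             learning_rate = 0.05, seed = 42L) {
  if (dim < 2) stop("`dim` must be >= 2")
  if (min_count < 1 || window < 1 || epochs < 1)
    stop("window, min_count and epochs must be positive")
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 min_count = as.integer(min_count),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "sg_config")
}

#' Construct an embedding model from vector tables
#'
#' Low-level constructor used by [train_embedding()], [read_embedding()]
#' and the planted-fixture generator.
#'
#' @param word_vectors Numeric matrix with one row per word; rownames are
#'   the (normalized) tokens.
#' @param subword_vectors Numeric matrix with one row per character
#'   bigram; may have zero rows.
#' @param config The `sg_config` the vectors were trained under (or a
#'   nominal one for planted models).
#' @return An object of class `embedding_model`.
#' @export
embedding_model <- function(word_vectors, subword_vectors = NULL,
                            config = embedding_config(dim = ncol(word_vectors))) {
  word_vectors <- as.matrix(word_vectors)
  d <- ncol(word_vectors)
  if (is.null(subword_vectors))
    subword_vectors <- matrix(numeric(0), nrow = 0, ncol = d)
  subword_vectors <- as.matrix(subword_vectors)
  if (nrow(subword_vectors) > 0 && ncol(subword_vectors) != d)
    stop("word and subword vectors must share one dimension")
  if (anyDuplicated(rownames(word_vectors)))
    stop("duplicate tokens in word vector table")
  structure(list(dim = d, word_vectors = word_vectors,
                 subword_vectors = subword_vectors, config = config),
            class = "embedding_model")
}

#' @method print embedding_model
#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("embedding_model: %d words, %d subwords, dim %d\n",
              nrow(x$word_vectors), nrow(x$subword_vectors), x$dim))
  invisible(x)
}

#' Train a character-bigram subword skip-gram embedding
#'
#' Trains a skip-gram model with negative sampling in which the input
#' representation of every token is the mean of its atomic word vector
#' and the vectors of its character bigrams (minimum and maximum subword
#' length 2). Tokens below `min_count` carry no word vector but remain
#' composable from subwords. Training is single-threaded and
#' deterministic under `config$seed`.
#'
#' @param corpus_path Path to a UTF-8 plain-text corpus, one document per
#'   line. Lines are passed through [normalize_text()].
#' @param config An [embedding_config()].
#' @return An [embedding_model()].
#' @export
train_embedding <- function(corpus_path, config = embedding_config()) {
  if (!file.exists(corpus_path)) stop("corpus file not found: ", corpus_path)
  lines <- readLines(corpus_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("corpus is empty: ", corpus_path)
  docs <- lapply(lines, normalize_text)
  docs <- docs[lengths(docs) > 0]
  if (length(docs) == 0) stop("corpus normalizes to zero tokens")

  freq <- table(unlist(docs))
  vocab <- names(freq)[freq >= config$min_count]
  if (length(vocab) == 0) stop("no token reaches min_count")
  vocab <- sort(vocab)
  counts <- as.numeric(freq[vocab])

  bigrams <- lapply(vocab, char_bigrams)
  sub_vocab <- sort(unique(unlist(bigrams)))
  sub_ids <- lapply(bigrams, function(b) match(b, sub_vocab))

  corpus_ids <- lapply(docs, function(d) {
    id <- match(d, vocab)
    id[is.na(id)] <- 0L
    as.integer(id)
  })

  fit <- .sg_train(corpus_ids, sub_ids, counts,
                   length(vocab), length(sub_vocab), config$dim,
                   config$window, config$epochs, config$negative,
                   config$learning_rate, config$seed)
  W <- fit$words; rownames(W) <- vocab
  S <- fit$subwords; rownames(S) <- sub_vocab
  embedding_model(W, S, config)
}

#' Vector for a single token
#'
#' Returns the stored word vector when the token is in vocabulary and
#' otherwise composes one as the mean of the vectors of its character
#' bigrams that are present in the subword table.
#'
#' @param model An `embedding_model`.
#' @param token A normalized token.
#' @return Numeric vector of length `model$dim`, or an error of class
#'   `pcgo_unresolvable` when neither the token nor any of its bigrams
#'   is known.
#' @export
token_vector <- function(model, token) {
  stopifnot(inherits(model, "embedding_model"))
  if (token %in% rownames(model$word_vectors))
    return(model$word_vectors[token, ])
  grams <- char_bigrams(token)
  known <- grams[grams %in% rownames(model$subword_vectors)]
  if (length(known) == 0)
    stop(structure(class = c("pcgo_unresolvable", "error", "condition"),
                   list(message = paste0("unresolvable token: ", token),
                        call = sys.call(-1))))
  colMeans(model$subword_vectors[known, , drop = FALSE])
}

#' Compose a unit-norm query vector for a natural-language name
#'
#' Each token of the normalized name is vectorized via [token_vector()],
#' L2-normalized, the normalized token vectors are averaged, and the
#' average is re-normalized to unit length.
#'
#' @param model An `embedding_model`.
#' @param name Complex or GO-term name (raw text).
#' @param scheme `"canonical"` or `"subunit"` naming scheme tag carried
#'   on the result.
#' @return A `query_vector`: list with `name`, `scheme` and unit-norm
#'   `vector`.
#' @export
compose_query_vector <- function(model, name,
                                 scheme = c("canonical", "subunit")) {
  scheme <- match.arg(scheme)
  tokens <- normalize_text(name)
  if (length(tokens) == 0)
    stop(structure(class = c("pcgo_unresolvable", "error", "condition"),
                   list(message = paste0("name normalizes to zero tokens: ", name),
                        call = sys.call(-1))))
  vecs <- list()
  for (tok in tokens) {
    v <- tryCatch(token_vector(model, tok),
                  pcgo_unresolvable = function(e) NULL)
    if (!is.null(v)) {
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) vecs[[length(vecs) + 1L]] <- v / nrm
    }
  }
  if (length(vecs) == 0)
    stop(structure(class = c("pcgo_unresolvable", "error", "condition"),
                   list(message = paste0("no resolvable token in: ", name),
                        call = sys.call(-1))))
  m <- Reduce(`+`, vecs) / length(vecs)
  nrm <- sqrt(sum(m^2))
  if (nrm == 0) stop("token vectors cancel to the zero vector: ", name)
  structure(list(name = name, scheme = scheme, vector = m / nrm),
            class = "query_vector")
}

#' Write an embedding in word2vec text format
#'
#' Writes `words.vec` (header `"n_words dim"`, then one
#' `"token v1 ... vd"` line per word) plus a `subwords.vec` sidecar in
#' the same dialect for the character-bigram table.
#'
#' @param model An `embedding_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_embedding <- function(model, dir) {
  stopifnot(inherits(model, "embedding_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_vec(model$word_vectors, file.path(dir, "words.vec"))
  .write_vec(model$subword_vectors, file.path(dir, "subwords.vec"))
  invisible(dir)
}

#' Read an embedding written by [write_embedding()]
#' @param dir Directory holding `words.vec` and optionally `subwords.vec`.
#' @return An `embedding_model`.
#' @export
read_embedding <- function(dir) {
  W <- .read_vec(file.path(dir, "words.vec"))
  sub_path <- file.path(dir, "subwords.vec")
  S <- if (file.exists(sub_path)) .read_vec(sub_path) else NULL
  embedding_model(W, S, embedding_config(dim = ncol(W)))
}

.write_vec <- function(mat, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  if (nrow(mat) > 0) {
    body <- apply(mat, 1, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = " "))
    writeLines(paste(rownames(mat), body), con)
  }
  invisible(path)
}

.read_vec <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  n <- hdr[1]; d <- hdr[2]
  if (n == 0) return(matrix(numeric(0), 0, d))
  parts <- strsplit(lines[-1][seq_len(n)], "\\s+")
  words <- vapply(parts, `[`, "", 1L)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vals) <- words
  vals
}
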