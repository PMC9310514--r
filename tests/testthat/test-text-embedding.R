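test_that("normalize_text lowercases, strips punctuation and repairs entities", {
  expect_equal(normalize_text("E3-Ubiquitin Ligase!"),
               c("e3", "ubiquitin", "ligase"))
  expect_equal(normalize_text("Proteasome"), "proteasome")
  expect_equal(normalize_text("DNA&nbsp;synthesis"), c("dna", "synthesis"))
  expect_equal(normalize_text("TGF-\u00ce\u00b2 signaling"),
               c("tgf", "beta", "signaling"))
  expect_equal(normalize_text("!!!"), character(0))
  expect_error(normalize_text(NA_character_))
})

test_that("normalize_text is idempotent on random strings", {
  set.seed(3)
  pool <- c(letters, LETTERS, 0:9, "-", "!", "&", " ", ".", "(", ")")
  for (i in 1:50) {
    raw <- paste(sample(pool, sample(5:40, 1), replace = TRUE), collapse = "")
    once <- normalize_text(raw)
    again <- if (length(once) == 0) normalize_text("")
             else normalize_text(paste(once, collapse = " "))
    expect_identical(again, once)
  }
})

test_that("char_bigrams yields overlapping pairs with the length-1 fallback", {
  expect_equal(char_bigrams("positive"),
               c("po", "os", "si", "it", "ti", "iv", "ve"))
  expect_equal(char_bigrams("ab"), "ab")
  expect_equal(char_bigrams("a"), "a")
  expect_error(char_bigrams(""))
  set.seed(4)
  for (i in 1:30) {
    tok <- paste(sample(letters, sample(1:12, 1), replace = TRUE),
                 collapse = "")
    expect_length(char_bigrams(tok), max(1L, nchar(tok) - 1L))
  }
})

test_that("token_vector returns stored vectors and composes OOV from bigrams", {
  m <- tiny_model()
  expect_identical(token_vector(m, "aa"), m$word_vectors["aa", ])
  # "abc" has bigrams ab, bc -> mean((1,1,0), (0,0,2)) = (0.5, 0.5, 1)
  expect_equal(unname(token_vector(m, "abc")), c(0.5, 0.5, 1))
  expect_error(token_vector(m, "zz"), class = "pcgo_unresolvable")
})

test_that("compose_query_vector averages normalized token vectors to unit norm", {
  m <- tiny_model()
  qv <- compose_query_vector(m, "aa bb")
  expect_s3_class(qv, "query_vector")
  expect_equal(unname(qv$vector), c(sqrt(2) / 2, sqrt(2) / 2, 0))
  single <- compose_query_vector(m, "aa")
  expect_equal(unname(single$vector), c(1, 0, 0))
  expect_error(compose_query_vector(m, "zz zz"), class = "pcgo_unresolvable")
  expect_error(compose_query_vector(m, "..."), class = "pcgo_unresolvable")
})

test_that("composed query vectors are unit-norm over random models and names", {
  set.seed(9)
  for (i in 1:20) {
    d <- sample(3:12, 1)
    words <- replicate(8, paste(sample(letters[1:6], sample(2:5, 1),
                                       replace = TRUE), collapse = ""))
    words <- unique(words)
    W <- matrix(rnorm(length(words) * d), length(words))
    rownames(W) <- words
    m <- embedding_model(W, NULL, embedding_config(dim = d))
    name <- paste(sample(words, sample(1:3, 1)), collapse = " ")
    qv <- compose_query_vector(m, name)
    expect_lt(abs(sqrt(sum(qv$vector^2)) - 1), 1e-9)
  }
})

test_that("training produces vectors of the configured dimension", {
  fx <- toy_fixture()
  corpus <- tempfile(fileext = ".txt")
  generate_corpus(fx$db, fx$ont, fx$cfg, corpus)
  cfg <- embedding_config(dim = 16, epochs = 3, min_count = 2, seed = 5)
  m <- train_embedding(corpus, cfg)
  expect_gt(nrow(m$word_vectors), 50)
  expect_equal(ncol(m$word_vectors), 16)
  expect_equal(ncol(m$subword_vectors), 16)
  expect_error(train_embedding(corpus, embedding_config(dim = 1)))
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(train_embedding(empty, cfg))
})

test_that("rare tokens lack word vectors but stay composable via subwords", {
  corpus <- tempfile(fileext = ".txt")
  lines <- c(rep("alpha beta gamma delta", 20), rep("alphabeta alpha", 3))
  writeLines(lines, corpus)
  m <- train_embedding(corpus, embedding_config(dim = 8, min_count = 5,
                                                epochs = 2, seed = 1))
  expect_false("alphabeta" %in% rownames(m$word_vectors))
  expect_true("alpha" %in% rownames(m$word_vectors))
  # still composable: its bigrams occur in the retained vocabulary
  expect_length(token_vector(m, "alphabeta"), 8)
})

test_that("training is reproducible under a fixed seed", {
  corpus <- tempfile(fileext = ".txt")
  set.seed(2)
  writeLines(replicate(60, paste(sample(letters[1:9], 6, replace = TRUE),
                                 collapse = " ")), corpus)
  cfg <- embedding_config(dim = 10, epochs = 2, seed = 33)
  m1 <- train_embedding(corpus, cfg)
  m2 <- train_embedding(corpus, cfg)
  expect_identical(m1$word_vectors, m2$word_vectors)
  m3 <- train_embedding(corpus, embedding_config(dim = 10, epochs = 2,
                                                 seed = 34))
  expect_false(identical(m1$word_vectors, m3$word_vectors))
})

test_that("planted co-occurrence shapes trained cosine similarity", {
  # cplxa always co-occurs with termx; termy lives in separate
  # sentences with its own context vocabulary
  mk_corpus <- function() {
    ctx1 <- letters[10:15]; ctx2 <- letters[16:21]
    c(replicate(80, paste(c("cplxa", "termx", sample(ctx1, 3)),
                          collapse = " ")),
      replicate(80, paste(c("termy", sample(ctx2, 4)), collapse = " ")))
  }
  wins <- 0L
  for (s in 1:10) {
    corpus <- tempfile(fileext = ".txt")
    set.seed(100 + s)
    writeLines(sample(mk_corpus()), corpus)
    m <- train_embedding(corpus, embedding_config(dim = 12, epochs = 8,
                                                  min_count = 2, seed = s))
    cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    va <- token_vector(m, "cplxa")
    if (cs(va, token_vector(m, "termx")) > cs(va, token_vector(m, "termy")))
      wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("word2vec text round trip preserves the vector tables", {
  m <- tiny_model()
  dir <- tempfile()
  write_embedding(m, dir)
  m2 <- read_embedding(dir)
  expect_equal(m2$word_vectors, m$word_vectors)
  expect_equal(m2$subword_vectors, m$subword_vectors)
  hdr <- readLines(file.path(dir, "words.vec"), n = 1)
  expect_equal(hdr, "2 3")
})
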