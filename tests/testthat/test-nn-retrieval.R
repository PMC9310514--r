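mk_sub <- function(mat, names) {
  rownames(mat) <- names
  structure(list(scheme = "canonical", names = names, ids = names,
                 matrix = mat, skipped = character(0)),
            class = "sub_embedding")
}

brute_ranking <- function(mat, q, names) {
  cos <- as.numeric(mat %*% q)
  names[order(-cos, names)]
}

test_that("sub-embeddings stack unit-norm rows and report skipped names", {
  fx <- toy_fixture()
  vocab <- go_vocabulary(fx$ont, "biological_process")
  sub <- build_sub_embedding(fx$emb, unname(fx$ont$name[vocab]), "canonical",
                             ids = vocab)
  expect_equal(nrow(sub$matrix), length(vocab))
  expect_true(all(abs(sqrt(rowSums(sub$matrix^2)) - 1) < 1e-9))
  expect_error(build_sub_embedding(fx$emb, c("x y", "x y")), "duplicate")
  sub2 <- build_sub_embedding(fx$emb,
                              c(unname(fx$ont$name[vocab[1]]), "qqqq wwww"))
  expect_equal(sub2$skipped, "qqqq wwww")
  expect_equal(nrow(sub2$matrix), 1)
})

test_that("index refuses non-unit rows and non-unit queries", {
  m <- rbind(c(1, 0), c(0, 2))
  expect_error(build_index(mk_sub(m, c("a", "b"))), "unit-norm")
  idx <- build_index(mk_sub(diag(2), c("a", "b")))
  expect_error(query_nn(idx, c(2, 0), 1), "unit-norm")
})

test_that("self-queries return the stored row at rank 1 with cosine 1", {
  mat <- runif_sphere(40, 8, seed = 31)
  names <- sprintf("t%02d", 1:40)
  idx <- build_index(mk_sub(mat, names))
  for (i in c(1, 17, 40)) {
    r <- query_nn(idx, mat[i, ], 5)
    expect_equal(r$name[1], names[i])
    expect_equal(r$cosine[1], 1, tolerance = 1e-9)
    expect_true(all(diff(r$cosine) <= 1e-12))
  }
})

test_that("k-d tree ranking equals brute-force cosine order", {
  mat <- runif_sphere(300, 12, seed = 41)
  names <- sprintf("n%03d", sample(300)) # scrambled so lexicographic != index
  idx <- build_index(mk_sub(mat, names))
  qs <- runif_sphere(20, 12, seed = 42)
  for (j in seq_len(nrow(qs))) {
    r <- query_nn(idx, qs[j, ], 300)
    expect_identical(r$name, brute_ranking(mat, qs[j, ], names))
  }
  # partial k agrees with the head of the full ranking
  r10 <- query_nn(idx, qs[1, ], 10)
  expect_identical(r10$name, brute_ranking(mat, qs[1, ], names)[1:10])
})

test_that("exact distance ties break lexicographically and reproducibly", {
  base <- runif_sphere(6, 5, seed = 51)
  mat <- rbind(base, base[2, ], base[4, ]) # duplicated rows -> exact ties
  names <- c("f", "d", "a", "c", "e", "b", "dd", "cc")
  idx <- build_index(mk_sub(mat, names))
  q <- runif_sphere(1, 5, seed = 52)[1, ]
  r1 <- query_nn(idx, q, 8)
  r2 <- query_nn(idx, q, 8)
  expect_identical(r1, r2)
  # within tied groups the names are sorted
  expect_identical(r1$name, brute_ranking(mat, q, names))
  dup1 <- which(r1$name %in% c("d", "dd"))
  expect_identical(r1$name[dup1], sort(c("d", "dd")))
})

test_that("k above the corpus size returns the full ranking, flagged", {
  mat <- runif_sphere(15, 6, seed = 61)
  idx <- build_index(mk_sub(mat, letters[1:15]))
  r <- query_nn(idx, mat[3, ], 50)
  expect_equal(nrow(r), 15)
  expect_true(attr(r, "truncated"))
  expect_setequal(r$name, letters[1:15])
})

test_that("recovery_count returns the rank of the worst truth member", {
  expect_equal(recovery_count(c("a", "b", "c", "d"), c("a", "c")), 3)
  expect_equal(recovery_count(letters[1:10], letters[1:10]), 10)
  expect_error(recovery_count(c("a", "b"), c("a", "z")), "absent")
})

test_that("recovery_count equals a linear-scan oracle on random rankings", {
  scan_oracle <- function(ranking, truth) {
    for (k in seq_along(ranking))
      if (all(truth %in% ranking[seq_len(k)])) return(k)
    stop("unreachable")
  }
  set.seed(71)
  for (i in 1:1000) {
    v <- sample(50, sample(5:50, 1))
    ranking <- paste0("x", v)
    truth <- sample(ranking, sample(1:min(5, length(ranking)), 1))
    expect_identical(recovery_count(ranking, truth),
                     scan_oracle(ranking, truth))
  }
})

test_that("recovery_count is monotone in the truth set", {
  set.seed(72)
  for (i in 1:50) {
    ranking <- paste0("x", sample(40))
    truth <- sample(ranking, 3)
    extra <- sample(setdiff(ranking, truth), 1)
    expect_gte(recovery_count(ranking, c(truth, extra)),
               recovery_count(ranking, truth))
  }
})

test_that("mean recovery averages per-complex counts and beats the random null", {
  fx <- toy_fixture()
  vocab <- go_vocabulary(fx$ont, "biological_process")
  idx <- build_index(build_sub_embedding(fx$emb, unname(fx$ont$name[vocab]),
                                         "canonical", ids = vocab))
  mr <- mean_recovery(fx$db, fx$emb, idx, "bp", "subunit")
  expect_length(mr$counts, nrow(fx$db))
  expect_equal(mr$mean, mean(mr$counts))
  ann <- complex_annotations(fx$db, "bp")
  expect_true(all(mr$counts >= lengths(ann)))
  # permutation null: expected recovery for t truth terms among V ranked
  # terms is t(V+1)/(t+1); the planted signal must sit far below it
  null_expect <- vapply(lengths(ann),
                        function(t) t * (length(vocab) + 1) / (t + 1), 0)
  expect_lt(mr$mean, mean(null_expect) * 0.5)
})

test_that("annotated terms rank significantly above random terms", {
  fx <- planted_fixture()
  idx <- fx$idx$biological_process
  ann <- complex_annotations(fx$db, "bp")
  subs <- subunit_list(fx$db)
  set.seed(81)
  ann_ranks <- c(); rnd_ranks <- c()
  for (i in seq_len(nrow(fx$db))) {
    qv <- compose_query_vector(fx$emb, paste(subs[[i]], collapse = " "),
                               "subunit")
    full <- query_nn(idx, qv, length(idx$names))
    pos <- match(ann[[i]], full$id)
    ann_ranks <- c(ann_ranks, pos)
    pool <- setdiff(full$id, ann[[i]])
    rnd_ranks <- c(rnd_ranks, match(sample(pool, length(pos)), full$id))
  }
  w <- stats::wilcox.test(ann_ranks, rnd_ranks, alternative = "less")
  expect_lt(w$p.value, 0.01)
})
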