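# choose()-based enumeration oracle for the hypergeometric tail
sf_oracle <- function(q, M, n, N) {
  ks <- 0:min(n, N)
  pmf <- choose(n, ks) * choose(M - n, N - ks) / choose(M, N)
  sum(pmf[ks > q])
}

test_that("hypergeometric survival matches enumeration on the full small grid", {
  for (M in 0:30) for (n in seq(0, M, by = 3)) for (N in seq(0, M, by = 3)) {
    xs <- 0:min(n, N)
    expect_equal(hypergeom_sf(xs - 1, M, n, N),
                 vapply(xs - 1, sf_oracle, 0, M = M, n = n, N = N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_sf(0, 10, 11, 5))
})

test_that("zero observed successes always yield p = 1 exactly", {
  for (M in c(5, 20, 150)) {
    expect_identical(hypergeom_sf(-1, M, 3, 4), 1)
    expect_identical(hypergeom_sf(-1, M, 0, 0), 1)
  }
})

test_that("the p-value is non-increasing in the observed count", {
  for (par in list(c(20, 6, 8), c(30, 15, 10), c(150, 12, 6))) {
    xs <- 0:min(par[2], par[3])
    p <- hypergeom_sf(xs - 1, par[1], par[2], par[3])
    expect_true(all(diff(p) <= 1e-15))
  }
})

# Fan ontology: one parent with `n_desc` children inside a vocabulary
# padded to `M` isolated terms.
fan_ontology <- function(M, n_desc) {
  ids <- sprintf("GO:95000%02d", seq_len(M))
  terms <- data.frame(id = ids, name = paste("fan term", seq_len(M)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = ids[2:(n_desc + 1)], parent = ids[1],
                      relation = "is_a", stringsAsFactors = FALSE)
  list(ont = go_ontology(terms, edges), ids = ids)
}

mk_ranking <- function(ids) {
  data.frame(rank = seq_along(ids), name = paste("nm", seq_along(ids)),
             id = ids, cosine = seq(1, 0, length.out = length(ids)))
}

test_that("enrichment on a fully descendant top list is highly significant", {
  # vocab of 50; parent with 5 descendants; the top-5 NN are exactly the
  # descendants; N_sample = 5 -> p = C(6,5) C(44,0) / C(50,5)
  fo <- fan_ontology(50, 5)
  desc_first <- c(fo$ids[2:6], fo$ids[1], fo$ids[7:50])
  res <- enrich_term(fo$ids[1], mk_ranking(desc_first), fo$ont, fo$ids,
                     N_sample = 5)
  expect_equal(res$M, 50); expect_equal(res$n, 6); expect_equal(res$x, 5)
  expect_equal(res$p_value, choose(6, 5) / choose(50, 5), tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(nrow(res$selected_children), 5)
  # children are the top-cosine descendants, in ranking order
  expect_identical(res$selected_children$go_id, fo$ids[2:6])
})

test_that("a leaf term outside the sample is never significant", {
  fo <- fan_ontology(50, 5)
  leaf <- fo$ids[50]
  res <- enrich_term(leaf, mk_ranking(fo$ids), fo$ont, fo$ids, N_sample = 5)
  expect_equal(res$x, 0)
  expect_identical(res$p_value, 1)
  expect_false(res$significant)
  expect_equal(nrow(res$selected_children), 0)
})

test_that("zero descendants in the sample never reach significance", {
  fo <- fan_ontology(40, 8)
  # push all descendants to the bottom of the ranking
  ids <- c(fo$ids[10:40], fo$ids[1], fo$ids[2:9])
  res <- enrich_term(fo$ids[1], mk_ranking(ids), fo$ont, fo$ids,
                     N_sample = 10)
  expect_equal(res$x, 0)
  expect_identical(res$p_value, 1)
  expect_false(res$significant)
})

test_that("fewer than ten descendant hits are all attached", {
  fo <- fan_ontology(60, 4)
  ids <- c(fo$ids[2:5], fo$ids[6:60], fo$ids[1])
  res <- enrich_term(fo$ids[1], mk_ranking(ids), fo$ont, fo$ids,
                     N_sample = 4)
  expect_true(res$significant)
  expect_equal(nrow(res$selected_children), 4) # < 10 available
})

test_that("sample sizes above the vocabulary are clamped with a warning", {
  fo <- fan_ontology(20, 3)
  expect_warning(
    res <- enrich_term(fo$ids[1], mk_ranking(fo$ids), fo$ont, fo$ids,
                       N_sample = 11044),
    "clamped")
  expect_equal(res$N_sample, 20)
})

test_that("subunit CC overlap intersects annotated subunits only", {
  pa <- data.frame(
    protein_id = c("SubA", "SubA", "SubB", "SubC"),
    go_id = c("GO:9500001", "GO:9500002", "GO:9500001", "GO:9500009"),
    namespace = c(rep("cellular_component", 3), "biological_process"),
    stringsAsFactors = FALSE)
  expect_setequal(subunit_cc_overlap(pa, c("suba", "subb")), "GO:9500001")
  # disjoint CC annotations
  pa2 <- pa; pa2$go_id[3] <- "GO:9500003"
  expect_length(subunit_cc_overlap(pa2, c("suba", "subb")), 0)
  # single subunit keeps its full CC set
  expect_setequal(subunit_cc_overlap(pa, "suba"),
                  c("GO:9500001", "GO:9500002"))
  # unannotated subunits are flagged, not fatal
  out <- subunit_cc_overlap(pa, c("suba", "ghost"))
  expect_equal(attr(out, "missing_subunits"), "ghost")
  expect_setequal(as.character(out), c("GO:9500001", "GO:9500002"))
  out2 <- subunit_cc_overlap(pa, "ghost")
  expect_length(out2, 0)
})

toy_bundle <- function(seed = 2, complex_row = 1, N_sample = NULL) {
  fx <- toy_fixture()
  nss <- c("biological_process", "molecular_function", "cellular_component")
  idx <- lapply(stats::setNames(nm = nss), function(ns) {
    vocab <- go_vocabulary(fx$ont, ns)
    build_index(build_sub_embedding(fx$emb, unname(fx$ont$name[vocab]),
                                    "canonical", ids = vocab))
  })
  clfs <- lapply(stats::setNames(nm = nss), function(ns) {
    ds <- build_pair_datasets(fx$db, fx$emb, fx$ont, ns, "subunit",
                              n_replicates = 1, seed = seed)[[1]]
    train_classifier(ds, "rf", seed = seed)
  })
  if (is.null(N_sample))
    N_sample <- stats::setNames(rep(10, 3), nss)
  subs <- subunit_list(fx$db)[[complex_row]]
  pa <- generate_protein_annotations(fx$db, fx$ont, fx$cfg)
  bundle <- annotate_complex(paste(subs, collapse = " "), "subunit",
                             fx$emb, idx, clfs, fx$ont,
                             N_sample = N_sample,
                             protein_annotations = pa, subunits = subs)
  list(fx = fx, bundle = bundle)
}

test_that("consolidation emits six lists with consistent DAG specs", {
  tb <- cached("toy_bundle", toy_bundle())
  b <- tb$bundle
  expect_length(b$lists, 3)
  for (ns in names(b$lists)) {
    expect_named(b$lists[[ns]], c("consolidated", "nn_only"))
    expect_lte(nrow(b$lists[[ns]]$nn_only), 20)
  }
  for (spec in b$dag_specs) {
    rf <- spec$nodes$id[spec$nodes$role == "rf_term"]
    desc <- go_descendants(tb$fx$ont, rf)
    nn <- spec$nodes$id[spec$nodes$role == "nn_term"]
    expect_true(all(nn %in% desc))
  }
  # CC consolidated list is a superset of the subunit overlap terms
  known_overlap <- intersect(b$cc_overlap,
                             go_vocabulary(tb$fx$ont, "cellular_component"))
  expect_true(all(known_overlap %in%
                    b$lists$cellular_component$consolidated$go_id))
})

test_that("an empty supervised list still yields the NN-only output", {
  fx <- toy_fixture()
  nss <- c("biological_process", "molecular_function", "cellular_component")
  rf_lists <- lapply(stats::setNames(nm = nss), function(ns)
    data.frame(go_id = character(0), go_name = character(0),
               probability = numeric(0)))
  nn_rankings <- lapply(stats::setNames(nm = nss), function(ns) {
    vocab <- go_vocabulary(fx$ont, ns)
    data.frame(rank = seq_along(vocab), name = unname(fx$ont$name[vocab]),
               id = vocab, cosine = seq(1, 0, length.out = length(vocab)))
  })
  b <- consolidate("empty test", rf_lists, nn_rankings, fx$ont,
                   N_sample = stats::setNames(rep(10, 3), nss))
  for (ns in nss) {
    expect_equal(nrow(b$lists[[ns]]$consolidated), 0)
    expect_gt(nrow(b$lists[[ns]]$nn_only), 0)
  }
  expect_length(b$dag_specs, 0)
})

test_that("written outputs are complete, well-formed and byte-stable", {
  tb <- cached("toy_bundle", toy_bundle())
  d1 <- file.path(tempfile(), "run1"); d2 <- file.path(tempfile(), "run2")
  man1 <- write_outputs(tb$bundle, tb$fx$ont, d1)
  man2 <- write_outputs(tb$bundle, tb$fx$ont, d2)
  expect_length(man1$lists, 6)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  for (f in man1$lists) {
    tab <- utils::read.delim(file.path(d1, f))
    expect_named(tab, c("rank", "go_id", "go_name", "source", "cosine",
                        "rf_probability", "p_value"))
  }
  # byte-identical across re-runs of the writer
  for (f in c(man1$lists, man1$dag_plots))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # DOT structure: a digraph with balanced braces and role colours
  if (length(man1$dag_plots) > 0) {
    dot <- readLines(file.path(d1, man1$dag_plots[1]))
    expect_match(dot[1], "^digraph")
    expect_equal(sum(grepl("\\{", dot)), sum(grepl("\\}", dot)))
    expect_true(any(grepl("fillcolor=green", dot)))
    expect_true(any(grepl("fillcolor=purple", dot)))
  }
})
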