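# Shared fixtures, generated once per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small fixture for fast unit tests.
toy_fixture <- function() {
  cached("toy", {
    cfg <- fixture_config(seed = 11, n_terms = 60L, n_complexes = 12L,
                          dim = 25L, docs_per_complex = 10L)
    ont <- generate_ontology(cfg)
    db <- generate_complex_db(ont, cfg)
    emb <- generate_planted_embedding(db, ont, cfg)
    list(cfg = cfg, ont = ont, db = db, emb = emb)
  })
}

# The planted study conditions used for the parameter-recovery and
# output-contract checks: 40 complexes, 150 terms per namespace,
# dimension 50, concentration kappa = 8, seed 7.
planted_fixture <- function() {
  cached("planted", {
    cfg <- fixture_config(seed = 7)
    ont <- generate_ontology(cfg)
    db <- generate_complex_db(ont, cfg)
    emb <- generate_planted_embedding(db, ont, cfg)
    idx <- lapply(stats::setNames(nm = c("biological_process",
                                         "molecular_function",
                                         "cellular_component")),
                  function(ns) {
                    vocab <- go_vocabulary(ont, ns)
                    build_index(build_sub_embedding(
                      emb, unname(ont$name[vocab]), "canonical", ids = vocab))
                  })
    list(cfg = cfg, ont = ont, db = db, emb = emb, idx = idx)
  })
}

# Hand-built tiny embedding: two words with orthogonal unit vectors and
# a known subword table (dimension 3).
tiny_model <- function() {
  W <- rbind(aa = c(1, 0, 0), bb = c(0, 1, 0))
  S <- rbind(ab = c(1, 1, 0), bc = c(0, 0, 2))
  embedding_model(W, S, embedding_config(dim = 3, min_count = 1))
}

# Small deterministic ontology used by the Wang / enrichment tests:
# one BP chain plus a fan-out, and an MF namespace for cross-namespace
# errors.
chain_ontology <- function() {
  terms <- data.frame(
    id = c("GO:9000001", "GO:9000002", "GO:9000003", "GO:9000004",
           "GO:9000005", "GO:9100001"),
    name = c("root process", "mid process", "leaf one", "leaf two",
             "other branch", "mf root"),
    namespace = c(rep("biological_process", 5), "molecular_function"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    id = c("GO:9000002", "GO:9000003", "GO:9000004", "GO:9000005"),
    parent = c("GO:9000001", "GO:9000002", "GO:9000002", "GO:9000001"),
    relation = c("is_a", "is_a", "is_a", "is_a"),
    stringsAsFactors = FALSE)
  go_ontology(terms, edges)
}

# Independent recursive Wang oracle: plain depth-first recursion over
# parent edges, no memoization shared with the package implementation.
wang_oracle <- function(ont, t1, t2, w = list(is_a = 0.8, part_of = 0.6)) {
  svals <- function(term) {
    out <- new.env(parent = emptyenv())
    rec <- function(t, val) {
      if (!is.null(out[[t]]) && out[[t]] >= val) return(invisible())
      out[[t]] <- val
      pe <- ont$parents[[t]]
      if (is.null(pe) || nrow(pe) == 0) return(invisible())
      for (i in seq_len(nrow(pe)))
        rec(pe$parent[i],
            val * (if (pe$relation[i] == "is_a") w$is_a else w$part_of))
    }
    rec(term, 1)
    unlist(as.list(out))
  }
  s1 <- svals(t1); s2 <- svals(t2)
  shared <- intersect(names(s1), names(s2))
  if (length(shared) == 0) return(0)
  (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
}

# Random DAG generator for property tests (single namespace).
random_dag <- function(n, seed, p_part_of = 0.2) {
  set.seed(seed)
  ids <- sprintf("GO:9%06d", seq_len(n))
  e_id <- character(); e_par <- character(); e_rel <- character()
  for (i in 2:n) {
    n_par <- sample(1:min(2, i - 1), 1)
    pars <- sample(seq_len(i - 1), n_par)
    for (p in pars) {
      e_id <- c(e_id, ids[i]); e_par <- c(e_par, ids[p])
      e_rel <- c(e_rel, if (runif(1) < p_part_of) "part_of" else "is_a")
    }
  }
  go_ontology(data.frame(id = ids, name = paste("term", seq_len(n)),
                         namespace = "biological_process",
                         stringsAsFactors = FALSE),
              data.frame(id = e_id, parent = e_par, relation = e_rel,
                         stringsAsFactors = FALSE))
}

# random unit vectors, rows unit-norm
runif_sphere <- function(n, d, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * d), n)
  m / sqrt(rowSums(m^2))
}

# rank-based AUC used only as a test oracle
.pcgo_test_auc <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
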