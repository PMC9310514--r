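#' Configuration for the synthetic fixture generators
#'
#' Defines the toy-scale study conditions every pipeline stage is tested
#' under: a random rooted DAG per GO namespace, a complex table whose
#' annotations concentrate in one "home" subtree per complex, a text
#' corpus that co-mentions subunits with annotated term names, and a
#' planted embedding in which annotated terms point near their
#' complexes' directions.
#'
#' @param seed Master seed; all generators are deterministic under
#'   `(config, seed)`.
#' @param n_terms Terms per namespace.
#' @param branching Maximum children per term during DAG growth.
#' @param max_depth Maximum term depth (root = 0).
#' @param n_complexes Number of complexes.
#' @param subunits_range Inclusive range of subunits per complex.
#' @param annotations_range Inclusive range of annotations per complex
#'   per namespace.
#' @param home_bias Fraction of a complex's annotations drawn from its
#'   home subtree.
#' @param docs_per_complex Corpus sentences mentioning each complex.
#' @param noise_fraction Fraction of corpus sentences that are pure
#'   noise from a fixed filler vocabulary.
#' @param dim Embedding dimension for planted vectors.
#' @param kappa Planted-signal concentration: annotated-term directions
#'   are the complex direction plus `N(0, I)/kappa`, renormalized.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_terms = 150L, branching = 3L,
                           max_depth = 6L, n_complexes = 40L,
                           subunits_range = c(2L, 6L),
                           annotations_range = c(2L, 5L),
                           home_bias = 0.85,
                           docs_per_complex = 30L, noise_fraction = 0.3,
                           dim = 50L, kappa = 8) {
  stopifnot(n_terms > 0, branching > 0, max_depth > 0, n_complexes > 0,
            all(subunits_range > 0), all(annotations_range > 0),
            docs_per_complex > 0, dim > 1, kappa > 0,
            noise_fraction >= 0, noise_fraction < 1)
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 branching = as.integer(branching),
                 max_depth = as.integer(max_depth),
                 n_complexes = as.integer(n_complexes),
                 subunits_range = as.integer(subunits_range),
                 annotations_range = as.integer(annotations_range),
                 home_bias = home_bias,
                 docs_per_complex = as.integer(docs_per_complex),
                 noise_fraction = noise_fraction,
                 dim = as.integer(dim), kappa = kappa),
            class = "fixture_config")
}

# pronounceable nonsense words with globally unique spellings, so every
# generated name owns its tokens and planted token vectors never clash
.word_maker <- function() {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "br", "dr", "kl", "pr", "st", "tr")
  vow <- c("a", "e", "i", "o", "u", "ae", "ia", "ou")
  used <- new.env(parent = emptyenv())
  function() {
    repeat {
      n_syl <- sample(2:3, 1)
      w <- paste0(vapply(seq_len(n_syl), function(i)
        paste0(sample(cons, 1), sample(vow, 1)), ""), collapse = "")
      if (is.null(used[[w]])) {
        used[[w]] <- TRUE
        return(w)
      }
    }
  }
}

#' Generate a synthetic GO ontology
#'
#' Builds a rooted random DAG per namespace: terms are added one at a
#' time under 1-2 existing parents with free child slots and depth below
#' `max_depth`; edges are `is_a` with occasional `part_of` (15%). Term
#' ids use the reserved synthetic range `GO:9xxxxxx` and names are
#' multi-word pronounceable strings with globally unique tokens.
#'
#' @param cfg A [fixture_config()].
#' @param path Optional path: if given, the ontology is also written as
#'   an OBO 1.2 file.
#' @return A [go_ontology()].
#' @export
generate_ontology <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  # capacity of a tree with this branching and depth
  cap <- sum(cfg$branching^seq_len(cfg$max_depth))
  if (cap < cfg$n_terms - 1)
    stop("infeasible config: branching ", cfg$branching, " and depth ",
         cfg$max_depth, " cannot hold ", cfg$n_terms, " terms")
  set.seed(cfg$seed)
  wordgen <- .word_maker()
  nss <- c(biological_process = 1L, molecular_function = 3L,
           cellular_component = 5L)
  ids <- character(); nms <- character(); nsv <- character()
  e_id <- character(); e_par <- character(); e_rel <- character()
  for (ns in names(nss)) {
    base <- 9000000L + nss[[ns]] * 100000L
    tid <- sprintf("GO:%07d", base + seq_len(cfg$n_terms) - 1L)
    depth <- integer(cfg$n_terms); n_child <- integer(cfg$n_terms)
    root_name <- if (ns == "biological_process") "biological process root"
                 else if (ns == "molecular_function") "molecular function root"
                 else "cellular component root"
    ids <- c(ids, tid[1]); nms <- c(nms, root_name); nsv <- c(nsv, ns)
    for (i in seq_len(cfg$n_terms)[-1]) {
      shallow <- which(depth[seq_len(i - 1L)] < cfg$max_depth)
      open <- shallow[n_child[shallow] < cfg$branching]
      if (length(open) == 0) {
        # branching is a soft cap: fall back to the least-loaded shallow
        # node rather than abort a feasible configuration
        if (length(shallow) == 0)
          stop("infeasible config: max_depth exhausted before n_terms")
        open <- shallow[n_child[shallow] == min(n_child[shallow])]
      }
      n_par <- if (length(open) > 1 && stats::runif(1) < 0.2) 2L else 1L
      # favour shallow parents so depth slots do not saturate
      w <- (cfg$max_depth - depth[open]) + 1L
      pars <- if (length(open) == 1) open
              else sample(open, n_par, prob = w)
      depth[i] <- max(depth[pars]) + 1L
      n_child[pars] <- n_child[pars] + 1L
      nm <- paste(vapply(seq_len(sample(2:3, 1)), function(k) wordgen(), ""),
                  collapse = " ")
      ids <- c(ids, tid[i]); nms <- c(nms, nm); nsv <- c(nsv, ns)
      for (p in pars) {
        rel <- if (stats::runif(1) < 0.15) "part_of" else "is_a"
        e_id <- c(e_id, tid[i]); e_par <- c(e_par, tid[p]); e_rel <- c(e_rel, rel)
      }
    }
  }
  ont <- go_ontology(data.frame(id = ids, name = nms, namespace = nsv,
                                stringsAsFactors = FALSE),
                     data.frame(id = e_id, parent = e_par, relation = e_rel,
                                stringsAsFactors = FALSE))
  if (!is.null(path)) write_obo(ont, path)
  ont
}

#' Generate a synthetic complex-annotation table
#'
#' Each complex receives gene-symbol-like subunit names (unique across
#' the table) and per-namespace annotations biased toward one "home"
#' subtree: a random internal term is chosen per namespace and
#' `home_bias` of the annotation draws come from that term's descendant
#' set (plus itself), the rest uniformly from the namespace. This plants
#' the parent/child structure that the enrichment test consumes.
#'
#' @param ont A [generate_ontology()] result.
#' @param cfg The same [fixture_config()].
#' @return A `complex_db` data frame; attribute `home_terms` records the
#'   per-complex home subtree roots.
#' @export
generate_complex_db <- function(ont, cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_complexes
  wordgen <- .word_maker()
  gene_symbol <- function() {
    paste0(paste(sample(letters, sample(3:5, 1), replace = TRUE),
                 collapse = ""), sample(1:99, 1))
  }
  used_syms <- character()
  nss <- c("biological_process", "molecular_function", "cellular_component")
  # candidate home roots: internal terms with a decent subtree
  home_pool <- lapply(nss, function(ns) {
    vocab <- go_vocabulary(ont, ns)
    vocab[vapply(vocab, function(t) length(go_descendants(ont, t)) >= 4, TRUE)]
  })
  names(home_pool) <- nss

  rows <- vector("list", n)
  home_terms <- vector("list", n)
  for (i in seq_len(n)) {
    n_sub <- sample(cfg$subunits_range[1]:cfg$subunits_range[2], 1)
    subs <- character(0)
    while (length(subs) < n_sub) {
      s <- gene_symbol()
      if (!s %in% used_syms) {
        subs <- c(subs, s); used_syms <- c(used_syms, s)
      }
    }
    ann <- list(); homes <- character(0)
    for (ns in nss) {
      vocab <- go_vocabulary(ont, ns)
      home <- sample(home_pool[[ns]], 1)
      homes <- c(homes, home)
      subtree <- c(home, go_descendants(ont, home))
      k <- sample(cfg$annotations_range[1]:cfg$annotations_range[2], 1)
      k <- min(k, length(vocab) - 1L)
      n_home <- min(ceiling(cfg$home_bias * k), length(subtree))
      picked <- sample(subtree, n_home)
      rest <- setdiff(vocab, picked)
      if (k - n_home > 0)
        picked <- c(picked, sample(rest, k - n_home))
      ann[[ns]] <- sort(picked)
    }
    home_terms[[i]] <- stats::setNames(homes, nss)
    rows[[i]] <- data.frame(
      complex_id = sprintf("CPX-S%03d", i),
      canonical_name = paste(wordgen(), "complex"),
      subunits = paste(subs, collapse = ";"),
      go_bp = paste(ann$biological_process, collapse = ";"),
      go_mf = paste(ann$molecular_function, collapse = ";"),
      go_cc = paste(ann$cellular_component, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  db <- do.call(rbind, rows)
  class(db) <- c("complex_db", "data.frame")
  attr(db, "home_terms") <- home_terms
  db
}

#' Generate a per-protein cellular-component annotation table
#'
#' GAF-like table (`protein_id`, `go_id`, `namespace`): every subunit of
#' a complex inherits the complex's CC annotations (so the subunit
#' intersection recovers them) plus occasional private noise terms.
#'
#' @param db A [generate_complex_db()] result.
#' @param ont The ontology.
#' @param cfg The same [fixture_config()].
#' @param noise_prob Probability that a subunit gains one extra private
#'   CC term.
#' @return Data frame with `protein_id`, `go_id`, `namespace`.
#' @export
generate_protein_annotations <- function(db, ont, cfg, noise_prob = 0.3) {
  set.seed(cfg$seed + 2L)
  vocab_cc <- go_vocabulary(ont, "cellular_component")
  subs <- subunit_list(db)
  ann_cc <- complex_annotations(db, "cellular_component")
  pid <- character(); gid <- character()
  for (i in seq_len(nrow(db))) {
    for (s in subs[[i]]) {
      terms <- ann_cc[[i]]
      if (stats::runif(1) < noise_prob)
        terms <- c(terms, sample(setdiff(vocab_cc, terms), 1))
      pid <- c(pid, rep(s, length(terms)))
      gid <- c(gid, terms)
    }
  }
  data.frame(protein_id = pid, go_id = gid,
             namespace = "cellular_component", stringsAsFactors = FALSE)
}

#' Generate a corpus with planted complex-term co-occurrence
#'
#' Writes one sentence per line: signal sentences co-mention a sample of
#' a complex's subunit names (and occasionally its canonical name) with
#' the name of one of its annotated GO terms, padded with filler words;
#' noise sentences are drawn from a fixed filler vocabulary and mixed in
#' at `noise_fraction` of the total.
#'
#' @param db A [generate_complex_db()] result.
#' @param ont The ontology.
#' @param cfg The same [fixture_config()].
#' @param path Output text file path.
#' @return `path`, invisibly; attribute `n_sentences` on the return
#'   gives the line count.
#' @export
generate_corpus <- function(db, ont, cfg, path) {
  set.seed(cfg$seed + 3L)
  filler <- c("protein", "cell", "assay", "binding", "measured", "levels",
              "observed", "study", "analysis", "results", "activity",
              "expression", "sample", "control", "pathway", "signal",
              "culture", "tissue", "model", "method", "data", "role",
              "effect", "response", "system", "function", "factor",
              "region", "domain", "structure")
  subs <- subunit_list(db)
  anns <- lapply(c("biological_process", "molecular_function",
                   "cellular_component"),
                 function(ns) complex_annotations(db, ns))
  sentences <- character(0)
  for (i in seq_len(nrow(db))) {
    for (d in seq_len(cfg$docs_per_complex)) {
      ns_idx <- sample(3, 1)
      terms <- anns[[ns_idx]][[i]]
      term <- sample(terms, 1)
      mention <- if (stats::runif(1) < 0.3) db$canonical_name[i]
                 else paste(sample(subs[[i]], min(length(subs[[i]]),
                                                  sample(2:4, 1))),
                            collapse = " ")
      pad <- sample(filler, sample(2:5, 1))
      words <- c(mention, ont$name[[term]], pad)
      sentences <- c(sentences, paste(sample(words), collapse = " "))
    }
  }
  n_noise <- round(cfg$noise_fraction / (1 - cfg$noise_fraction) *
                     length(sentences))
  for (j in seq_len(n_noise))
    sentences <- c(sentences,
                   paste(sample(filler, sample(5:10, 1), replace = TRUE),
                         collapse = " "))
  set.seed(cfg$seed + 4L)
  sentences <- sample(sentences)
  writeLines(sentences, path, useBytes = TRUE)
  out <- invisible(path)
  attr(out, "n_sentences") <- length(sentences)
  out
}

#' Generate a planted embedding (training bypass)
#'
#' Assigns every complex a uniform random unit direction; every
#' annotated GO term points at the normalized mean of its annotating
#' complexes' directions plus Gaussian noise scaled by `1/kappa`
#' (renormalized); unannotated terms are uniform on the sphere. Every
#' token of a name receives its owner's vector (tokens are globally
#' unique by construction), so composed query vectors reproduce the
#' planted geometry exactly. Subunit tokens get their complex's
#' direction plus the same noise, making subunit-scheme queries align
#' with the complex.
#'
#' @param db A [generate_complex_db()] result.
#' @param ont The ontology.
#' @param cfg The same [fixture_config()].
#' @return An [embedding_model()] with an empty subword table.
#' @export
generate_planted_embedding <- function(db, ont, cfg) {
  set.seed(cfg$seed + 5L)
  d <- cfg$dim
  runit <- function() {
    v <- stats::rnorm(d)
    v / sqrt(sum(v^2))
  }
  U <- t(vapply(seq_len(nrow(db)), function(i) runit(), numeric(d)))

  # which complexes annotate each term
  annotators <- new.env(parent = emptyenv())
  for (ns in c("bp", "mf", "cc")) {
    ann <- complex_annotations(db, ns)
    for (i in seq_along(ann))
      for (t in ann[[i]])
        annotators[[t]] <- c(annotators[[t]], i)
  }

  tokens <- character(0); vecs <- list()
  add <- function(words, vec) {
    for (w in words) {
      tokens[[length(tokens) + 1L]] <<- w
      vecs[[length(vecs) + 1L]] <<- vec
    }
  }
  for (t in ont$ids) {
    who <- annotators[[t]]
    v <- if (is.null(who)) runit() else {
      base <- colMeans(U[who, , drop = FALSE])
      base <- base / sqrt(sum(base^2))
      w <- base + stats::rnorm(d) / cfg$kappa
      w / sqrt(sum(w^2))
    }
    add(normalize_text(ont$name[[t]]), v)
  }
  subs <- subunit_list(db)
  for (i in seq_len(nrow(db))) {
    add(normalize_text(db$canonical_name[i]), U[i, ])
    for (s in subs[[i]]) {
      w <- U[i, ] + stats::rnorm(d) / cfg$kappa
      add(normalize_text(s), w / sqrt(sum(w^2)))
    }
  }
  # tokens owned by several entities (e.g. "complex", "root") carry no
  # planted signal: give them a neutral random direction
  dup_names <- unique(tokens[duplicated(tokens)])
  keep <- !duplicated(tokens)
  W <- do.call(rbind, vecs[keep])
  rownames(W) <- tokens[keep]
  for (w in dup_names) W[w, ] <- runit()
  embedding_model(W, NULL, embedding_config(dim = d, seed = cfg$seed))
}
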