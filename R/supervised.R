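#' Feature vector for a complex-GO pair
#'
#' Combines the unit-norm complex query vector and GO-term query vector
#' into one classifier input. The default, the elementwise product,
#' makes the alignment between the two vectors (their cosine is the
#' feature sum) learnable by axis-aligned methods and, crucially,
#' transfers to complexes never seen in training. Concatenation and
#' difference are provided as alternatives; note that concatenated
#' features place a held-out complex in a region of feature space that
#' training never visited, which defeats complex-level cross-validation.
#'
#' @param pc_vec,go_vec `query_vector`s (or bare numeric vectors) of the
#'   same dimension.
#' @param mode `"product"`, `"concat"` or `"difference"`.
#' @return Numeric feature vector (length `d`, or `2d` for concat).
#' @export
pair_features <- function(pc_vec, go_vec,
                          mode = c("product", "concat", "difference")) {
  mode <- match.arg(mode)
  p <- if (inherits(pc_vec, "query_vector")) pc_vec$vector else as.numeric(pc_vec)
  g <- if (inherits(go_vec, "query_vector")) go_vec$vector else as.numeric(go_vec)
  if (length(p) != length(g)) stop("pair vectors differ in dimension")
  switch(mode,
         product = p * g,
         concat = c(p, g),
         difference = p - g)
}

#' Build balanced complex-GO pair datasets with replicate negatives
#'
#' Every annotated (complex, GO) pair of the namespace is a positive
#' example; for each complex an equal number of negatives is drawn
#' uniformly without replacement from the namespace vocabulary minus the
#' complex's annotations. Replicates share all positives and differ only
#' in the negative draws (replicate r uses the derived seed
#' `seed + r - 1`).
#'
#' @param db A `complex_db` (see [read_complex_db()]).
#' @param model An [embedding_model()].
#' @param ont A [go_ontology()].
#' @param namespace Namespace to build pairs for.
#' @param scheme Complex naming scheme (`"subunit"` or `"canonical"`).
#' @param n_replicates Number of negative-sampling replicates.
#' @param seed Base seed for the negative draws.
#' @param feature_mode Passed to [pair_features()].
#' @return List of `pair_dataset`s, one per replicate; each has a
#'   feature `matrix` `x`, labels `y` (1 positive / 0 negative), and the
#'   aligned `complex_id` and `go_id` vectors.
#' @export
build_pair_datasets <- function(db, model, ont, namespace,
                                scheme = c("subunit", "canonical"),
                                n_replicates = 5L, seed = 1L,
                                feature_mode = "product") {
  scheme <- match.arg(scheme)
  namespace <- expand_namespace(namespace)
  vocab <- go_vocabulary(ont, namespace)
  ann <- complex_annotations(db, namespace)
  subs <- subunit_list(db)

  pc_vecs <- lapply(seq_len(nrow(db)), function(i) {
    qname <- if (scheme == "canonical") db$canonical_name[i]
             else paste(subs[[i]], collapse = " ")
    compose_query_vector(model, qname, scheme)$vector
  })
  go_vec_of <- new.env(parent = emptyenv())
  go_vector <- function(id) {
    if (is.null(go_vec_of[[id]]))
      go_vec_of[[id]] <- compose_query_vector(model, ont$name[[id]],
                                              "canonical")$vector
    go_vec_of[[id]]
  }

  for (i in seq_len(nrow(db))) {
    if (length(ann[[i]]) == 0)
      stop("complex without ", namespace, " annotations: ", db$complex_id[i])
    if (length(setdiff(vocab, ann[[i]])) == 0)
      stop("complex annotated with the entire vocabulary: ", db$complex_id[i])
  }

  datasets <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cid <- character(); gid <- character(); y <- integer()
    rows <- list()
    set.seed(seed + r - 1L) # one negative-sampling stream per replicate
    for (i in seq_len(nrow(db))) {
      pos <- ann[[i]]
      pool <- setdiff(vocab, pos)
      neg <- sample(pool, length(pos), replace = FALSE)
      for (g in c(pos, neg))
        rows[[length(rows) + 1L]] <- pair_features(pc_vecs[[i]], go_vector(g),
                                                   feature_mode)
      cid <- c(cid, rep(db$complex_id[i], 2L * length(pos)))
      gid <- c(gid, pos, neg)
      y <- c(y, rep(1L, length(pos)), rep(0L, length(pos)))
    }
    datasets[[r]] <- structure(list(
      namespace = namespace, scheme = scheme, replicate = r,
      x = do.call(rbind, rows), y = y,
      complex_id = cid, go_id = gid,
      seed = seed + r - 1L, feature_mode = feature_mode),
      class = "pair_dataset")
  }
  datasets
}

#' Train a classifier on a pair dataset
#'
#' Supported algorithms: random forest (`"rf"`, 100 trees,
#' sqrt-features per split), ridge-penalized logistic regression
#' (`"lr"`), Gaussian naive Bayes (`"nb_gauss"`) and Bernoulli naive
#' Bayes on sign-binarized features (`"nb_bernoulli"`). All are
#' deterministic given `seed`.
#'
#' @param dataset A `pair_dataset` (or any list with `x` and `y`).
#' @param algorithm One of `"rf"`, `"lr"`, `"nb_gauss"`, `"nb_bernoulli"`.
#' @param seed Integer seed.
#' @param ntree,mtry Random-forest size and features per split (defaults
#'   100 and `floor(sqrt(ncol(x)))`).
#' @param lambda Ridge penalty for `"lr"`.
#' @return A `trained_classifier`; use [predict_pair_prob()] to score
#'   new feature rows.
#' @export
train_classifier <- function(dataset, algorithm = c("rf", "lr", "nb_gauss",
                                                    "nb_bernoulli"),
                             seed = 1L, ntree = 100L, mtry = NULL,
                             lambda = 0.01) {
  algorithm <- match.arg(algorithm)
  x <- dataset$x; y <- dataset$y
  if (length(unique(y)) < 2) stop("dataset must contain both classes")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(seed)
  fit <- switch(algorithm,
    rf = randomForest::randomForest(
      x, factor(y, levels = c(0, 1)),
      ntree = ntree,
      mtry = if (is.null(mtry)) max(1L, floor(sqrt(ncol(x)))) else mtry),
    lr = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda),
    nb_gauss = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    nb_bernoulli = e1071::naiveBayes(
      as.data.frame(lapply(as.data.frame(x > 0),
                           factor, levels = c(FALSE, TRUE))),
      factor(y, levels = c(0, 1)), laplace = 1)
  )
  structure(list(algorithm = algorithm, fit = fit, seed = seed,
                 n_features = ncol(x),
                 namespace = dataset$namespace %||% NA_character_,
                 feature_mode = dataset$feature_mode %||% "product"),
            class = "trained_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Positive-class probability for feature rows
#' @param clf A `trained_classifier`.
#' @param x Feature matrix (rows = pairs).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_pair_prob <- function(clf, x) {
  stopifnot(inherits(clf, "trained_classifier"))
  x <- as.matrix(x)
  if (ncol(x) != clf$n_features) stop("feature dimension mismatch")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  switch(clf$algorithm,
    rf = unname(stats::predict(clf$fit, x, type = "prob")[, "1"]),
    lr = as.numeric(stats::predict(clf$fit, x, type = "response")),
    nb_gauss = unname(stats::predict(clf$fit, as.data.frame(x),
                                     type = "raw")[, "1"]),
    nb_bernoulli = unname(stats::predict(
      clf$fit,
      as.data.frame(lapply(as.data.frame(x > 0),
                           factor, levels = c(FALSE, TRUE))),
      type = "raw")[, "1"])
  )
}

#' Protein-complex leave-one-out cross-validation
#'
#' One fold per complex: all pairs (positive and negative) of the
#' held-out complex are scored by a model trained on the remaining
#' complexes' pairs, so no complex-level information leaks into its own
#' fold. AUC is the trapezoidal area under the ROC of the pooled
#' held-out scores; a per-fold mean AUC and precision-recall points are
#' also reported.
#'
#' @inheritParams build_pair_datasets
#' @param algorithm Classifier passed to [train_classifier()].
#' @param dataset Optional pre-built `pair_dataset` (replicate 1 is
#'   built internally when omitted).
#' @param permute_labels If `TRUE`, labels are globally shuffled before
#'   training (null-control mode; the pooled AUC should fall near 0.5).
#' @return A `cv_report`: list with `predictions` (complex_id, go_id,
#'   label, score), pooled `auc`, `fold_auc` mean, `pr_curve` points,
#'   `accuracy` and `f1` at the 0.5 threshold.
#' @export
pc_loocv <- function(db, model, ont, namespace,
                     scheme = c("subunit", "canonical"),
                     algorithm = "rf", seed = 1L,
                     feature_mode = "product", dataset = NULL,
                     permute_labels = FALSE) {
  scheme <- match.arg(scheme)
  if (nrow(db) < 3) stop("need at least 3 complexes for complex-level LOOCV")
  if (is.null(dataset))
    dataset <- build_pair_datasets(db, model, ont, namespace, scheme,
                                   n_replicates = 1L, seed = seed,
                                   feature_mode = feature_mode)[[1]]
  y <- dataset$y
  if (permute_labels) {
    set.seed(seed + 104729L)
    y <- sample(y)
  }
  cxs <- unique(dataset$complex_id)
  score <- rep(NA_real_, length(y))
  fold_auc <- numeric(0)
  leakage_free <- TRUE
  for (cx in cxs) {
    test <- dataset$complex_id == cx
    train_ids <- dataset$complex_id[!test]
    leakage_free <- leakage_free && !cx %in% train_ids
    train <- structure(list(x = dataset$x[!test, , drop = FALSE],
                            y = y[!test],
                            namespace = dataset$namespace,
                            feature_mode = dataset$feature_mode),
                       class = "pair_dataset")
    clf <- train_classifier(train, algorithm, seed = seed)
    score[test] <- predict_pair_prob(clf, dataset$x[test, , drop = FALSE])
    if (length(unique(y[test])) == 2)
      fold_auc <- c(fold_auc, .auc(score[test], y[test]))
  }
  pred <- data.frame(complex_id = dataset$complex_id, go_id = dataset$go_id,
                     label = y, score = score, stringsAsFactors = FALSE)
  hard <- as.integer(score > 0.5)
  tp <- sum(hard == 1 & y == 1); fp <- sum(hard == 1 & y == 0)
  fn <- sum(hard == 0 & y == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(predictions = pred,
                 auc = .auc(score, y),
                 fold_auc_mean = if (length(fold_auc)) mean(fold_auc) else NA_real_,
                 pr_curve = .pr_curve(score, y),
                 accuracy = mean(hard == y),
                 f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
                   2 * prec * rec / (prec + rec) else NA_real_,
                 algorithm = algorithm, namespace = dataset$namespace,
                 scheme = scheme, n_folds = length(cxs),
                 leakage_free = leakage_free),
            class = "cv_report")
}

# trapezoidal ROC AUC via pROC
.auc <- function(score, label) {
  as.numeric(pROC::auc(pROC::roc(response = label, predictor = score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

.pr_curve <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  data.frame(recall = tp / sum(lab == 1),
             precision = tp / (tp + fp))
}

#' @method print cv_report
#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s, %s, %s): %d folds, pooled AUC %.3f, acc %.3f\n",
              x$algorithm, x$namespace, x$scheme, x$n_folds, x$auc,
              x$accuracy))
  invisible(x)
}

#' Capped supervised prediction list for one complex
#'
#' Scores every term of the namespace sub-embedding with the trained
#' classifier, keeps terms with positive-class probability above
#' `threshold`, sorts by decreasing probability and truncates at `cap`.
#'
#' @param clf A `trained_classifier`.
#' @param pc_vec `query_vector` of the complex.
#' @param sub A `sub_embedding` of the namespace GO terms (ids = GO
#'   accessions).
#' @param threshold Probability cut-off (exclusive).
#' @param cap Maximum list length.
#' @return An `rf_prediction_list` data frame with columns `go_id`,
#'   `go_name`, `probability` (non-increasing); may have zero rows.
#' @export
predict_rf_list <- function(clf, pc_vec, sub, threshold = 0.5, cap = 10L) {
  stopifnot(inherits(sub, "sub_embedding"))
  if (nrow(sub$matrix) == 0) stop("sub-embedding is empty")
  p <- if (inherits(pc_vec, "query_vector")) pc_vec$vector else as.numeric(pc_vec)
  feats <- t(apply(sub$matrix, 1, function(g)
    pair_features(p, g, clf$feature_mode)))
  prob <- predict_pair_prob(clf, feats)
  keep <- which(prob > threshold)
  keep <- keep[order(-prob[keep], sub$names[keep])]
  keep <- utils::head(keep, cap)
  out <- data.frame(go_id = sub$ids[keep], go_name = sub$names[keep],
                    probability = prob[keep], stringsAsFactors = FALSE)
  class(out) <- c("rf_prediction_list", "data.frame")
  out
}
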