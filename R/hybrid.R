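# Hybrid pipeline: classical classifiers (random forest, k-nearest
# neighbours, support vector machine) trained on the network's fused
# features, evaluated with the same fold protocol and metrics.

#' Classify extracted features with a conventional classifier
#'
#' Trains the named classifier on the training rows of each fold split and
#' evaluates on the test rows with [compute_metrics()].  Classifiers are the
#' standard library implementations at their defaults (`randomForest`,
#' `class::knn` with k = 5, `e1071::svm` radial), with the RNG pinned per
#' fold for reproducibility.
#'
#' @param features numeric matrix (n x p), e.g. from [extract_features()].
#' @param labels integer labels (0/1), length n.
#' @param splits list of `fold_split`s from [make_folds()].
#' @param classifier one of `"rf"`, `"knn"`, `"svm"`.
#' @param seed RNG seed.
#' @return a `metrics_aggregate` over the splits.
#' @export
hybrid_classify <- function(features, labels, splits,
                            classifier = c("rf", "knn", "svm"), seed = 1L) {
  classifier <- match.arg(classifier)
  labels <- as.integer(labels)
  per_fold <- lapply(splits, function(sp) {
    tr <- sp$train_ids; te <- sp$test_ids
    pred <- with_seed(seed + sp$fold_index, switch(
      classifier,
      rf = {
        fit <- randomForest::randomForest(features[tr, , drop = FALSE],
                                          factor(labels[tr],
                                                 levels = c(0, 1)))
        as.integer(as.character(stats::predict(fit,
                                               features[te, , drop = FALSE])))
      },
      knn = as.integer(as.character(
        class::knn(features[tr, , drop = FALSE],
                   features[te, , drop = FALSE],
                   factor(labels[tr], levels = c(0, 1)), k = 5))),
      svm = {
        fit <- e1071::svm(features[tr, , drop = FALSE],
                          factor(labels[tr], levels = c(0, 1)))
        as.integer(as.character(stats::predict(fit,
                                               features[te, , drop = FALSE])))
      }))
    compute_metrics(labels[te], pred)
  })
  aggregate_metrics(per_fold)
}
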