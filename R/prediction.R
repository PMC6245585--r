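# Per-term protein-function prediction with class-weighted linear SVMs and
# random forests under nested 3-fold cross-validation, plus the
# leave-one-feature-out ablation.

#' Classifier specification
#'
#' @param family `"linear_svm"` or `"random_forest"`.
#' @param C_grid SVM misclassification-cost grid.
#' @param mtry_grid RF `mtry` grid; when `NULL` it is derived from the
#'   feature count d as `{ceil(sqrt(d))/2, ceil(sqrt(d)), 2*ceil(sqrt(d)),
#'   d/2}` clipped to `[1, d]`.
#' @param ntree number of RF trees.
#' @param class_weights apply the per-term class weights to the SVM
#'   (weights 1 and `(n-p)/p` for the negative and positive class).
#' @param seed base seed for fold assignment and RF randomness.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("linear_svm", "random_forest"),
                            C_grid = c(0.01, 0.1, 1, 10, 100),
                            mtry_grid = NULL, ntree = 500,
                            class_weights = TRUE, seed = 1) {
  family <- match.arg(family)
  structure(list(family = family, C_grid = C_grid, mtry_grid = mtry_grid,
                 ntree = ntree, class_weights = class_weights, seed = seed),
            class = "classifier_spec")
}

default_mtry_grid <- function(d) {
  r <- ceiling(sqrt(d))
  g <- unique(pmin(pmax(c(floor(r / 2), r, 2 * r, floor(d / 2)), 1), d))
  sort(g)
}

#' Class weights for a term
#'
#' The SVM class weights for term `k` are 1 for the negative class and
#' `(n - p) / p` for the positive class, with `p` the number of old-release
#' positives, counterbalancing the rarity of positives.
#'
#' @param older an `annotation_release`.
#' @param k term identifier.
#' @return Numeric vector `c(negative = 1, positive = (n - p) / p)`.
#' @export
class_weight_for_term <- function(older, k) {
  if (!k %in% colnames(older$Y)) stop("unknown term '", k, "'")
  p <- sum(older$Y[, k])
  n <- nrow(older$Y)
  if (p == 0) stop("term '", k, "' has no positives")
  if (p == n) stop("term '", k, "' has no negatives (degenerate)")
  c(negative = 1, positive = (n - p) / p)
}

hyper_grid <- function(spec, d) {
  if (spec$family == "linear_svm") spec$C_grid
  else spec$mtry_grid %||% default_mtry_grid(d)
}

# Fit one model; returns NULL when the training labels are single-class
# (callers treat NULL as "predict the majority class / score 0").
fit_model <- function(spec, X, y, hyper, weights = NULL, seed = 1) {
  yf <- factor(y, levels = c(0, 1))
  if (length(unique(y)) < 2) return(NULL)
  if (spec$family == "linear_svm") {
    cw <- if (!is.null(weights)) c("0" = unname(weights[1]),
                                   "1" = unname(weights[2])) else NULL
    # e1071 standardizes columns internally; constant columns only trigger a
    # scaling warning, which is irrelevant for fitting.
    suppressWarnings(
      e1071::svm(x = X, y = yf, kernel = "linear", cost = hyper,
                 class.weights = cw, scale = TRUE))
  } else {
    with_seed(seed,
      randomForest::randomForest(x = as.data.frame(X), y = yf,
                                 mtry = hyper, ntree = spec$ntree))
  }
}

predict_class <- function(model, X) {
  if (is.null(model)) return(rep(0L, nrow(X)))
  if (inherits(model, "svm")) as.integer(as.character(predict(model, X)))
  else as.integer(as.character(predict(model, as.data.frame(X))))
}

# Positive-class score: SVM decision value oriented toward class "1", or the
# RF positive-class vote fraction.
predict_score <- function(model, X) {
  if (is.null(model)) return(rep(0, nrow(X)))
  if (inherits(model, "svm")) {
    p <- predict(model, X, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    s <- as.numeric(dv[, 1])
    if (startsWith(colnames(dv)[1], "0")) -s else s
  } else {
    as.numeric(predict(model, as.data.frame(X), type = "prob")[, "1"])
  }
}

# Inner k-fold CV selection of the hyperparameter maximizing mean F1.
# Ties keep the first grid point. Returns list(hyper, f1).
tune_hyper <- function(spec, X, y, weights, folds = 3, seed = 1) {
  grid <- hyper_grid(spec, ncol(X))
  fold <- stratified_folds(y, folds, seed = seed)
  scores <- vapply(seq_along(grid), function(g) {
    fs <- numeric(max(fold))
    for (f in seq_len(max(fold))) {
      tr <- fold != f; te <- fold == f
      m <- fit_model(spec, X[tr, , drop = FALSE], y[tr], grid[g], weights,
                     seed = derive_seed(seed, g, f))
      fs[f] <- binary_f1(y[te], predict_class(m, X[te, , drop = FALSE]))[["f1"]]
    }
    mean(fs)
  }, numeric(1))
  best <- which.max(scores)
  list(hyper = grid[best], f1 = scores[best])
}

#' Nested cross-validated evaluation of one term
#'
#' Stratified 3-fold outer CV; on each outer-training portion an inner
#' 3-fold CV selects the hyperparameter (C for the SVM, mtry for the RF)
#' maximizing F1; the refit model is scored on the outer test fold. F1,
#' precision and recall are reported per fold and averaged.
#'
#' @param matrix a `term_feature_matrix` (or plain matrix) over all proteins.
#' @param labels 0/1 vector of old-release annotations for the term.
#' @param spec a [classifier_spec()].
#' @param weights optional class-weight pair from [class_weight_for_term()].
#' @param outer_folds,inner_folds protocol sizes.
#' @param representation tag recorded in the output.
#' @return A `prediction_metrics` list: `folds` data frame and `mean`
#'   (named vector `f1`, `precision`, `recall`), or `NULL` if some outer
#'   fold is single-class (term skipped, with a message).
#' @export
nested_cv_evaluate <- function(matrix, labels, spec, weights = NULL,
                               outer_folds = 3, inner_folds = 3,
                               representation = "") {
  X <- unclass(matrix)
  y <- labels
  if (length(unique(y)) < 2) {
    message("term skipped: single-class labels")
    return(NULL)
  }
  fold <- stratified_folds(y, outer_folds, seed = spec$seed)
  recs <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 1 ||
        sum(te) == 0) {
      message("term skipped: degenerate outer fold")
      return(NULL)
    }
    tuned <- tune_hyper(spec, X[tr, , drop = FALSE], y[tr], weights,
                        folds = inner_folds, seed = derive_seed(spec$seed, f))
    m <- fit_model(spec, X[tr, , drop = FALSE], y[tr], tuned$hyper, weights,
                   seed = derive_seed(spec$seed, f, 999))
    met <- binary_f1(y[te], predict_class(m, X[te, , drop = FALSE]))
    recs[[f]] <- data.frame(fold = f, hyper = tuned$hyper,
                            f1 = met[["f1"]], precision = met[["precision"]],
                            recall = met[["recall"]])
  }
  folds <- do.call(rbind, recs)
  structure(list(folds = folds,
                 mean = c(f1 = mean(folds$f1),
                          precision = mean(folds$precision),
                          recall = mean(folds$recall)),
                 representation = representation, family = spec$family),
            class = "prediction_metrics")
}

#' Leave-one-feature-out ablation
#'
#' Repeats [nested_cv_evaluate()] removing one feature of `pool` at a
#' time and evaluating on the remaining columns. The random-walk features
#' are deliberately not part of the default pool, so the ablation covers
#' f1--f14 only.
#'
#' @param matrix feature matrix over all proteins (must contain `pool`).
#' @param labels 0/1 labels for the term.
#' @param spec a [classifier_spec()].
#' @param pool features removed in turn (default `f1..f14`).
#' @param weights optional SVM class weights.
#' @return Named list of `prediction_metrics`, one per removed feature,
#'   tagged `ablation:-fk`.
#' @export
ablation_study <- function(matrix, labels, spec, pool = paste0("f", 1:14),
                           weights = NULL) {
  stopifnot(all(pool %in% colnames(matrix)))
  out <- lapply(pool, function(fk) {
    keep <- setdiff(pool, fk)
    nested_cv_evaluate(matrix[, keep, drop = FALSE], labels, spec,
                       weights = weights,
                       representation = paste0("ablation:-", fk))
  })
  names(out) <- pool
  out
}
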