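# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points funnel through
# this so that results are reproducible and do not disturb the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministically derive a child seed from a base seed and one or more
# integer tags; result stays in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (t in tags) x <- (x * 48271 + as.double(t) + 1) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

#' F1 score for binary labels
#'
#' F1 = 2PR/(P+R) with the convention that precision, recall and F1 are 0
#' when their denominators vanish (e.g. a classifier predicting no
#' positives). Inputs are 0/1 vectors (or factors coercible to them).
#'
#' @param truth observed 0/1 labels.
#' @param pred predicted 0/1 labels.
#' @return Named numeric vector with elements `f1`, `precision`, `recall`.
#' @export
binary_f1 <- function(truth, pred) {
  truth <- as.integer(as.character(truth))
  pred <- as.integer(as.character(pred))
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(f1 = f1, precision = prec, recall = rec)
}

# Label-stratified fold assignment: within each class, instances are shuffled
# and dealt round-robin into k folds, so class proportions are as balanced as
# integer counts allow. Returns an integer vector of fold ids in 1..k.
stratified_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- if (length(idx) > 1) sample(idx) else idx
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

feature_names_all <- function() paste0("f", 1:17)

# Canonical order for tie-breaking among feature names f1..f17.
feature_rank <- function(x) as.integer(sub("^f", "", x))
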