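# Feature-relevance experiment: CART-wrapped sequential floating forward
# selection (SFFS) on the C_np classification problem, run under the
# three-subset / triple 3-fold cross-validation protocol, aggregated into
# per-feature selection frequencies.

#' Configuration for the SFFS wrapper
#'
#' @param pool candidate feature names (subset of `f1..f17`).
#' @param inner_folds folds of the wrapper's cross-validated criterion.
#' @param max_size largest subset the search may return.
#' @param seed RNG seed fixing the fold assignment.
#' @param rpart_control CART settings; default is a depth-unlimited tree
#'   with minimum leaf size 2 and no internal pruning cross-validation.
#' @return An `sffs_config` list.
#' @export
sffs_config <- function(pool, inner_folds = 3, max_size = length(pool),
                        seed = 1,
                        rpart_control = rpart::rpart.control(
                          minsplit = 4, minbucket = 2, cp = 0,
                          maxdepth = 30, xval = 0)) {
  stopifnot(length(pool) >= 1, inner_folds >= 2)
  structure(list(pool = pool, inner_folds = inner_folds,
                 max_size = max_size, seed = seed,
                 rpart_control = rpart_control),
            class = "sffs_config")
}

# Mean F1 of a CART classifier over pre-assigned CV folds, for one feature
# subset. Returns 0 for the empty subset (the no-model baseline).
cart_cv_f1 <- function(X, y, feats, fold, control) {
  if (length(feats) == 0) return(0)
  k <- max(fold)
  scores <- numeric(k)
  df <- data.frame(X[, feats, drop = FALSE])
  df$.lab <- factor(y, levels = c(0, 1))
  for (f in seq_len(k)) {
    tr <- df[fold != f, , drop = FALSE]
    te <- df[fold == f, , drop = FALSE]
    if (length(unique(tr$.lab)) < 2 || nrow(te) == 0) {
      scores[f] <- 0
      next
    }
    fit <- rpart::rpart(.lab ~ ., data = tr, method = "class",
                        control = control)
    pred <- predict(fit, te, type = "class")
    scores[f] <- binary_f1(te$.lab, pred)[["f1"]]
  }
  mean(scores)
}

#' Instance set for the relevance experiment of one term
#'
#' Instances are the old-release non-positives of term `k`; the label is 1
#' iff the protein belongs to `C_np(k)` (it became positive in the newer
#' release) and 0 iff it stayed unannotated in both releases. Terms with
#' fewer than two instances in either class are unusable and yield `NULL`
#' (with a message).
#'
#' @param holdout a `temporal_holdout`.
#' @param term_matrix a `term_feature_matrix` for `k` over all proteins.
#' @param k term identifier.
#' @return A `relevance_instances` list (`X`, `labels`, `proteins`) or
#'   `NULL` when the term is degenerate.
#' @export
build_instances <- function(holdout, term_matrix, k) {
  Y <- holdout$older$Y
  if (!k %in% colnames(Y)) stop("unknown term '", k, "'")
  prot <- rownames(Y)[Y[, k] == 0L]
  lab <- as.integer(prot %in% holdout$cnp[[k]])
  if (sum(lab == 1) < 2 || sum(lab == 0) < 2) {
    message("term ", k, " skipped: fewer than 2 instances in one class")
    return(NULL)
  }
  structure(list(X = term_matrix[prot, , drop = FALSE], labels = lab,
                 proteins = prot), class = "relevance_instances")
}

#' Sequential floating forward selection with a CART wrapper
#'
#' Classic SFFS: repeatedly add the feature whose inclusion maximizes the
#' inner cross-validated F1 of a CART classifier, then float backwards,
#' removing features while a removal strictly improves on the best
#' criterion previously seen at the smaller size. The search stops when no
#' addition strictly improves the criterion or `max_size` is reached.
#' Given a seed the procedure is fully deterministic (fixed fold
#' assignment; ties broken by canonical feature order).
#'
#' @param instances a `relevance_instances` set.
#' @param cfg an [sffs_config()].
#' @return List with `features` (selected subset, canonical order),
#'   `criterion` (its inner-CV F1) and `trace` (per-step log).
#' @export
sffs_select <- function(instances, cfg) {
  stopifnot(inherits(instances, "relevance_instances"),
            inherits(cfg, "sffs_config"))
  X <- instances$X; y <- instances$labels
  pool <- cfg$pool
  if (!all(pool %in% colnames(X))) stop("pool features missing from matrix")
  fold <- stratified_folds(y, cfg$inner_folds, seed = cfg$seed)
  cache <- new.env(parent = emptyenv())
  crit <- function(feats) {
    feats <- feats[order(feature_rank(feats))]
    key <- paste(feats, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- cart_cv_f1(X, y, feats, fold, cfg$rpart_control)
    cache[[key]] <- v
    v
  }
  eps <- 1e-12
  sel <- character(0)
  best_at_size <- numeric(cfg$max_size + 1)  # best criterion seen per size+1
  best_at_size[] <- -Inf
  best_at_size[1] <- 0                       # empty set baseline
  cur <- 0
  trace <- list()
  repeat {
    if (length(sel) >= cfg$max_size) break
    cand <- setdiff(pool, sel)
    if (length(cand) == 0) break
    vals <- vapply(cand, function(f) crit(c(sel, f)), numeric(1))
    ord <- order(-vals, feature_rank(cand))
    fbest <- cand[ord[1]]; vbest <- unname(vals[ord[1]])
    if (vbest <= cur + eps) break
    sel <- c(sel, fbest); cur <- vbest
    if (cur > best_at_size[length(sel) + 1]) best_at_size[length(sel) + 1] <- cur
    trace[[length(trace) + 1]] <- list(step = "add", feature = fbest, crit = cur)
    # Floating removal phase.
    while (length(sel) > 2) {
      vals_r <- vapply(sel, function(f) crit(setdiff(sel, f)), numeric(1))
      ord_r <- order(-vals_r, feature_rank(sel))
      rbest <- sel[ord_r[1]]; vr <- unname(vals_r[ord_r[1]])
      if (vr > best_at_size[length(sel)] + eps) {
        sel <- setdiff(sel, rbest); cur <- vr
        best_at_size[length(sel) + 1] <- cur
        trace[[length(trace) + 1]] <- list(step = "remove", feature = rbest,
                                           crit = cur)
      } else break
    }
  }
  list(features = sel[order(feature_rank(sel))], criterion = cur, trace = trace)
}

#' Triple-loop relevance experiment over a set of terms
#'
#' For every term: instances are split into three non-overlapping
#' label-stratified subsets; within each subset a 3-fold outer CV is run;
#' on each outer-training portion [sffs_select()] is executed (inner
#' 3-fold F1 criterion) and the selected subset is validated by F1 on the
#' outer test fold. Each of the 3 x 3 = 9 selection events per term
#' increments the counters of its selected features; the table reports the
#' proportion of events in which each feature was selected.
#'
#' @param net a `weighted_network`.
#' @param holdout a `temporal_holdout`.
#' @param terms term identifiers to process (typically the output of
#'   [filter_terms()] with the `min_cnp` rule).
#' @param pool candidate feature names.
#' @param seed base RNG seed; per-term and per-fold seeds are derived.
#' @param n_subsets,outer_folds,inner_folds protocol sizes (3/3/3).
#' @param cache optional [network_feature_cache()].
#' @param max_size cap on the SFFS subset size.
#' @return A `feature_frequency_table` data frame with columns `feature`,
#'   `count`, `runs`, `proportion`, plus attributes `pool`,
#'   `mean_proportion`, `outer_f1` and `skipped`.
#' @export
triple_loop_relevance <- function(net, holdout, terms,
                                  pool = paste0("f", 1:14), seed = 1,
                                  n_subsets = 3, outer_folds = 3,
                                  inner_folds = 3, cache = NULL,
                                  max_size = length(pool)) {
  if (length(terms) == 0) stop("no terms to process")
  if (is.null(cache)) cache <- network_feature_cache(net)
  counts <- stats::setNames(numeric(length(pool)), pool)
  runs <- 0L
  skipped <- character(0)
  outer_f1 <- numeric(0)
  for (ti in seq_along(terms)) {
    k <- terms[ti]
    mat <- assemble_term_matrix(net, holdout, k, features = pool, cache = cache)
    inst <- build_instances(holdout, mat, k)
    if (is.null(inst)) { skipped <- c(skipped, k); next }
    subset_id <- stratified_folds(inst$labels, n_subsets,
                                  seed = derive_seed(seed, ti, 0))
    for (s in seq_len(n_subsets)) {
      idx <- which(subset_id == s)
      Xs <- inst$X[idx, , drop = FALSE]; ys <- inst$labels[idx]
      if (sum(ys == 1) < 2 || sum(ys == 0) < 2) next
      fold <- stratified_folds(ys, outer_folds, seed = derive_seed(seed, ti, s))
      for (f in seq_len(outer_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        if (length(unique(ys[tr])) < 2 || length(te) == 0) next
        sub_inst <- structure(list(X = Xs[tr, , drop = FALSE],
                                   labels = ys[tr],
                                   proteins = inst$proteins[idx][tr]),
                              class = "relevance_instances")
        cfg <- sffs_config(pool, inner_folds = inner_folds,
                           max_size = max_size,
                           seed = derive_seed(seed, ti, s, f))
        res <- sffs_select(sub_inst, cfg)
        runs <- runs + 1L
        if (length(res$features)) {
          counts[res$features] <- counts[res$features] + 1
          df <- data.frame(Xs[, res$features, drop = FALSE])
          df$.lab <- factor(ys, levels = c(0, 1))
          fit <- rpart::rpart(.lab ~ ., data = df[tr, , drop = FALSE],
                              method = "class", control = cfg$rpart_control)
          pred <- predict(fit, df[te, , drop = FALSE], type = "class")
          outer_f1 <- c(outer_f1, binary_f1(ys[te], pred)[["f1"]])
        } else {
          outer_f1 <- c(outer_f1, 0)
        }
      }
    }
  }
  if (runs == 0L) stop("every term was skipped; no selection events")
  tab <- data.frame(feature = pool, count = as.numeric(counts),
                    runs = runs, proportion = as.numeric(counts) / runs,
                    row.names = NULL)
  structure(tab, pool = pool, mean_proportion = mean(tab$proportion),
            outer_f1 = outer_f1, skipped = skipped,
            class = c("feature_frequency_table", "data.frame"))
}

#' Reduce a frequency table to a feature subset
#'
#' `top_q` returns the `q` features with the highest selection proportion
#' (ties broken by canonical feature order); `mean` returns the features
#' whose proportion is strictly greater than the mean proportion of the
#' pool (so a perfectly flat table yields an empty subset, with a warning).
#'
#' @param table a `feature_frequency_table`.
#' @param rule `"top_q"` or `"mean"`.
#' @param q subset size for `top_q`.
#' @return Character vector of feature names in canonical order.
#' @export
subset_by_rule <- function(table, rule = c("top_q", "mean"), q = 5) {
  rule <- match.arg(rule)
  stopifnot(nrow(table) >= 1)
  if (rule == "top_q") {
    if (q > nrow(table)) stop("q exceeds the pool size")
    ord <- order(-table$proportion, feature_rank(table$feature))
    out <- table$feature[ord[seq_len(q)]]
  } else {
    m <- mean(table$proportion)
    out <- table$feature[table$proportion > m]
    if (length(out) == 0)
      warning("no feature exceeds the mean proportion; empty subset")
  }
  out[order(feature_rank(out))]
}
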