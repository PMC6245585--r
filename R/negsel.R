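# Budgeted negative selection: per-term models trained on the older release
# rank the non-positive candidates; the bottom-ranked ones are selected as
# reliable negatives and false negatives (C_np members among them) counted
# across a grid of budgets.

#' The seven canonical feature configurations
#'
#' Resolves a configuration name to a concrete feature set. Rule-based
#' configurations (`topq`, `mean`) require the corresponding frequency
#' table from the relevance experiment.
#'
#' @param name one of `"f15-f17"`, `"f1-f14-topq"`, `"f1-f14-mean"`,
#'   `"f1-f14"`, `"f1-f17-topq"`, `"f1-f17-mean"`, `"f1-f17"`.
#' @param freq_f14 `feature_frequency_table` computed over pool f1--f14.
#' @param freq_f17 `feature_frequency_table` computed over pool f1--f17.
#' @param q subset size of the `topq` rule.
#' @return Character vector of feature names.
#' @export
resolve_configuration <- function(name, freq_f14 = NULL, freq_f17 = NULL,
                                  q = 5) {
  need14 <- function() {
    if (is.null(freq_f14)) stop("configuration '", name,
                                "' needs the f1-f14 frequency table")
    freq_f14
  }
  need17 <- function() {
    if (is.null(freq_f17)) stop("configuration '", name,
                                "' needs the f1-f17 frequency table")
    freq_f17
  }
  switch(name,
    "f15-f17" = paste0("f", 15:17),
    "f1-f14" = paste0("f", 1:14),
    "f1-f17" = paste0("f", 1:17),
    "f1-f14-topq" = subset_by_rule(need14(), "top_q", q = q),
    "f1-f14-mean" = subset_by_rule(need14(), "mean"),
    "f1-f17-topq" = subset_by_rule(need17(), "top_q", q = q),
    "f1-f17-mean" = subset_by_rule(need17(), "mean"),
    stop("unknown configuration '", name, "'"))
}

#' @rdname resolve_configuration
#' @export
negsel_configurations <- function() {
  c("f15-f17", "f1-f14-topq", "f1-f14-mean", "f1-f14",
    "f1-f17-topq", "f1-f17-mean", "f1-f17")
}

#' Rank candidate negatives for one term
#'
#' Trains the model on all proteins with the older-release labels (positives
#' = annotated for `k`), tunes its hyperparameter by stratified 3-fold CV
#' maximizing F1, and orders the candidates (old-release non-positives) by
#' ascending positive-class score: the SVM decision value or the RF
#' positive-class probability. Bottom-ranked candidates are the ones a
#' budgeted selection takes first. Score ties are broken by protein
#' identifier for determinism.
#'
#' @param matrix feature matrix over all proteins (columns already
#'   restricted to the configuration in use).
#' @param older an `annotation_release`.
#' @param k term identifier.
#' @param spec a [classifier_spec()].
#' @return Data frame `protein`, `score` ordered by ascending score, or
#'   `NULL` when the term's labels are degenerate.
#' @export
rank_candidates <- function(matrix, older, k, spec) {
  y <- as.integer(older$Y[, k])
  if (length(unique(y)) < 2) {
    message("term ", k, " skipped: degenerate labels")
    return(NULL)
  }
  X <- unclass(matrix)
  weights <- if (spec$family == "linear_svm" && spec$class_weights)
    class_weight_for_term(older, k) else NULL
  tuned <- tune_hyper(spec, X, y, weights, folds = 3,
                      seed = derive_seed(spec$seed, 7))
  m <- fit_model(spec, X, y, tuned$hyper, weights,
                 seed = derive_seed(spec$seed, 7, 999))
  cand <- which(y == 0)
  sc <- predict_score(m, X[cand, , drop = FALSE])
  prot <- rownames(older$Y)[cand]
  ord <- order(sc, prot)
  data.frame(protein = prot[ord], score = sc[ord], row.names = NULL)
}

#' Budgeted selection from a ranking
#'
#' For each percentage `x` of `budgets_pct` the budget is
#' `floor(x * n / 100)` with `n` the total protein count (raised to 1 when
#' the floor is 0, capped at the candidate-pool size), and the selection is
#' the corresponding prefix of the ascending-score ranking.
#'
#' @param ranking output of [rank_candidates()].
#' @param n_total total number of proteins in the network.
#' @param budgets_pct percentage grid (default `c(1,5,10,15,20,25,30)`).
#' @return Named list of character vectors (selected proteins per budget).
#' @export
select_at_budget <- function(ranking, n_total,
                             budgets_pct = c(1, 5, 10, 15, 20, 25, 30)) {
  stopifnot(nrow(ranking) >= 1)
  out <- lapply(budgets_pct, function(x) {
    b <- max(1L, floor(x * n_total / 100))
    if (b > nrow(ranking)) b <- nrow(ranking)
    ranking$protein[seq_len(b)]
  })
  names(out) <- as.character(budgets_pct)
  out
}

#' Count false negatives in a selection
#'
#' A false negative is a `C_np` protein (one that became positive in the
#' newer release) chosen as a reliable negative.
#'
#' @param selected character vector of selected proteins.
#' @param cnp_set character vector, the `C_np` members of the term.
#' @return Integer count `|selected intersect C_np|`.
#' @export
count_false_negatives <- function(selected, cnp_set) {
  length(intersect(selected, cnp_set))
}

#' Full negative-selection experiment
#'
#' Crosses feature configurations x model families x budgets over a term
#' set, counting per-term false negatives and averaging across terms. Each
#' cell also carries the random-selection expectation
#' `budget * |C_np intersect candidates| / |candidates|`.
#'
#' @param net a `weighted_network`.
#' @param holdout a `temporal_holdout`.
#' @param terms terms to evaluate (typically [filter_terms()] with the
#'   `annotation_range` rule).
#' @param configurations configuration names (see
#'   [negsel_configurations()]).
#' @param models character subset of `c("linear_svm", "random_forest")`.
#' @param budgets_pct budget percentages.
#' @param freq_f14,freq_f17 frequency tables backing the rule-based
#'   configurations.
#' @param seed base seed.
#' @param cache optional [network_feature_cache()].
#' @return A `negsel_report`: list with `per_term` and `summary` data
#'   frames (`configuration`, `model`, `budget_pct`, `mean_fn`,
#'   `baseline_fn`, `n_terms`) plus `skipped`.
#' @export
evaluate_configurations <- function(net, holdout, terms,
                                    configurations = negsel_configurations(),
                                    models = c("linear_svm", "random_forest"),
                                    budgets_pct = c(1, 5, 10, 15, 20, 25, 30),
                                    freq_f14 = NULL, freq_f17 = NULL,
                                    seed = 1, cache = NULL) {
  if (is.null(cache)) cache <- network_feature_cache(net)
  n_total <- length(net$node_labels)
  rows <- list()
  skipped <- character(0)
  for (ti in seq_along(terms)) {
    k <- terms[ti]
    mat <- assemble_term_matrix(net, holdout, k, cache = cache)
    cnp <- holdout$cnp[[k]]
    cand_n <- sum(holdout$older$Y[, k] == 0L)
    cnp_in_cand <- length(cnp)  # C_np proteins are old-release non-positives
    for (cfg in configurations) {
      feats <- resolve_configuration(cfg, freq_f14, freq_f17)
      sub <- mat[, feats, drop = FALSE]
      for (fam in models) {
        spec <- classifier_spec(fam, seed = derive_seed(seed, ti))
        rk <- rank_candidates(sub, holdout$older, k, spec)
        if (is.null(rk)) { skipped <- c(skipped, k); next }
        sels <- select_at_budget(rk, n_total, budgets_pct)
        for (x in names(sels)) {
          b <- length(sels[[x]])
          rows[[length(rows) + 1]] <- data.frame(
            term = k, configuration = cfg, model = fam,
            budget_pct = as.numeric(x), budget_size = b,
            fn = count_false_negatives(sels[[x]], cnp),
            baseline_fn = b * cnp_in_cand / cand_n,
            candidates = cand_n)
        }
      }
    }
  }
  per_term <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(fn, baseline_fn) ~ configuration + model +
                            budget_pct, data = per_term, FUN = mean)
  names(agg)[names(agg) == "fn"] <- "mean_fn"
  nterms <- stats::aggregate(term ~ configuration + model + budget_pct,
                             data = per_term,
                             FUN = function(t) length(unique(t)))
  agg$n_terms <- nterms$term[match(
    paste(agg$configuration, agg$model, agg$budget_pct),
    paste(nterms$configuration, nterms$model, nterms$budget_pct))]
  agg <- agg[order(agg$configuration, agg$model, agg$budget_pct), ]
  rownames(agg) <- NULL
  structure(list(per_term = per_term, summary = agg,
                 skipped = unique(skipped)),
            class = "negsel_report")
}

#' @export
print.negsel_report <- function(x, ...) {
  cat("negsel_report over", length(unique(x$per_term$term)), "terms\n")
  print(utils::head(x$summary, 20))
  invisible(x)
}
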