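# End-to-end driver: generate a fixture, write it to disk, re-ingest it
# through the file-format loaders, and run feature extraction, relevance,
# function prediction and negative selection, writing plain-text outputs.

#' Run the full pipeline on a synthetic fixture
#'
#' Exercises every stage on files, the way a study on real data would run:
#' the fixture is written as TSVs, re-loaded via [load_string_edges()] /
#' [load_annotations()], and then feature extraction, the relevance
#' experiment, nested-CV function prediction and budgeted negative
#' selection are executed. All outputs are written under `out_dir` as TSVs
#' with deterministic formatting; with a fixed `seed` two runs produce
#' byte-identical files.
#'
#' @param fixture fixture name (see [make_fixture()]); sized for `tiny`.
#' @param seed seed forwarded to the generator and every stochastic stage.
#' @param out_dir output directory.
#' @param min_cnp `min_cnp` threshold for the relevance term filter (the
#'   tiny fixture documents 5; larger fixtures use 20).
#' @param budgets_pct negative-selection budget grid.
#' @return Invisibly, a list with the in-memory results (`stats`, `freq`,
#'   `prediction`, `negsel`) and the written file paths.
#' @export
run_pipeline <- function(fixture = "tiny", seed = 11,
                         out_dir = tempfile("netfeat_run_"),
                         min_cnp = if (fixture == "tiny") 5 else 20,
                         budgets_pct = c(1, 5, 10, 15, 20, 25, 30)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- make_fixture(fixture, seed = seed)
  data_dir <- file.path(out_dir, "data")
  write_dataset(ds, data_dir)

  raw <- load_string_edges(file.path(data_dir, "edges.tsv"), threshold = 700)
  net <- symmetric_normalize(raw)
  old <- load_annotations(file.path(data_dir, "annotations_old.tsv"),
                          net$node_labels, release = "older")
  new <- load_annotations(file.path(data_dir, "annotations_new.tsv"),
                          net$node_labels, release = "newer")
  holdout <- build_holdout(old, new)
  cache <- network_feature_cache(net)
  stats <- network_stats(net, cache$comps, cache$paths)

  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    path
  }

  terms_rel <- filter_terms(holdout, "min_cnp", min_cnp = min_cnp)
  feat_paths <- character(0)
  for (k in terms_rel) {
    mat <- assemble_term_matrix(net, holdout, k, cache = cache)
    df <- data.frame(protein = rownames(mat),
                     signif(as.data.frame(unclass(mat)), 10))
    feat_paths <- c(feat_paths, write_tsv(df, paste0("features_", k, ".tsv")))
  }

  freq <- triple_loop_relevance(net, holdout, terms_rel,
                                pool = paste0("f", 1:14),
                                seed = derive_seed(seed, 31), cache = cache)
  freq_df <- as.data.frame(freq)
  freq_df$above_mean <- freq_df$proportion > attr(freq, "mean_proportion")
  freq_path <- write_tsv(freq_df, "relevance_frequencies.tsv")

  pred_rows <- list()
  for (k in terms_rel) {
    mat <- assemble_term_matrix(net, holdout, k, cache = cache)
    labels <- as.integer(holdout$older$Y[, k])
    for (fam in c("linear_svm", "random_forest")) {
      spec <- classifier_spec(fam, seed = derive_seed(seed, 41))
      w <- if (fam == "linear_svm") class_weight_for_term(holdout$older, k)
           else NULL
      met <- nested_cv_evaluate(mat, labels, spec, weights = w,
                                representation = "f1-f17")
      if (is.null(met)) next
      pred_rows[[length(pred_rows) + 1]] <- data.frame(
        term = k, model = fam, representation = "f1-f17",
        f1 = signif(met$mean[["f1"]], 10),
        precision = signif(met$mean[["precision"]], 10),
        recall = signif(met$mean[["recall"]], 10))
    }
  }
  pred_df <- do.call(rbind, pred_rows)
  pred_path <- write_tsv(pred_df, "prediction_metrics.tsv")

  report <- evaluate_configurations(
    net, holdout, terms_rel,
    configurations = c("f15-f17", "f1-f14", "f1-f17"),
    budgets_pct = budgets_pct, seed = derive_seed(seed, 51), cache = cache)
  summ <- report$summary
  summ$baseline_fn <- signif(summ$baseline_fn, 10)
  summ$mean_fn <- signif(summ$mean_fn, 10)
  negsel_path <- write_tsv(summ, "negative_selection.tsv")

  stats_df <- data.frame(nodes = stats$nodes,
                         average_degree = signif(stats$average_degree, 10),
                         components = stats$components,
                         diameter = stats$diameter,
                         weighted_diameter = signif(stats$weighted_diameter, 10))
  stats_path <- write_tsv(stats_df, "network_stats.tsv")

  invisible(list(stats = stats, freq = freq, prediction = pred_df,
                 negsel = report,
                 paths = c(feat_paths, freq_path, pred_path, negsel_path,
                           stats_path)))
}
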