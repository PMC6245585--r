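# Loading of protein-to-GO-term annotation releases and construction of the
# temporal holdout (older release Y for training, newer release Ybar for
# validation, with the per-term C_np class of negatives-that-become-positive).

# Evidence codes treated as "experimentally validated" by default.
experimental_evidence_codes <- function() c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Load one release of a protein--term annotation table
#'
#' Reads a 3-column TSV (`protein`, `term`, `evidence_code`) and builds the
#' binary annotation matrix restricted to the proteins of the network.
#' When `experimental_only` is set (the default), rows whose evidence code
#' falls outside `evidence_codes` are discarded. Proteins present in the
#' file but absent from `node_labels` are dropped (count reported via
#' `message()`); duplicated rows are idempotent.
#'
#' @param path annotation TSV path.
#' @param node_labels protein identifiers of the network; the matrix rows
#'   are exactly these, in this order.
#' @param experimental_only keep only experimentally validated rows.
#' @param evidence_codes the experimental whitelist.
#' @param release tag stored alongside the matrix.
#' @return An `annotation_release`: list with binary matrix `Y`
#'   (protein x term), `terms`, `release`.
#' @export
load_annotations <- function(path, node_labels, experimental_only = TRUE,
                             evidence_codes = experimental_evidence_codes(),
                             release = basename(path)) {
  df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "",
                          colClasses = "character", col.names = c("protein", "term", "evidence"),
                          fill = FALSE, blank.lines.skip = TRUE)
  if (nrow(df) > 0 && identical(tolower(df$protein[1]), "protein"))
    df <- df[-1, , drop = FALSE]
  if (experimental_only)
    df <- df[df$evidence %in% evidence_codes, , drop = FALSE]
  known <- df$protein %in% node_labels
  if (nrow(df) > 0 && !any(known))
    stop("no overlap between annotation proteins and network nodes")
  if (any(!known))
    message(sum(!known), " annotation row(s) for proteins absent from the network dropped")
  df <- df[known, , drop = FALSE]
  terms <- sort(unique(df$term))
  Y <- matrix(0L, length(node_labels), length(terms),
              dimnames = list(node_labels, terms))
  if (nrow(df) > 0)
    Y[cbind(match(df$protein, node_labels), match(df$term, terms))] <- 1L
  new_annotation_release(Y, release)
}

new_annotation_release <- function(Y, release) {
  structure(list(Y = Y, terms = colnames(Y), release = release),
            class = "annotation_release")
}

#' Build a temporal holdout from two annotation releases
#'
#' Pairs an older release `Y` with a newer release `Ybar` over the shared
#' term set and computes, per term, the set
#' `C_np(k) = { i : Y_ik = 0 & Ybar_ik = 1 }` of proteins that received the
#' annotation during the holdout period. Annotations present in the older
#' release but revoked in the newer one are counted and reported; the
#' protein remains an old-release positive (the conservative choice for a
#' study of negatives), so `C_np` is unaffected.
#'
#' @param older,newer `annotation_release` objects over the same proteins.
#' @return A `temporal_holdout`: list with `older`, `newer` (both restricted
#'   to the shared terms), `terms`, `cnp` (named list of protein labels per
#'   term) and `revocations` (named integer vector).
#' @export
build_holdout <- function(older, newer) {
  stopifnot(inherits(older, "annotation_release"),
            inherits(newer, "annotation_release"))
  if (!identical(rownames(older$Y), rownames(newer$Y)))
    stop("older and newer releases must cover the same protein universe")
  shared <- intersect(older$terms, newer$terms)
  dropped <- length(older$terms) + length(newer$terms) - 2 * length(shared)
  if (dropped > 0)
    message(dropped, " term(s) present in only one release dropped")
  Y <- older$Y[, shared, drop = FALSE]
  Yb <- newer$Y[, shared, drop = FALSE]
  cnp <- lapply(shared, function(k) rownames(Y)[Y[, k] == 0L & Yb[, k] == 1L])
  names(cnp) <- shared
  rev <- vapply(shared, function(k) sum(Y[, k] == 1L & Yb[, k] == 0L), integer(1))
  if (sum(rev) > 0)
    message(sum(rev), " revoked annotation(s) kept as old-release positives")
  structure(list(older = new_annotation_release(Y, older$release),
                 newer = new_annotation_release(Yb, newer$release),
                 terms = shared, cnp = cnp, revocations = rev),
            class = "temporal_holdout")
}

#' @export
print.temporal_holdout <- function(x, ...) {
  cat("temporal_holdout:", nrow(x$older$Y), "proteins,", length(x$terms),
      "terms; median |C_np| =", stats::median(lengths(x$cnp)), "\n")
  invisible(x)
}

#' Filter holdout terms
#'
#' Two selection rules: `min_cnp` keeps terms with at least `min_cnp`
#' proteins in `C_np` (the relevance-experiment criterion); `annotation_range`
#' keeps terms whose newer-release annotation count lies in `range`
#' (inclusive; the function-prediction criterion, by default 20--200 so that
#' a classifier has enough positives while overly generic terms are excluded).
#'
#' @param holdout a `temporal_holdout`.
#' @param rule `"min_cnp"` or `"annotation_range"`.
#' @param min_cnp minimum `|C_np|` (inclusive).
#' @param range inclusive `[lower, upper]` bounds on newer-release counts.
#' @return Character vector of surviving term identifiers.
#' @export
filter_terms <- function(holdout, rule = c("min_cnp", "annotation_range"),
                         min_cnp = 20, range = c(20, 200)) {
  rule <- match.arg(rule)
  keep <- switch(rule,
    min_cnp = lengths(holdout$cnp) >= min_cnp,
    annotation_range = {
      cnt <- colSums(holdout$newer$Y)
      cnt >= range[1] & cnt <= range[2]
    })
  out <- holdout$terms[keep]
  if (length(out) == 0) warning("no terms pass the '", rule, "' filter")
  out
}
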