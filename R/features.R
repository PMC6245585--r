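# The seventeen per-protein features: local neighborhood statistics (f1-f4),
# annotation count (f5), geometric centralities (f6-f9), their term-aware
# counterparts (f10-f14), and the 1/2/3-step random-walk probabilities
# (f15-f17), plus the per-column sum-to-one normalization.

#' Local neighborhood features f1--f4
#'
#' For each node i with neighborhood `N_i`:
#' f1 (neighborhood mean) is the mean of `W_ij` over `N_i`; f2 (neighborhood
#' variance) is the sample variance of the same weights (divisor `|N_i|-1`,
#' defined as 0 for a single neighbor); f3 (weighted degree) is their sum;
#' f4 (weighted clustering coefficient) is the ratio between the total
#' weight of closed triples centered at i, each triple weighted by the mean
#' of its three edge weights, and the total weight of all triples centered
#' at i, each weighted by the mean of its two spoke weights. f4 reduces to
#' the standard local clustering coefficient when all weights are equal, and
#' is 0 for nodes with fewer than two neighbors.
#'
#' @param net a `weighted_network`.
#' @return Numeric matrix with columns `f1..f4`, one row per protein.
#' @export
local_features <- function(net) {
  W <- net$W
  n <- nrow(W)
  adj <- W > 0
  deg <- rowSums(adj)
  f3 <- rowSums(W)
  f1 <- f3 / deg
  dev2 <- (W - f1)^2 * adj
  f2 <- ifelse(deg > 1, rowSums(dev2) / (deg - 1), 0)
  f4 <- numeric(n)
  for (i in which(deg >= 2)) {
    nb <- which(adj[i, ])
    wi <- W[i, nb]
    A <- W[nb, nb, drop = FALSE]
    S <- outer(wi, wi, "+")        # w_ij + w_ij' for ordered pairs
    denom <- (sum(S) - sum(diag(S))) / 2
    closed <- A > 0                # j' in N_j; diagonal is 0 (no self-loops)
    num <- sum(((S + A) / 3)[closed])
    f4[i] <- if (denom > 0) num / denom else 0
  }
  out <- cbind(f1 = f1, f2 = f2, f3 = f3, f4 = f4)
  rownames(out) <- net$node_labels
  out
}

#' Annotation-count feature f5
#'
#' Number of terms the protein is annotated with in the older release,
#' excluding the term under study (so the feature carries cross-term
#' multifunctionality signal without leaking the current label).
#'
#' @param older an `annotation_release`.
#' @param k term identifier (must be a column of the release).
#' @return Numeric vector, one value per protein.
#' @export
annotation_count <- function(older, k) {
  if (!k %in% colnames(older$Y)) stop("unknown term '", k, "'")
  as.numeric(rowSums(older$Y) - older$Y[, k])
}

#' Geometric centralities f6--f9
#'
#' Within each connected component `C_i`: f6 (closeness) is the reciprocal
#' of the sum of shortest-path distances to the other members; f7 (Lin's
#' index) multiplies closeness by `|C_i|^2`, compensating the bias of
#' closeness on disconnected networks; f8 (harmonic centrality) is the sum
#' of reciprocal distances; f9 (betweenness) is the sum over unordered pairs
#' `s != t` (both different from i) of the fraction of minimum-cost s--t
#' paths passing through i.
#'
#' @param net a `weighted_network`.
#' @param comps a `component_index`.
#' @param paths a `path_cache`.
#' @return Numeric matrix with columns `f6..f9`.
#' @export
geometric_centralities <- function(net, comps, paths) {
  d <- paths$dist
  n <- nrow(d)
  fin <- is.finite(d)
  sumd <- rowSums(ifelse(fin, d, 0))
  csize <- comps$sizes[comps$component_id]
  f6 <- 1 / sumd
  f7 <- csize^2 / sumd
  inv <- ifelse(fin & d > 0, 1 / d, 0)
  f8 <- rowSums(inv)
  f9 <- betweenness_nodes(paths)
  out <- cbind(f6 = f6, f7 = f7, f8 = f8, f9 = f9)
  rownames(out) <- net$node_labels
  out
}

# Betweenness via the pair-counting identity: sigma_st(i) = sigma_si *
# sigma_it when d_si + d_it = d_st. Summed over ordered pairs, halved.
betweenness_nodes <- function(paths) {
  d <- paths$dist; sg <- paths$sigma
  n <- nrow(d)
  fin <- is.finite(d)
  bt <- numeric(n)
  for (i in seq_len(n)) {
    tot <- outer(d[, i], d[i, ], "+")
    on_path <- fin & abs(tot - d) <= paths$tie_tol
    contrib <- outer(sg[, i], sg[i, ]) * on_path
    contrib[i, ] <- 0; contrib[, i] <- 0; diag(contrib) <- 0
    ok <- contrib > 0
    bt[i] <- sum(contrib[ok] / sg[ok]) / 2
  }
  bt
}

#' Term context for the term-aware features
#'
#' Collects, for a GO term `k`, the old-release positive set and each
#' node's positive neighborhood `N_i^+` (neighbors annotated for k in the
#' older release). All positives are taken from the older release only: the
#' newer release is reserved for validation.
#'
#' @param net a `weighted_network`.
#' @param older an `annotation_release` aligned to `net`.
#' @param k term identifier.
#' @return A `term_context` list with `term`, `positive` (0/1 vector) and
#'   `pos_idx`.
#' @export
term_context <- function(net, older, k) {
  if (!k %in% colnames(older$Y)) stop("unknown term '", k, "'")
  y <- as.numeric(older$Y[rownames(older$Y), k])
  names(y) <- rownames(older$Y)
  structure(list(term = k, positive = y, pos_idx = which(y == 1)),
            class = "term_context")
}

#' Term-aware features f10--f14
#'
#' f10 (positive neighborhood) sums the weights toward positively annotated
#' neighbors, the guilt-by-association score; f11 is its mean (0 when the
#' positive neighborhood is empty). f12--f14 are the positive counterparts of
#' closeness, Lin's index and harmonic centrality, computed over the
#' positives `C_i^+` of the node's component: distances are summed over
#' positives other than i itself (when i is positive the self term is
#' excluded, while `|C_i^+|` still counts it), and the empty-set convention
#' gives 0 when no reachable positive exists.
#'
#' @param net a `weighted_network`.
#' @param paths a `path_cache`.
#' @param ctx a `term_context` built from the older release.
#' @return Numeric matrix with columns `f10..f14`.
#' @export
term_aware_features <- function(net, paths, ctx) {
  W <- net$W
  n <- nrow(W)
  y <- ctx$positive
  adj <- W > 0
  f10 <- as.numeric(W %*% y)
  nplus <- as.numeric(adj %*% y)
  f11 <- ifelse(nplus > 0, f10 / nplus, 0)
  P <- ctx$pos_idx
  if (length(P) == 0) {
    z <- numeric(n)
    out <- cbind(f10 = f10, f11 = f11, f12 = z, f13 = z, f14 = z)
    rownames(out) <- net$node_labels
    return(out)
  }
  dP <- paths$dist[, P, drop = FALSE]
  finP <- is.finite(dP)
  sumd <- rowSums(ifelse(finP, dP, 0))      # self term adds d_ii = 0
  cnt <- rowSums(finP)                      # |C_i^+|, self included if positive
  inv <- ifelse(finP & dP > 0, 1 / dP, 0)   # excludes the self term
  f12 <- ifelse(sumd > 0, 1 / sumd, 0)
  f13 <- ifelse(sumd > 0, cnt^2 / sumd, 0)
  f14 <- rowSums(inv)
  out <- cbind(f10 = f10, f11 = f11, f12 = f12, f13 = f13, f14 = f14)
  rownames(out) <- net$node_labels
  out
}

#' Random-walk features f15--f17 (3Prop)
#'
#' Probabilities that a random walk of length 1, 2 and 3 started at a
#' uniformly chosen old-release positive ends at each node. The transition
#' matrix is the row normalization of `W` (each row divided by its sum, so
#' rows sum to one) and the start distribution is uniform over the
#' positives. Powers are applied as repeated operator--vector products;
#' the dense cube of the transition matrix is never materialized.
#'
#' @param net a `weighted_network`.
#' @param ctx a `term_context` with at least one positive.
#' @return Numeric matrix with columns `f15..f17`.
#' @export
three_prop <- function(net, ctx) {
  if (length(ctx$pos_idx) == 0)
    stop("3Prop undefined for unannotated term '", ctx$term, "'")
  W <- net$W
  rs <- rowSums(W)
  if (any(rs == 0)) stop("network contains isolated nodes")
  P <- W / rs
  y <- ctx$positive / sum(ctx$positive)
  f15 <- as.numeric(P %*% y)
  f16 <- as.numeric(P %*% f15)
  f17 <- as.numeric(P %*% f16)
  out <- cbind(f15 = f15, f16 = f16, f17 = f17)
  rownames(out) <- net$node_labels
  out
}

#' Sum-to-one normalization of a feature matrix
#'
#' Divides every column by its sum so that each feature sums to one across
#' proteins, which puts the heterogeneous feature ranges on a comparable
#' scale. All-zero columns are left untouched (with a warning); negative
#' entries are a data error since every feature is non-negative by
#' construction.
#'
#' @param mat numeric matrix (proteins x features).
#' @return The column-normalized matrix.
#' @export
normalize_features <- function(mat) {
  if (any(mat < 0)) stop("negative feature values: features must be non-negative")
  cs <- colSums(mat)
  zero <- cs == 0
  if (any(zero))
    warning("all-zero feature column(s) left unnormalized: ",
            paste(colnames(mat)[zero], collapse = ", "))
  cs[zero] <- 1
  sweep(mat, 2, cs, "/")
}

#' Precompute the term-unaware layer of the feature pipeline
#'
#' Components, the shortest-path cache and the raw term-unaware columns
#' (f1--f4, f6--f9) depend only on the network, so they are computed once
#' and shared across terms.
#'
#' @param net a `weighted_network`.
#' @param cost_mode shortest-path cost transform (see [shortest_paths()]).
#' @return A `feature_cache` list with `comps`, `paths` and `base`.
#' @export
network_feature_cache <- function(net, cost_mode = "weight_as_cost") {
  comps <- connected_components(net)
  paths <- shortest_paths(net, comps, cost_mode = cost_mode)
  base <- cbind(local_features(net),
                geometric_centralities(net, comps, paths))
  rownames(base) <- net$node_labels
  structure(list(comps = comps, paths = paths, base = base,
                 cost_mode = cost_mode), class = "feature_cache")
}

#' Assemble the feature matrix for one term
#'
#' Computes the requested subset of `f1..f17` for term `k`, reusing the
#' shared term-unaware cache, and applies the sum-to-one normalization
#' (including to f15--f17, for uniformity). Columns are always in canonical
#' f-index order.
#'
#' @param net a `weighted_network`.
#' @param holdout a `temporal_holdout` aligned to `net`.
#' @param k term identifier.
#' @param features subset of `paste0("f", 1:17)`.
#' @param cache optional [network_feature_cache()] result.
#' @param normalize apply [normalize_features()].
#' @return A `term_feature_matrix`: numeric matrix (protein x feature) with
#'   attributes `term` and `normalized`.
#' @export
assemble_term_matrix <- function(net, holdout, k,
                                 features = feature_names_all(),
                                 cache = NULL, normalize = TRUE) {
  stopifnot(all(features %in% feature_names_all()))
  features <- features[order(feature_rank(features))]
  if (is.null(cache)) cache <- network_feature_cache(net)
  older <- holdout$older
  cols <- list()
  base_wanted <- intersect(features, colnames(cache$base))
  if (length(base_wanted))
    cols <- c(cols, lapply(base_wanted, function(f) cache$base[, f]))
  names(cols) <- base_wanted
  if ("f5" %in% features) cols$f5 <- annotation_count(older, k)
  need_ctx <- any(features %in% paste0("f", 10:17))
  if (need_ctx) ctx <- term_context(net, older, k)
  if (any(features %in% paste0("f", 10:14))) {
    ta <- term_aware_features(net, cache$paths, ctx)
    for (f in intersect(features, colnames(ta))) cols[[f]] <- ta[, f]
  }
  if (any(features %in% paste0("f", 15:17))) {
    tp <- three_prop(net, ctx)
    for (f in intersect(features, colnames(tp))) cols[[f]] <- tp[, f]
  }
  mat <- do.call(cbind, cols[features])
  colnames(mat) <- features
  rownames(mat) <- net$node_labels
  if (normalize) mat <- normalize_features(mat)
  structure(mat, term = k, normalized = normalize,
            class = c("term_feature_matrix", class(mat)))
}
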