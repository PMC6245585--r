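# Network ingestion, normalization, components, shortest paths and summary
# statistics over STRING-style weighted protein networks.

#' Load a STRING-dialect weighted edge list
#'
#' Reads a whitespace/tab-separated edge list with two protein identifier
#' columns and one integer combined-score column (scores in 1--999, the
#' STRING convention), drops edges below `threshold`, and returns the raw
#' symmetric weight matrix with kept scores mapped to `score / 1000`.
#' Proteins appearing only in dropped edges (isolated after thresholding)
#' are removed. A header line is auto-detected; files ending in `.gz` are
#' read transparently.
#'
#' Identical duplicated rows are collapsed silently; two orientations of the
#' same pair with conflicting scores raise an error (data corruption should
#' surface, not be averaged away). Self-loops are dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @param threshold minimum combined score kept (default 700, the cutoff
#'   recommended by STRING curators for high-confidence edges).
#' @return A `raw_network`: list with `node_labels` and the symmetric
#'   non-negative matrix `raw_weights` (zero diagonal).
#' @export
load_string_edges <- function(path, threshold = 700) {
  stopifnot(threshold >= 1, threshold <= 999)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(new_raw_network(character(0),
                           matrix(0, 0, 0, dimnames = list(NULL, NULL))))
  }
  start <- nonblank[1]
  first <- strsplit(trimws(lines[start]), "[ \t]+")[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  rows <- nonblank[nonblank > ifelse(has_header, start, start - 1L)]

  from <- character(length(rows)); to <- character(length(rows))
  score <- numeric(length(rows))
  for (r in seq_along(rows)) {
    ln <- rows[r]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 3)
      stop("malformed edge row at line ", ln, ": expected 3 columns, got ",
           length(f))
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s))
      stop("malformed edge row at line ", ln, ": score '", f[3],
           "' is not numeric")
    from[r] <- f[1]; to[r] <- f[2]; score[r] <- s
  }

  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    from <- from[!self]; to <- to[!self]; score <- score[!self]
  }

  # Collapse duplicate orientations; conflicting scores for a pair are an error.
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(score, key, function(s) length(unique(s)))
    bad <- names(agg)[agg > 1]
    if (length(bad))
      stop("conflicting scores for pair(s): ",
           paste(gsub("\r", " - ", bad[seq_len(min(5, length(bad)))]),
                 collapse = ", "))
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }

  keep <- score >= threshold
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  labels <- sort(unique(c(a, b)))
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 0) {
    ia <- match(a, labels); ib <- match(b, labels)
    W[cbind(ia, ib)] <- score / 1000
    W[cbind(ib, ia)] <- score / 1000
  }
  new_raw_network(labels, W)
}

new_raw_network <- function(labels, W) {
  structure(list(node_labels = labels, raw_weights = W),
            class = "raw_network")
}

#' Symmetric degree normalization of a raw network
#'
#' Computes `W = D^{-1/2} %*% What %*% D^{-1/2}` where `D` is the diagonal
#' matrix of row sums of the raw weights, i.e. `W_ij = What_ij /
#' sqrt(d_i d_j)`. The result is symmetric with entries in `[0, 1]` and is
#' invariant to a global rescaling of the raw weights. Isolated nodes
#' (zero row sum) violate the precondition and raise an error.
#'
#' @param raw a `raw_network` from [load_string_edges()].
#' @return A `weighted_network`: list with `node_labels`, normalized matrix
#'   `W`, and `D` (the vector of raw row sums).
#' @export
symmetric_normalize <- function(raw) {
  stopifnot(inherits(raw, "raw_network"))
  What <- raw$raw_weights
  if (nrow(What) == 0)
    return(new_weighted_network(raw$node_labels, What, numeric(0)))
  if (any(What < 0)) stop("raw weights must be non-negative")
  if (max(abs(What - t(What))) > 0) stop("raw weight matrix must be symmetric")
  d <- rowSums(What)
  if (any(d == 0))
    stop("isolated node(s) present (zero row sum): ",
         paste(utils::head(raw$node_labels[d == 0], 5), collapse = ", "))
  s <- 1 / sqrt(d)
  W <- What * outer(s, s)
  diag(W) <- 0
  new_weighted_network(raw$node_labels, W, d)
}

new_weighted_network <- function(labels, W, D) {
  structure(list(node_labels = labels, W = W, D = D),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network:", length(x$node_labels), "proteins,",
      sum(x$W > 0) / 2, "edges\n")
  invisible(x)
}

#' Connected components of a weighted network
#'
#' Standard undirected connectivity over the nonzero entries of `W`.
#'
#' @param net a `weighted_network`.
#' @return A `component_index`: list with `component_id` (integer per node,
#'   numbered by first-seen node) and `sizes`.
#' @export
connected_components <- function(net) {
  W <- net$W
  n <- nrow(W)
  comp <- integer(n)
  cid <- 0L
  adj <- W > 0
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- which(matrixStats_any(adj, frontier) & comp == 0L)
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  structure(list(component_id = comp,
                 sizes = as.integer(table(factor(comp, levels = seq_len(cid))))),
            class = "component_index")
}

# Column-wise "any" over the rows in `rows` of a logical matrix; avoids
# building igraph objects for a three-line BFS.
matrixStats_any <- function(adj, rows) {
  if (length(rows) == 1) adj[rows, ] else colSums(adj[rows, , drop = FALSE]) > 0
}

#' All-pairs shortest paths with path counting
#'
#' Dijkstra from every source over the edges of `W`, recording the weighted
#' distance `d_st`, the number of distinct minimum-cost paths `sigma_st`
#' (ties on path cost resolved with tolerance `tie_tol`), and the unweighted
#' hop distance (used for the hop diameter). The edge cost is derived from
#' the similarity `W_ij` according to `cost_mode`:
#' `weight_as_cost` (the default; the literal reading of "using W as the
#' weight matrix"), `inverse_weight` (`1/W_ij`), `one_minus_weight`
#' (`1 - W_ij`), or `hop` (unit costs).
#'
#' @param net a `weighted_network`.
#' @param comps optional `component_index` (recomputed if missing).
#' @param cost_mode one of `"weight_as_cost"`, `"inverse_weight"`,
#'   `"one_minus_weight"`, `"hop"`.
#' @param tie_tol absolute tolerance for equal path costs.
#' @return A `path_cache`: list with matrices `dist`, `sigma`, `hops`
#'   (entries `Inf`/0 across components), plus `cost_mode` and `tie_tol`.
#' @export
shortest_paths <- function(net, comps = NULL, cost_mode = "weight_as_cost",
                           tie_tol = 1e-12) {
  modes <- c("weight_as_cost", "inverse_weight", "one_minus_weight", "hop")
  if (!cost_mode %in% modes)
    stop("unknown cost_mode '", cost_mode, "'; use one of: ",
         paste(modes, collapse = ", "))
  W <- net$W
  n <- nrow(W)
  cost <- matrix(Inf, n, n)
  edge <- W > 0
  cost[edge] <- switch(cost_mode,
                       weight_as_cost = W[edge],
                       inverse_weight = 1 / W[edge],
                       one_minus_weight = 1 - W[edge],
                       hop = 1)
  nbrs <- lapply(seq_len(n), function(i) which(edge[i, ]))
  wsp <- all_pairs_dijkstra(cost, nbrs, tie_tol)
  unit <- matrix(Inf, n, n); unit[edge] <- 1
  hsp <- all_pairs_dijkstra(unit, nbrs, tie_tol)
  structure(list(dist = wsp$dist, sigma = wsp$sigma, hops = hsp$dist,
                 cost_mode = cost_mode, tie_tol = tie_tol),
            class = "path_cache")
}

# Dense Dijkstra with minimum-cost path counting from every source.
all_pairs_dijkstra <- function(cost, nbrs, tie_tol) {
  n <- nrow(cost)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- numeric(n); done <- logical(n)
    d[s] <- 0; sg[s] <- 1
    pending <- d  # settled entries set to Inf so which.min skips them
    repeat {
      u <- which.min(pending)
      if (!is.finite(pending[u])) break
      pending[u] <- Inf
      done[u] <- TRUE
      nb <- nbrs[[u]]
      nb <- nb[!done[nb]]
      if (length(nb)) {
        nd <- d[u] + cost[u, nb]
        better <- nd < d[nb] - tie_tol
        equal <- !better & nd <= d[nb] + tie_tol
        if (any(better)) {
          i <- nb[better]
          d[i] <- nd[better]; pending[i] <- nd[better]; sg[i] <- sg[u]
        }
        if (any(equal)) {
          i <- nb[equal]
          sg[i] <- sg[i] + sg[u]
        }
      }
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  list(dist = dist, sigma = sigma)
}

# sigma_st(i): number of minimum-cost s-t paths through internal node i,
# recovered from the cache via sigma_st(i) = sigma_si * sigma_it when
# d_si + d_it = d_st (and 0 otherwise).
path_through_counts <- function(paths, i) {
  d <- paths$dist; sg <- paths$sigma
  tot <- outer(d[, i], d[i, ], "+")
  on_path <- is.finite(d) & abs(tot - d) <= paths$tie_tol
  cnt <- outer(sg[, i], sg[i, ]) * on_path
  cnt[i, ] <- 0; cnt[, i] <- 0; diag(cnt) <- 0
  cnt
}

#' Summary statistics of a weighted network
#'
#' Node count, average degree (mean number of neighbors), number and sizes of
#' connected components, hop diameter (number of edges on the longest
#' shortest path, ignoring edge weights) and weighted diameter (longest
#' weighted shortest-path distance).
#'
#' @param net a `weighted_network`.
#' @param comps a `component_index` for `net`.
#' @param paths a `path_cache` for `net`.
#' @return A `network_stats` list.
#' @export
network_stats <- function(net, comps, paths) {
  W <- net$W
  fin <- is.finite(paths$hops)
  finw <- is.finite(paths$dist)
  structure(list(
    nodes = nrow(W),
    average_degree = mean(rowSums(W > 0)),
    components = length(comps$sizes),
    component_sizes = sort(comps$sizes, decreasing = TRUE),
    diameter = if (any(fin)) max(paths$hops[fin]) else 0,
    weighted_diameter = if (any(finw)) max(paths$dist[finw]) else 0
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Nodes:", x$nodes,
      "\nAverage degree:", round(x$average_degree, 4),
      "\nComponents:", x$components,
      "\nComponent sizes:", paste(utils::head(x$component_sizes, 8),
                                  collapse = ", "),
      "\nDiameter (hops):", x$diameter,
      "\nWeighted diameter:", round(x$weighted_diameter, 4), "\n")
  invisible(x)
}
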