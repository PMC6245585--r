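# Builders for small hand-checked networks and random weighted graphs, plus
# independent oracles (exhaustive simple-path enumeration, Monte-Carlo
# random walks) used to validate the analytic implementations.

make_net <- function(W, labels = NULL) {
  n <- nrow(W)
  if (is.null(labels)) labels <- letters[seq_len(n)]
  dimnames(W) <- list(labels, labels)
  netfeat:::new_weighted_network(labels, W, rowSums(W))
}

# Path a-b-c with weights 0.4 and 0.6 (used by several worked examples).
path_abc <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.4
  W[2, 3] <- W[3, 2] <- 0.6
  make_net(W)
}

# Star with center a and three unit-weight leaves.
star4 <- function() {
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- W[2:4, 1] <- 1
  make_net(W)
}

triangle <- function(w = 1) {
  W <- matrix(w, 3, 3); diag(W) <- 0
  make_net(W)
}

# Random connected weighted graph: edge probability p, weights uniform in
# (0.1, 1). Redraws until connected.
random_connected_net <- function(n, p = 0.45) {
  repeat {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W), arr.ind = TRUE)
    e <- runif(nrow(ut)) < p
    w <- runif(sum(e), 0.1, 1)
    W[ut[e, , drop = FALSE]] <- w
    W <- W + t(W)
    if (all(rowSums(W) > 0) &&
        length(netfeat::connected_components(make_net(W))$sizes) == 1)
      return(make_net(W))
  }
}

# Exhaustive simple-path oracle: for every ordered pair (s, t) enumerate all
# simple paths, returning the minimum cost, the count of minimum-cost paths
# (cost ties grouped at `tol`), and the per-node internal through counts.
brute_paths <- function(net, cost_mode = "weight_as_cost", tol = 1e-9) {
  W <- net$W
  n <- nrow(W)
  cost <- matrix(Inf, n, n)
  edge <- W > 0
  cost[edge] <- switch(cost_mode,
                       weight_as_cost = W[edge],
                       inverse_weight = 1 / W[edge],
                       one_minus_weight = 1 - W[edge],
                       hop = 1)
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  through <- array(0, c(n, n, n))
  hops <- matrix(Inf, n, n); diag(hops) <- 0
  for (s in seq_len(n)) {
    paths <- list()  # per target: list of (cost, internal nodes, nedges)
    rec <- function(v, visited, acc, internal) {
      for (u in which(edge[v, ])) {
        if (visited[u]) next
        cu <- acc + cost[v, u]
        paths[[length(paths) + 1]] <<- list(t = u, cost = cu,
                                            internal = internal,
                                            nedges = sum(visited))
        vis2 <- visited; vis2[u] <- TRUE
        rec(u, vis2, cu, c(internal, u))
      }
    }
    vis <- logical(n); vis[s] <- TRUE
    rec(s, vis, 0, integer(0))
    tgt <- vapply(paths, function(p) p$t, integer(1))
    for (t in setdiff(unique(tgt), s)) {
      ps <- paths[tgt == t]
      costs <- vapply(ps, function(p) p$cost, numeric(1))
      dmin <- min(costs)
      onmin <- which(costs <= dmin + tol)
      dist[s, t] <- dmin
      sigma[s, t] <- length(onmin)
      hops[s, t] <- min(vapply(ps[onmin], function(p) p$nedges, numeric(1)))
      for (ix in onmin)
        for (v in ps[[ix]]$internal) through[s, t, v] <- through[s, t, v] + 1
    }
  }
  list(dist = dist, sigma = sigma, through = through, hops = hops)
}

# Centralities computed directly from the brute-force oracle.
brute_centralities <- function(net, bp) {
  n <- nrow(net$W)
  fin <- is.finite(bp$dist)
  sumd <- rowSums(ifelse(fin, bp$dist, 0))
  csize <- rowSums(fin)  # component members (incl. self: d_ii = 0 finite)
  f6 <- 1 / sumd
  f7 <- csize^2 / sumd
  f8 <- rowSums(ifelse(fin & bp$dist > 0, 1 / bp$dist, 0))
  f9 <- vapply(seq_len(n), function(i) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == i || t == i) next
      if (!is.finite(bp$dist[s, t]) || bp$sigma[s, t] == 0) next
      tot <- tot + bp$through[s, t, i] / bp$sigma[s, t]
    }
    tot
  }, numeric(1))
  cbind(f6 = f6, f7 = f7, f8 = f8, f9 = f9)
}

brute_positive_centralities <- function(net, bp, pos_idx) {
  n <- nrow(net$W)
  t(vapply(seq_len(n), function(i) {
    js <- setdiff(pos_idx[is.finite(bp$dist[i, pos_idx])], i)
    cnt <- sum(is.finite(bp$dist[i, pos_idx]))  # includes self if positive
    sumd <- sum(bp$dist[i, js])
    c(f12 = if (sumd > 0) 1 / sumd else 0,
      f13 = if (sumd > 0) cnt^2 / sumd else 0,
      f14 = sum(1 / bp$dist[i, js]))
  }, numeric(3)))
}

# Monte-Carlo estimate of the random-walk features: p_i^j is the
# probability that a length-j walk from node i lands on an (old-release)
# positive, divided by the number of positives — the formula-level meaning
# of P^j_{i.} y with y uniform over positives.
mc_three_prop <- function(net, pos_idx, nwalk = 1e5) {
  W <- net$W
  n <- nrow(W)
  P <- W / rowSums(W)
  est <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    cur <- rep.int(i, nwalk)
    for (step in 1:3) {
      nxt <- integer(nwalk)
      for (u in unique(cur)) {
        idx <- which(cur == u)
        nxt[idx] <- sample.int(n, length(idx), replace = TRUE, prob = P[u, ])
      }
      cur <- nxt
      est[i, step] <- mean(cur %in% pos_idx) / length(pos_idx)
    }
  }
  est
}

# Minimal holdout wrapper for feature tests: a single term with the given
# positive proteins in the older release.
toy_holdout <- function(net, pos_labels, new_labels = pos_labels,
                        term = "T1") {
  labs <- net$node_labels
  Y <- matrix(0L, length(labs), 1, dimnames = list(labs, term))
  Y[pos_labels, 1] <- 1L
  Yb <- Y
  Yb[new_labels, 1] <- 1L
  netfeat::build_holdout(netfeat:::new_annotation_release(Y, "old"),
                         netfeat:::new_annotation_release(Yb, "new"))
}
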