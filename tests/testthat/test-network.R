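# Network ingestion, normalization, components, shortest paths, statistics.

write_edges <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

test_that("edge loading applies the score threshold, scaling and pruning", {
  p <- write_edges(c("p1\tp2\t850", "p2\tp3\t699", "p1\tp3\t700"))
  raw <- load_string_edges(p, threshold = 700)
  expect_setequal(raw$node_labels, c("p1", "p2", "p3"))
  expect_equal(raw$raw_weights["p1", "p2"], 0.85)
  expect_equal(raw$raw_weights["p2", "p3"], 0)    # sub-threshold edge absent
  expect_equal(raw$raw_weights["p1", "p3"], 0.7)  # threshold is inclusive

  # A node appearing only in dropped edges disappears entirely.
  p2 <- write_edges(c("p1\tp2\t850", "p2\tp4\t500"))
  raw2 <- load_string_edges(p2, threshold = 700)
  expect_setequal(raw2$node_labels, c("p1", "p2"))
})

test_that("edge loading handles headers, gzip, duplicates and empty input", {
  p <- write_edges(c("protein1\tprotein2\tcombined_score", "a\tb\t800"), gz = TRUE)
  raw <- load_string_edges(p)
  expect_equal(raw$raw_weights["a", "b"], 0.8)

  empty <- load_string_edges(write_edges(character(0)))
  expect_length(empty$node_labels, 0)

  # Identical duplicated rows (either orientation) collapse silently.
  dup <- load_string_edges(write_edges(c("a\tb\t800", "b\ta\t800", "a\tb\t800")))
  expect_equal(dup$raw_weights["a", "b"], 0.8)

  expect_error(load_string_edges(write_edges(c("a\tb\t800", "b\ta\t900"))),
               "conflicting")
  expect_warning(load_string_edges(write_edges(c("a\ta\t900", "a\tb\t800"))),
                 "self-loop")
  expect_error(load_string_edges(write_edges(c("a\tb\t800", "c\td"))),
               "line 2")
  expect_error(load_string_edges(write_edges(c("a\tb\t800", "c\td\tnope"))),
               "not numeric")
})

test_that("symmetric normalization matches hand-computed values", {
  W2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  net <- symmetric_normalize(netfeat:::new_raw_network(c("a", "b"), W2))
  expect_equal(net$W["a", "b"], 1.0)

  # Triangle with equal raw weights: every normalized entry is 1/2, for any w.
  for (w in c(0.1, 0.7, 5)) {
    Wt <- matrix(w, 3, 3); diag(Wt) <- 0
    dimnames(Wt) <- list(letters[1:3], letters[1:3])
    nt <- symmetric_normalize(netfeat:::new_raw_network(letters[1:3], Wt))
    expect_equal(unname(nt$W[1, 2]), 0.5)
    expect_equal(unname(nt$W[1, 3]), 0.5)
  }

  # Unit row sums leave the matrix unchanged.
  W1 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(symmetric_normalize(netfeat:::new_raw_network(c("a", "b"), W1))$W, W1)

  Wi <- matrix(0, 3, 3); Wi[1, 2] <- Wi[2, 1] <- 1
  dimnames(Wi) <- list(letters[1:3], letters[1:3])
  expect_error(symmetric_normalize(netfeat:::new_raw_network(letters[1:3], Wi)),
               "isolated")
})

test_that("normalization is symmetric, bounded and scale-invariant", {
  set.seed(401)
  for (rep in 1:50) {
    n <- sample(3:20, 1)
    A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < 0.5)
    A <- A + t(A); diag(A) <- 0
    if (any(rowSums(A) == 0)) next
    dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    net <- symmetric_normalize(netfeat:::new_raw_network(rownames(A), A))
    expect_equal(max(abs(net$W - t(net$W))), 0)
    expect_true(all(net$W >= 0 & net$W <= 1))
    c_ <- runif(1, 0.01, 100)
    net2 <- symmetric_normalize(netfeat:::new_raw_network(rownames(A), c_ * A))
    expect_equal(net2$W, net$W, tolerance = 1e-12)
  }
})

test_that("connected components agree with simple cases and igraph", {
  net <- path_abc()
  expect_equal(connected_components(net)$sizes, 3L)

  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5; W[3, 4] <- W[4, 3] <- 0.5
  expect_equal(sort(connected_components(make_net(W))$sizes), c(2L, 2L))

  K5 <- matrix(0.3, 5, 5); diag(K5) <- 0
  expect_equal(connected_components(make_net(K5))$sizes, 5L)

  skip_if_not_installed("igraph")
  set.seed(402)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    A <- matrix(runif(n * n) < 0.2, n, n) * 1
    A <- pmax(A, t(A)) * 0.5; diag(A) <- 0
    keep <- rowSums(A) > 0
    if (sum(keep) < 2) next
    A <- A[keep, keep, drop = FALSE]
    net <- make_net(A, labels = sprintf("n%02d", seq_len(nrow(A))))
    g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
    expect_equal(length(connected_components(net)$sizes),
                 igraph::components(g)$no)
  }
})

test_that("shortest paths: distances, counts, cost modes", {
  net <- path_abc()
  paths <- shortest_paths(net)
  expect_equal(paths$dist[1, 3], 1.0)
  expect_equal(paths$sigma[1, 3], 1)
  expect_equal(diag(paths$dist), rep(0, 3))

  # Square with equal weights: two shortest paths between opposite corners,
  # one through each intermediate corner.
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  sq <- make_net(W)
  ps <- shortest_paths(sq)
  expect_equal(ps$sigma[1, 3], 2)
  th <- netfeat:::path_through_counts(ps, 2)
  expect_equal(th[1, 3], 1)

  inv <- shortest_paths(net, cost_mode = "inverse_weight")
  expect_equal(inv$dist[1, 3], 1 / 0.4 + 1 / 0.6)
  hop <- shortest_paths(net, cost_mode = "hop")
  expect_equal(hop$dist[1, 3], 2)
  expect_error(shortest_paths(net, cost_mode = "bogus"), "cost_mode")
})

test_that("weighted distances agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(403)
  for (rep in 1:20) {
    net <- random_connected_net(sample(4:9, 1))
    ps <- shortest_paths(net)
    g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                             weighted = TRUE)
    d <- igraph::distances(g, weights = igraph::E(g)$weight)
    dimnames(ps$dist) <- dimnames(d)
    expect_equal(ps$dist, d, tolerance = 1e-9)
  }
})

test_that("network statistics match hand-computed examples", {
  st <- {
    net <- star4()
    comps <- connected_components(net)
    network_stats(net, comps, shortest_paths(net, comps))
  }
  expect_equal(st$average_degree, 1.5)
  expect_equal(st$diameter, 2)

  tr <- {
    net <- triangle(0.5)
    comps <- connected_components(net)
    network_stats(net, comps, shortest_paths(net, comps))
  }
  expect_equal(tr$diameter, 1)
  expect_equal(tr$average_degree, 2)
  expect_equal(tr$components, 1)

  W <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  ed <- make_net(W)
  comps <- connected_components(ed)
  se <- network_stats(ed, comps, shortest_paths(ed, comps))
  expect_equal(se$weighted_diameter, 0.3)
})

test_that("hop and weighted diameters match brute force on random graphs", {
  set.seed(404)
  for (rep in 1:10) {
    net <- random_connected_net(sample(4:8, 1))
    comps <- connected_components(net)
    ps <- shortest_paths(net, comps)
    st <- network_stats(net, comps, ps)
    bp <- brute_paths(net)
    bph <- brute_paths(net, cost_mode = "hop")
    expect_equal(st$weighted_diameter, max(bp$dist[is.finite(bp$dist)]),
                 tolerance = 1e-9)
    expect_equal(st$diameter, max(bph$dist[is.finite(bph$dist)]))
  }
})
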