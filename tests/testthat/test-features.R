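# The seventeen features and their normalization.

test_that("local features match the path worked example and conventions", {
  lf <- local_features(path_abc())
  expect_equal(unname(lf["b", ]), c(0.5, 0.02, 1.0, 0))
  # Leaves: single neighbor -> variance and clustering are 0 by convention.
  expect_equal(unname(lf["a", c("f2", "f4")]), c(0, 0))

  # Fully closed neighborhoods give f4 = 1 regardless of the weight.
  expect_equal(unname(local_features(triangle(0.3))[, "f4"]), rep(1, 3))
})

test_that("annotation count excludes the current term", {
  labs <- c("p1", "p2")
  Y <- matrix(c(1, 0, 0, 0, 1, 0, 1, 0), 2, 4,
              dimnames = list(labs, sprintf("T%d", 1:4)))
  rel <- netfeat:::new_annotation_release(Y, "r")
  expect_equal(annotation_count(rel, "T1"), c(2, 0))
  expect_equal(annotation_count(rel, "T2"), c(3, 0))
  expect_error(annotation_count(rel, "nope"), "unknown term")
})

test_that("geometric centralities match the star and path examples", {
  net <- star4()
  comps <- connected_components(net)
  gc <- geometric_centralities(net, comps, shortest_paths(net, comps))
  expect_equal(unname(gc[1, ]), c(1 / 3, 16 / 3, 3, 3))
  expect_equal(unname(gc[2, "f9"]), 0)  # leaves lie on no internal path

  # Path with unit costs: harmonic centrality of an endpoint is 1 + 1/2.
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  netp <- make_net(W)
  cp <- connected_components(netp)
  gp <- geometric_centralities(netp, cp, shortest_paths(netp, cp))
  expect_equal(unname(gp[1, "f8"]), 1.5)
})

test_that("term-aware features match worked examples and conventions", {
  net <- path_abc()
  paths <- shortest_paths(net)
  h <- toy_holdout(net, "a")
  ctx <- term_context(net, h$older, "T1")
  ta <- term_aware_features(net, paths, ctx)
  expect_equal(unname(ta["b", c("f10", "f11")]), c(0.4, 0.4))
  expect_equal(unname(ta["a", "f10"]), 0)

  # Star, unit costs, positives = two leaves.
  nets <- star4()
  pss <- shortest_paths(nets)
  hs <- toy_holdout(nets, c("b", "c"))
  tas <- term_aware_features(nets, pss, term_context(nets, hs$older, "T1"))
  expect_equal(unname(tas["a", "f13"]), 2)
  expect_equal(unname(tas["a", "f14"]), 2)
  expect_equal(unname(tas["d", "f14"]), 1)

  # No positives anywhere: positive centralities are identically zero.
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5; W[3, 4] <- W[4, 3] <- 0.5
  net2 <- make_net(W)
  h2 <- toy_holdout(net2, "a")
  ta2 <- term_aware_features(net2, shortest_paths(net2),
                             term_context(net2, h2$older, "T1"))
  expect_equal(unname(ta2[c("c", "d"), c("f12", "f13", "f14")]),
               matrix(0, 2, 3))
})

test_that("random-walk features match hand matrix powers", {
  net <- path_abc()
  h <- toy_holdout(net, "a")
  tp <- three_prop(net, term_context(net, h$older, "T1"))
  expect_equal(unname(tp[, "f15"]), c(0, 0.4, 0))
  expect_equal(unname(tp[, "f16"]), c(0.4, 0, 0.4))
  expect_equal(unname(tp[, "f17"]), c(0, 0.4, 0))

  # Single edge, both endpoints positive: one step stays uniform.
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  net2 <- make_net(W)
  h2 <- toy_holdout(net2, c("a", "b"))
  tp2 <- three_prop(net2, term_context(net2, h2$older, "T1"))
  expect_equal(unname(tp2[, "f15"]), c(0.5, 0.5))

  # All nodes of a regular graph positive: uniform at every length.
  netr <- triangle(0.7)
  hr <- toy_holdout(netr, c("a", "b", "c"))
  tpr <- three_prop(netr, term_context(netr, hr$older, "T1"))
  expect_equal(unname(tpr), matrix(1 / 3, 3, 3), tolerance = 1e-12)

  h0 <- toy_holdout(net, "a")
  ctx0 <- term_context(net, h0$older, "T1")
  ctx0$positive[] <- 0; ctx0$pos_idx <- integer(0)
  expect_error(three_prop(net, ctx0), "3Prop undefined")
})

test_that("sum-to-one normalization behaves on worked and degenerate columns", {
  m <- cbind(a = c(0.4, 1.0, 0.6), b = c(0.2, 0.5, 0.3))
  norm <- normalize_features(m)
  expect_equal(unname(norm[, "a"]), c(0.2, 0.5, 0.3))
  expect_equal(normalize_features(norm), norm)  # idempotent
  z <- cbind(a = c(1, 1), b = c(0, 0))
  expect_warning(nz <- normalize_features(z), "all-zero")
  expect_equal(unname(nz[, "b"]), c(0, 0))
  expect_error(normalize_features(cbind(a = c(-1, 2))), "negative")
})

test_that("term matrix assembly orders, subsets and caches consistently", {
  net <- path_abc()
  h <- toy_holdout(net, "a", new_labels = c("a", "c"))
  cache <- network_feature_cache(net)

  # f5 is all-zero for a single-term release, so normalization warns.
  m14 <- suppressWarnings(
    assemble_term_matrix(net, h, "T1", paste0("f", 1:14), cache = cache))
  expect_equal(colnames(m14), paste0("f", 1:14))
  m3 <- assemble_term_matrix(net, h, "T1", paste0("f", 15:17), cache = cache)
  expect_equal(ncol(m3), 3)

  # Nonzero normalized columns sum to one.
  cs <- colSums(m14)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-9))

  # Term-unaware raw columns are shared across terms.
  h2 <- toy_holdout(net, "b")
  h12 <- build_holdout(
    netfeat:::new_annotation_release(cbind(h$older$Y, T2 = h2$older$Y[, 1]), "o"),
    netfeat:::new_annotation_release(cbind(h$newer$Y, T2 = h2$newer$Y[, 1]), "n"))
  a1 <- assemble_term_matrix(net, h12, "T1", cache = cache, normalize = FALSE)
  a2 <- assemble_term_matrix(net, h12, "T2", cache = cache, normalize = FALSE)
  shared <- paste0("f", c(1:4, 6:9))
  expect_equal(a1[, shared], a2[, shared])
  expect_false(isTRUE(all.equal(a1[, "f10"], a2[, "f10"])))
})

test_that("equal-weight clustering equals the unweighted coefficient", {
  skip_if_not_installed("igraph")
  set.seed(406)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    A <- matrix(runif(n * n) < 0.4, n, n) * 1
    A <- pmax(A, t(A)); diag(A) <- 0
    if (any(rowSums(A) == 0)) next
    w <- runif(1, 0.1, 1)
    net <- make_net(A * w, labels = sprintf("n%02d", 1:n))
    f4 <- local_features(net)[, "f4"]
    g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    cc[is.nan(cc)] <- 0
    expect_equal(unname(f4), cc, tolerance = 1e-12)
  }
})
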