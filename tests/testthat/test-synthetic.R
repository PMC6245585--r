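# Synthetic generator: reproducibility, modular structure, holdout
# correctness, and calibration of the guilt-by-association conversion model.

test_that("generation is reproducible bit-for-bit from (config, seed)", {
  cfg <- synthetic_config(n = 100, communities = 2, within_p = 0.3,
                          between_p = 0.02, m_terms = 4,
                          pos_range = c(6, 10), target_cnp = 12,
                          min_cnp_enforce = 5, seed = 77)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_identical(g1$scores, g2$scores)
  h1 <- generate_two_release_annotations(g1, cfg)
  h2 <- generate_two_release_annotations(g2, cfg)
  expect_identical(h1$older$Y, h2$older$Y)
  expect_identical(h1$newer$Y, h2$newer$Y)
})

test_that("planted partitions are modular and disconnect when between_p = 0", {
  cfg <- synthetic_config(n = 100, communities = 2, within_p = 0.3,
                          between_p = 0.01, m_terms = 2, seed = 5)
  g <- generate_network(cfg)
  same <- outer(g$membership, g$membership, "==")
  within <- sum(g$scores[upper.tri(g$scores)] > 0 & same[upper.tri(same)])
  total <- sum(g$scores[upper.tri(g$scores)] > 0)
  expect_gt(within / total, 0.9)  # expectation is ~0.97 at these rates

  cfg0 <- synthetic_config(n = 100, communities = 2, within_p = 0.3,
                           between_p = 0, m_terms = 2, seed = 5)
  g0 <- generate_network(cfg0)
  comps <- connected_components(g0$net)
  expect_gte(length(comps$sizes), 2)

  expect_error(synthetic_config(n = 200, communities = 2, within_p = 0.005,
                                between_p = 0.0005),
               "unsatisfiable density")
})

test_that("generated holdouts define C_np exactly and contain no revocations", {
  for (nm in c("tiny", "negsel")) {
    ds <- make_fixture(nm)
    Y <- ds$holdout$older$Y
    Yb <- ds$holdout$newer$Y
    expect_true(all(Yb >= Y))               # no revocations by construction
    expect_equal(sum(ds$holdout$revocations), 0)
    for (k in ds$holdout$terms)
      expect_setequal(ds$holdout$cnp[[k]],
                      rownames(Y)[Y[, k] == 0 & Yb[, k] == 1])
  }
})

test_that("fixtures pass their configured C_np filters", {
  expect_true(all(lengths(make_fixture("tiny")$holdout$cnp) >= 5))
  for (nm in c("afp", "negsel"))
    expect_true(all(lengths(make_fixture(nm)$holdout$cnp) >= 20))
})

test_that("the relevance and null fixtures differ only in beta", {
  rel <- make_fixture("relevance")
  nul <- make_fixture("null")
  expect_identical(rel$scores, nul$scores)
  expect_identical(rel$holdout$older$Y, nul$holdout$older$Y)
  expect_false(identical(rel$holdout$newer$Y, nul$holdout$newer$Y))
  expect_equal(unique(nul$config$beta), 0)
})

test_that("beta = 0 conversions are independent of f10", {
  # Pooled chi-square of conversion against f10 deciles across small
  # replicates; at the 0.01 level we expect about 0.2 rejections in 20.
  rejections <- 0
  for (seed in 1:20) {
    cfg <- synthetic_config(n = 150, communities = 3, within_p = 0.25,
                            between_p = 0.02, m_terms = 4,
                            pos_range = c(8, 12), target_cnp = 15, beta = 0,
                            min_cnp_enforce = NULL, seed = 500 + seed)
    g <- generate_network(cfg)
    h <- generate_two_release_annotations(g, cfg)
    W <- g$net$W
    f10s <- conv <- numeric(0)
    for (k in h$terms) {
      y <- h$older$Y[, k]
      cand <- which(y == 0)
      f10 <- as.numeric(W %*% y)[cand]
      f10s <- c(f10s, f10)
      conv <- c(conv, as.numeric(h$newer$Y[cand, k]))
    }
    dec <- cut(rank(f10s, ties.method = "first"), 10)
    pv <- suppressWarnings(chisq.test(table(dec, conv))$p.value)
    if (pv < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)
})

test_that("large beta concentrates conversions on high-f10 proteins", {
  wins <- 0
  for (seed in 1:10) {
    cfg <- synthetic_config(n = 150, communities = 3, within_p = 0.25,
                            between_p = 0.02, m_terms = 3,
                            pos_range = c(8, 12), target_cnp = 15, beta = 3,
                            min_cnp_enforce = NULL, seed = 600 + seed)
    g <- generate_network(cfg)
    h <- generate_two_release_annotations(g, cfg)
    W <- g$net$W
    diff <- 0
    for (k in h$terms) {
      y <- h$older$Y[, k]
      cand <- which(y == 0)
      f10 <- as.numeric(W %*% y)[cand]
      is_cnp <- rownames(h$older$Y)[cand] %in% h$cnp[[k]]
      diff <- diff + mean(f10[is_cnp]) - mean(f10[!is_cnp])
    }
    if (diff > 0) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("the intercept calibration hits the target C_np size", {
  cfg <- synthetic_config(n = 500, communities = 5, m_terms = 10,
                          target_cnp = 25, beta = 3,
                          min_cnp_enforce = NULL, seed = 303)
  g <- generate_network(cfg)
  h <- generate_two_release_annotations(g, cfg)
  sizes <- lengths(h$cnp)
  # Poisson-binomial sd is below 5; the mean of 10 terms concentrates hard.
  expect_lt(abs(mean(sizes) - 25), 5)
  expect_true(all(abs(sizes - 25) <= 15))
})

test_that("rank correlation between f10 and conversion increases with beta", {
  mean_cor <- function(beta) {
    rs <- numeric(0)
    for (seed in 1:15) {
      cfg <- synthetic_config(n = 120, communities = 2, within_p = 0.3,
                              between_p = 0.03, m_terms = 2,
                              pos_range = c(8, 12), target_cnp = 14,
                              beta = beta, min_cnp_enforce = NULL,
                              seed = 700 + seed)
      g <- generate_network(cfg)
      h <- generate_two_release_annotations(g, cfg)
      W <- g$net$W
      for (k in h$terms) {
        y <- h$older$Y[, k]
        cand <- which(y == 0)
        f10 <- as.numeric(W %*% y)[cand]
        conv <- as.numeric(h$newer$Y[cand, k])
        if (sd(conv) > 0)
          rs <- c(rs, cor(f10, conv, method = "spearman"))
      }
    }
    mean(rs)
  }
  r0 <- mean_cor(0); r1 <- mean_cor(1.5); r3 <- mean_cor(4)
  expect_gte(r1, r0 - 0.02)
  expect_gte(r3, r1 - 0.02)
  expect_gt(r3, r0 + 0.05)
})

test_that("written datasets round-trip through the file loaders", {
  ds <- make_fixture("tiny")
  dir <- tempfile("rt_")
  write_dataset(ds, dir)
  raw <- load_string_edges(file.path(dir, "edges.tsv"), threshold = 700)
  net <- symmetric_normalize(raw)
  expect_setequal(net$node_labels, ds$network$node_labels)
  expect_equal(net$W[ds$network$node_labels, ds$network$node_labels],
               ds$network$W, tolerance = 1e-12)
  old <- load_annotations(file.path(dir, "annotations_old.tsv"),
                          net$node_labels)
  expect_equal(old$Y[rownames(ds$holdout$older$Y), colnames(ds$holdout$older$Y)],
               ds$holdout$older$Y)
})
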