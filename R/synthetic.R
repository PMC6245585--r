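# Synthetic benchmark generator: planted-partition weighted networks and
# paired two-release annotation matrices in which the probability that a
# non-positive converts to a positive (the C_np class) is a logistic
# function of its guilt-by-association score f10. The effect size beta is
# the dial the benchmarks turn; everything else is calibrated.

#' Synthetic benchmark configuration
#'
#' Defines a planted-partition network (communities with dense
#' within-community and sparse between-community connectivity, STRING-like
#' integer scores drawn from a scaled Beta distribution) and a two-release
#' annotation process: per term, old-release positives are sampled inside a
#' home community, and each old-release non-positive converts to a
#' newer-release positive with probability
#' `plogis(alpha + beta * z(f10))`, where `z(f10)` is the standardized
#' positive-neighborhood score and `alpha` is solved by bisection so the
#' expected `|C_np|` matches `target_cnp`. With `beta = 0` conversions are
#' uniform; large `beta` concentrates them on high-f10 proteins.
#'
#' @param n number of proteins.
#' @param communities number of equally sized communities.
#' @param within_p,between_p edge probabilities inside / across communities.
#' @param score_shape1,score_shape2 Beta shape parameters for the combined
#'   scores, which are drawn as `round(701 + 298 * Beta)` so every edge
#'   survives the standard 700 threshold.
#' @param m_terms number of GO-like terms.
#' @param pos_range inclusive range of old-release positive counts per term.
#' @param target_cnp expected `|C_np|` per term the intercept is calibrated
#'   to.
#' @param beta guilt-by-association effect size (scalar, or one value per
#'   term for a graded design).
#' @param noise_rate probability that any (protein, term) pair receives an
#'   extra old-release annotation, giving the annotation-count feature a
#'   non-degenerate distribution.
#' @param planted_modules plant each term's positive class as a
#'   degree-compensated dense module: the positives are drawn uniformly in
#'   the home community, extra edges are added among them up to internal
#'   density `planted_density`, and each added edge is compensated by
#'   deleting a random edge from one endpoint toward the outside, so
#'   degrees and weight distributions stay flat while connectivity toward
#'   the positive set becomes the discriminating signal (separable terms).
#' @param planted_density target internal edge density of a planted module.
#' @param degree_sdlog standard deviation (log scale) of the per-node
#'   connection propensity; 0 gives homogeneous degrees, larger values give
#'   a heavy-tailed degree distribution with hubs, through which weighted
#'   shortest paths then preferentially route.
#' @param min_cnp_enforce redraw conversions (bounded retries) until every
#'   term has at least this many `C_np` members; `NULL` disables.
#' @param seed RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 500, communities = 5, within_p = 0.15,
                             between_p = 0.01, score_shape1 = 2,
                             score_shape2 = 2, m_terms = 60,
                             pos_range = c(10, 25), target_cnp = 30,
                             beta = 3, noise_rate = 0.01,
                             planted_modules = FALSE, planted_density = 0.6,
                             degree_sdlog = 0,
                             min_cnp_enforce = 20, seed = 1) {
  stopifnot(n %% communities == 0, within_p >= 0, within_p <= 1,
            between_p >= 0, between_p <= 1, all(beta >= 0),
            pos_range[1] <= pos_range[2], target_cnp >= 1)
  size <- n / communities
  p_iso <- (1 - within_p)^(size - 1) * (1 - between_p)^(n - size)
  if (p_iso > 0.2)
    stop("unsatisfiable density: expected isolated fraction ",
         round(p_iso, 3), " exceeds 20%")
  structure(list(n = n, communities = communities, within_p = within_p,
                 between_p = between_p, score_shape1 = score_shape1,
                 score_shape2 = score_shape2, m_terms = m_terms,
                 pos_range = pos_range, target_cnp = target_cnp,
                 beta = beta, noise_rate = noise_rate,
                 planted_modules = planted_modules,
                 planted_density = planted_density,
                 degree_sdlog = degree_sdlog,
                 min_cnp_enforce = min_cnp_enforce, seed = seed),
            class = "synthetic_config")
}

#' Generate a planted-partition weighted network
#'
#' Draws within/between-community edges independently, assigns integer
#' combined scores in 701--999 from the configured Beta distribution, and
#' rewires any isolated node to a random member of its community. The raw
#' weights are `score / 1000`; the returned network is symmetric-normalized.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `net` (`weighted_network`), `raw` (`raw_network`),
#'   `scores` (integer score matrix) and `membership`.
#' @export
generate_network <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1), {
    n <- cfg$n
    size <- n / cfg$communities
    membership <- rep(seq_len(cfg$communities), each = size)
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- membership[ut[, 1]] == membership[ut[, 2]]
    p <- ifelse(same, cfg$within_p, cfg$between_p)
    if ((cfg$degree_sdlog %||% 0) > 0) {
      # Heavy-tailed per-node propensities (mean 1) create hub nodes.
      theta <- stats::rlnorm(n, -cfg$degree_sdlog^2 / 2, cfg$degree_sdlog)
      p <- pmin(1, p * theta[ut[, 1]] * theta[ut[, 2]])
    }
    edge <- stats::rbinom(nrow(ut), 1, p) == 1
    scores <- matrix(0L, n, n)
    ne <- sum(edge)
    sc <- as.integer(round(701 + 298 *
                             stats::rbeta(ne, cfg$score_shape1, cfg$score_shape2)))
    scores[ut[edge, , drop = FALSE]] <- sc
    scores <- scores + t(scores)
    planted <- NULL
    if (isTRUE(cfg$planted_modules)) {
      planted <- vector("list", cfg$m_terms)
      for (k in seq_len(cfg$m_terms)) {
        home <- (k - 1L) %% cfg$communities + 1L
        npos <- if (cfg$pos_range[1] == cfg$pos_range[2]) cfg$pos_range[1]
                else sample(seq(cfg$pos_range[1], cfg$pos_range[2]), 1)
        P <- sort(sample(which(membership == home), npos))
        planted[[k]] <- P
        # Raise the density of edges across the two halves of the module to
        # the target (bipartite-style, so local clustering stays flat) and
        # compensate each added edge by deleting one outside edge per
        # endpoint, keeping degrees flat. What remains elevated is exactly
        # the connectivity toward the positive set.
        half <- integer(npos); half[sample(npos, floor(npos / 2))] <- 1L
        pr <- which(upper.tri(matrix(0, npos, npos)), arr.ind = TRUE)
        pr <- pr[half[pr[, 1]] != half[pr[, 2]], , drop = FALSE]
        absent <- which(scores[cbind(P[pr[, 1]], P[pr[, 2]])] == 0)
        p_add <- max(0, (cfg$planted_density - cfg$within_p) /
                          max(1e-12, 1 - cfg$within_p))
        add <- absent[stats::runif(length(absent)) < p_add]
        for (e in add) {
          i <- P[pr[e, 1]]; j <- P[pr[e, 2]]
          s <- as.integer(round(701 + 298 *
                                  stats::rbeta(1, cfg$score_shape1,
                                               cfg$score_shape2)))
          scores[i, j] <- s; scores[j, i] <- s
          for (ep in c(i, j)) {
            out <- setdiff(which(scores[ep, ] > 0), P)
            if (length(out) > 1) {
              del <- out[sample.int(length(out), 1)]
              scores[ep, del] <- 0L; scores[del, ep] <- 0L
            }
          }
        }
      }
    }
    # Rewire isolates to a random community member.
    iso <- which(rowSums(scores) == 0)
    for (i in iso) {
      pool <- setdiff(which(membership == membership[i]), i)
      j <- pool[sample.int(length(pool), 1)]
      s <- as.integer(round(701 + 298 *
                              stats::rbeta(1, cfg$score_shape1, cfg$score_shape2)))
      scores[i, j] <- s; scores[j, i] <- s
    }
    labels <- sprintf("P%04d", seq_len(n))
    dimnames(scores) <- list(labels, labels)
    raw <- new_raw_network(labels, scores / 1000)
    list(net = symmetric_normalize(raw), raw = raw, scores = scores,
         membership = membership, planted = planted)
  })
}

# Solve for the intercept alpha such that sum(plogis(alpha + beta*z)) equals
# the target expected number of conversions.
calibrate_alpha <- function(z, beta, target, lo = -40, hi = 40) {
  f <- function(a) sum(stats::plogis(a + beta * z)) - target
  if (f(lo) > 0 || f(hi) < 0)
    stop("intercept calibration failed to bracket the target |C_np| (",
         "target=", target, ", candidates=", length(z), ")")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a two-release annotation holdout on a network
#'
#' Per term: a home community is chosen cyclically and old-release
#' positives are sampled uniformly inside it (or taken from the planted
#' module when the network was generated with `planted_modules`), plus
#' uniform noise annotations at `noise_rate`. The guilt-by-association
#' score f10 is computed with respect to those positives, and old-release
#' non-positives convert to newer-release positives with probability
#' `plogis(alpha + beta * z(f10))` with `alpha` calibrated to the target
#' `|C_np|`. The newer release always contains the older one (no
#' revocations by construction).
#'
#' @param netgen output of [generate_network()].
#' @param cfg the same [synthetic_config()].
#' @return A `temporal_holdout` with an extra attribute `generation_log`
#'   (per-term alpha, beta, realized `|C_np|`).
#' @export
generate_two_release_annotations <- function(netgen, cfg) {
  with_seed(derive_seed(cfg$seed, 2), {
    net <- netgen$net
    W <- net$W
    n <- cfg$n
    labels <- net$node_labels
    m <- cfg$m_terms
    betas <- rep_len(cfg$beta, m)
    terms <- sprintf("T%03d", seq_len(m))
    Y <- matrix(0L, n, m, dimnames = list(labels, terms))
    Yb <- matrix(0L, n, m, dimnames = list(labels, terms))
    log <- vector("list", m)
    for (k in seq_len(m)) {
      home <- (k - 1L) %% cfg$communities + 1L
      pool <- which(netgen$membership == home)
      # The older release is drawn on its own per-term stream, so that twin
      # configurations differing only in beta share it exactly.
      y <- with_seed(derive_seed(cfg$seed, 2, k), {
        pos <- if (!is.null(netgen$planted)) netgen$planted[[k]]
        else {
          npos <- if (cfg$pos_range[1] == cfg$pos_range[2]) cfg$pos_range[1]
                  else sample(seq(cfg$pos_range[1], cfg$pos_range[2]), 1)
          sample(pool, npos)
        }
        y <- integer(n); y[pos] <- 1L
        noise <- which(stats::runif(n) < cfg$noise_rate & y == 0L)
        y[noise] <- 1L
        y
      })
      f10 <- as.numeric(W %*% y)
      cand <- which(y == 0L)
      z <- f10[cand]
      z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
      beta_k <- betas[k]
      alpha <- calibrate_alpha(z, beta_k, cfg$target_cnp)
      pr <- stats::plogis(alpha + beta_k * z)
      tries <- 0L
      conv <- with_seed(derive_seed(cfg$seed, 3, k), {
        repeat {
          conv <- stats::rbinom(length(cand), 1, pr) == 1
          tries <- tries + 1L
          if (is.null(cfg$min_cnp_enforce) ||
              sum(conv) >= cfg$min_cnp_enforce || tries >= 25L) break
        }
        conv
      })
      if (!is.null(cfg$min_cnp_enforce) && sum(conv) < cfg$min_cnp_enforce)
        stop("term ", terms[k], ": could not reach |C_np| >= ",
             cfg$min_cnp_enforce, " after 25 redraws")
      Y[, k] <- y
      Yb[, k] <- y
      Yb[cand[conv], k] <- 1L
      log[[k]] <- data.frame(term = terms[k], alpha = alpha, beta = beta_k,
                             n_pos = sum(y), cnp = sum(conv), tries = tries)
    }
    holdout <- build_holdout(new_annotation_release(Y, "older"),
                             new_annotation_release(Yb, "newer"))
    attr(holdout, "generation_log") <- do.call(rbind, log)
    holdout
  })
}

#' Canned benchmark fixtures
#'
#' Seeded configurations exercising every pipeline stage:
#' * `tiny` -- n = 30, 2 terms; small enough to run the full pipeline
#'   end-to-end in seconds (its terms pass `min_cnp(5)`, not the default 20).
#' * `relevance` -- n = 500, 60 terms, strong guilt-by-association effect
#'   (beta = 3).
#' * `null` -- the beta = 0 twin of `relevance` (same seed, same network,
#'   same positives; only the conversion mechanism differs).
#' * `afp` -- n = 240, 3 separable terms (assortative positive sampling).
#' * `negsel` -- n = 300, 12 terms with beta graded over {0.5, 1, 2, 3}.
#'
#' @param name fixture name.
#' @param seed optional seed override (defaults are fixed per fixture so
#'   fixtures regenerate bit-identically).
#' @return A `synthetic_dataset`: list with `network` (`weighted_network`),
#'   `raw`, `scores`, `membership`, `holdout`, `config` and `log`.
#' @export
make_fixture <- function(name = c("tiny", "relevance", "null", "afp", "negsel"),
                         seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = synthetic_config(n = 30, communities = 2, within_p = 0.4,
                            between_p = 0.06, m_terms = 2,
                            pos_range = c(4, 6), target_cnp = 8, beta = 2,
                            noise_rate = 0.02, min_cnp_enforce = 5,
                            seed = seed %||% 11),
    relevance = synthetic_config(m_terms = 60, beta = 3,
                                 seed = seed %||% 42),
    null = synthetic_config(m_terms = 60, beta = 0, seed = seed %||% 42),
    afp = synthetic_config(n = 450, communities = 1, within_p = 0.25,
                           between_p = 0, m_terms = 3,
                           pos_range = c(40, 50), target_cnp = 30, beta = 2,
                           noise_rate = 0, planted_modules = TRUE,
                           planted_density = 0.8, degree_sdlog = 1,
                           seed = seed %||% 7),
    negsel = synthetic_config(n = 300, communities = 5, within_p = 0.2,
                              between_p = 0.015, m_terms = 12,
                              pos_range = c(15, 25), target_cnp = 30,
                              beta = rep(c(0.5, 1, 2, 3), 3),
                              noise_rate = 0.05,
                              seed = seed %||% 99))
  gen <- generate_network(cfg)
  holdout <- generate_two_release_annotations(gen, cfg)
  structure(list(network = gen$net, raw = gen$raw, scores = gen$scores,
                 membership = gen$membership, holdout = holdout,
                 config = cfg, log = attr(holdout, "generation_log"),
                 name = name),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset '", x$name, "': ", x$config$n, " proteins, ",
      x$config$m_terms, " terms, beta = ",
      paste(unique(x$config$beta), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset in the pipeline input formats
#'
#' Emits `edges.tsv` (protein1, protein2, combined_score),
#' `annotations_old.tsv` and `annotations_new.tsv` (protein, term,
#' evidence), so that a generated dataset can be re-ingested through
#' [load_string_edges()] and [load_annotations()].
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- ds$scores
  ut <- which(upper.tri(sc) & sc > 0, arr.ind = TRUE)
  edges <- data.frame(protein1 = rownames(sc)[ut[, 1]],
                      protein2 = colnames(sc)[ut[, 2]],
                      combined_score = sc[ut])
  edges <- edges[order(edges$protein1, edges$protein2), ]
  write_tsv <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  ann_df <- function(Y) {
    idx <- which(Y == 1L, arr.ind = TRUE)
    df <- data.frame(protein = rownames(Y)[idx[, 1]],
                     term = colnames(Y)[idx[, 2]], evidence = "EXP")
    df[order(df$protein, df$term), ]
  }
  paths <- c(edges = file.path(dir, "edges.tsv"),
             old = file.path(dir, "annotations_old.tsv"),
             new = file.path(dir, "annotations_new.tsv"))
  write_tsv(edges, paths["edges"])
  write_tsv(ann_df(ds$holdout$older$Y), paths["old"])
  write_tsv(ann_df(ds$holdout$newer$Y), paths["new"])
  invisible(paths)
}
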