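fake_dccm <- function(vals) {
  rownames(vals) <- colnames(vals) <- paste0("A", seq_len(nrow(vals)))
  structure(list(values = vals, residues = NULL, window = c(1, 2),
                 scheme = "CA"), class = "dccm_matrix")
}

test_that("contact frequencies count frames inside the cutoff", {
  # residues 1-2 fixed at 4 A; residues 2-3 inside the cutoff in 3 of 6
  # frames; residue 4 never within 10 A of anything
  frames <- lapply(1:6, function(f) {
    rbind(c(0, 0, 0), c(4, 0, 0),
          c(if (f <= 3) 8 else 40, 0, 0), c(100, 0, 0))
  })
  tr <- frames_trajectory(frames)
  f <- contact_frequencies(tr, cutoff = 5.7)
  expect_equal(unname(f[1, 2]), 1)
  expect_equal(unname(f[2, 3]), 0.5)
  expect_equal(unname(f[1, 4]), 0)
  expect_equal(unname(diag(f)), rep(1, 4))
})

test_that("edge pruning follows the strict less-than-threshold rule", {
  C <- rbind(c(1, 0.9, 0.8), c(0.9, 1, 0.7), c(0.8, 0.7, 1))
  d <- fake_dccm(C)
  freqs <- rbind(c(1, 0.5, 0.4), c(0.5, 1, 1), c(0.4, 1, 1))
  g <- build_weighted_network(d, freqs)
  key <- paste(g$edges$i, g$edges$j)
  expect_true("1 2" %in% key)    # f = 0.5 exactly: retained
  expect_false("1 3" %in% key)   # f = 0.4 < 0.5: removed
  expect_true("2 3" %in% key)
  # cost transform
  e12 <- g$edges[g$edges$i == 1 & g$edges$j == 2, ]
  expect_equal(e12$cost, -log(0.9), tolerance = 1e-12)
  expect_equal(e12$correlation, 0.9)

  # anticorrelated edges carry |C|-based positive cost
  Cn <- rbind(c(1, -0.9), c(-0.9, 1))
  gn <- build_weighted_network(fake_dccm(Cn), matrix(1, 2, 2))
  expect_equal(gn$edges$cost, -log(0.9), tolerance = 1e-12)
  expect_equal(gn$edges$correlation, -0.9)

  # |C| = 1 floored to keep the cost positive; C = 0 dropped
  C1 <- rbind(c(1, 1, 0), c(1, 1, 0.5), c(0, 0.5, 1))
  g1 <- build_weighted_network(fake_dccm(C1), matrix(1, 3, 3))
  expect_true(all(g1$edges$cost > 0))
  expect_false("1 3" %in% paste(g1$edges$i, g1$edges$j))

  # linear transform
  gl <- build_weighted_network(fake_dccm(Cn), matrix(1, 2, 2),
                               transform = "linear")
  expect_equal(gl$edges$cost, 0.1, tolerance = 1e-12)
})

test_that("graph construction is invariant to residue relabeling", {
  set.seed(10)
  n <- 8
  C <- matrix(stats::runif(n * n, -1, 1), n, n)
  C <- (C + t(C)) / 2; diag(C) <- 1
  freqs <- matrix(stats::runif(n * n), n, n)
  freqs <- (freqs + t(freqs)) / 2; diag(freqs) <- 1
  g <- build_weighted_network(fake_dccm(C), freqs)
  perm <- sample(n)
  gp <- build_weighted_network(fake_dccm(C[perm, perm]),
                               freqs[perm, perm])
  # edges map back to the same residue pairs with the same weights
  orig <- g$edges
  back <- gp$edges
  back$i2 <- pmin(perm[back$i], perm[back$j])
  back$j2 <- pmax(perm[back$i], perm[back$j])
  back <- back[order(back$i2, back$j2), ]
  orig <- orig[order(orig$i, orig$j), ]
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$i2, orig$i)
  expect_equal(back$j2, orig$j)
  expect_equal(back$cost, orig$cost)
})

test_that("shortest paths match hand-enumerated minima and contracts", {
  # AB:1 BC:1 AC:3 CD:1 BD:5 -> A..D via A-B-C-D, cost 3
  g <- edge_graph(i = c(1, 2, 1, 3, 2), j = c(2, 3, 3, 4, 4),
                  cost = c(1, 1, 3, 1, 5))
  p <- shortest_path(g, 1, 4)
  expect_identical(p$path, c(1L, 2L, 3L, 4L))
  expect_equal(p$cost, 3)
  expect_equal(sum(p$edge_costs), p$cost)

  # source = target
  p0 <- shortest_path(g, 2, 2)
  expect_identical(p0$path, 2L)
  expect_equal(p0$cost, 0)

  # unreachable target: explicit no-path, not an exception
  g2 <- edge_graph(i = 1, j = 2, cost = 1, n = 3)
  pn <- shortest_path(g2, 1, 3)
  expect_false(pn$found)
  expect_equal(pn$cost, Inf)
})

test_that("cost ties break by hops then lexicographic order", {
  # two cost-2 A-D routes: A-B-D and A-C-D -> pick A-B-D (lex smaller);
  # plus a 3-hop cost-2 route A-E-F-D that loses on hops
  g <- edge_graph(i = c(1, 2, 1, 3, 1, 5, 6),
                  j = c(2, 4, 3, 4, 5, 6, 4),
                  cost = c(1, 1, 1, 1, 0.5, 0.5, 1))
  p <- shortest_path(g, 1, 4)
  expect_identical(p$path, c(1L, 2L, 4L))
  oracle <- brute_best_path(g, 1, 4)
  expect_identical(p$path, as.integer(oracle$path))
})

test_that("Dijkstra agrees with brute-force enumeration on random graphs", {
  for (seed in 1:40) {
    n <- 4L + (seed %% 7L)
    g <- make_random_graph(n, 0.45, c(0.1, 2), seed = seed)
    if (nrow(g$edges) == 0L) next
    s <- 1L; t <- n
    p <- shortest_path(g, s, t)
    oracle <- brute_best_path(g, s, t)
    if (!p$found) {
      expect_true(is.infinite(oracle$cost))
    } else {
      expect_equal(p$cost, oracle$cost, tolerance = 1e-9)
      expect_identical(p$path, as.integer(oracle$path))
    }
  }
})

test_that("removing an edge never shortens any path", {
  for (seed in 1:10) {
    g <- make_random_graph(8, 0.5, c(0.1, 2), seed = seed)
    if (nrow(g$edges) < 2L) next
    p_full <- shortest_path(g, 1, 8)
    g_cut <- g
    g_cut$edges <- g_cut$edges[-1L, ]
    p_cut <- shortest_path(g_cut, 1, 8)
    expect_gte(p_cut$cost, p_full$cost - 1e-12)
  }
})

test_that("allosteric pathways deduplicate shared stems", {
  # star-like: site 1 - 2 - 3, then 3 branches to targets 4, 5, 6
  g <- edge_graph(i = c(1, 2, 3, 3, 3), j = c(2, 3, 4, 5, 6),
                  cost = rep(1, 5))
  targets <- regions_from_residues(4:6, 6)
  pw <- allosteric_pathways(g, 1, targets)
  expect_length(pw$paths, 3L)
  expect_true(all(vapply(pw$paths, function(p) p$found, logical(1L))))
  # stem edges (1,2) and (2,3) appear exactly once in the union
  expect_equal(nrow(pw$edge_union), 5L)

  # targets = site: single trivial path
  pw0 <- allosteric_pathways(g, 1, regions_from_residues(1L, 6))
  expect_length(pw0$paths, 1L)
  expect_identical(pw0$paths[[1L]]$path, 1L)
  expect_equal(nrow(pw0$edge_union), 0L)

  # unreachable region: no-path entries, union unchanged
  g2 <- edge_graph(i = 1, j = 2, cost = 1, n = 4)
  pw2 <- allosteric_pathways(g2, 1, regions_from_residues(3:4, 4))
  expect_true(all(!vapply(pw2$paths, function(p) p$found, logical(1L))))
  expect_equal(nrow(pw2$edge_union), 0L)

  # empty target set -> empty list
  pw3 <- allosteric_pathways(g2, 1, regions_from_residues(integer(), 4))
  expect_length(pw3$paths, 0L)
})

test_that("residue graphs reject invalid costs and self-edges", {
  expect_error(edge_graph(1, 1, 1), "self-edges")
  expect_error(edge_graph(1, 2, 0), "positive")
  expect_error(edge_graph(1, 2, Inf), "positive|finite")
})
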