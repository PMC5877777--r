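make_rigid_copies <- function(base, transforms) {
  # base: N x 3 node matrix; each frame is a true rigid transform of the
  # full atom set (so superposition can recover it exactly)
  s <- point_structure(base)
  A <- as.matrix(s$atom[, c("x", "y", "z")])
  xyz <- do.call(rbind, lapply(transforms, function(tr)
    as.vector(t(sweep(A %*% t(tr$R), 2L, -tr$t)))))
  allonet:::new_trajectory(xyz, s$atom[, c("chain", "resno", "resid",
                                           "elety")])
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0),
                           c(sin(a), cos(a), 0),
                           c(0, 0, 1))

test_that("superposition removes translations and rotations", {
  base <- node_coordinates(make_helical_bundle(1, 8, seed = 1), "CB")
  tr <- make_rigid_copies(base, list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(3), t = c(5, -2, 1)),
    list(R = rot_z(0.7), t = c(0, 0, 0)),
    list(R = rot_z(-1.2), t = c(3, 3, -4))))
  fit <- superpose_frames(tr, reference = "first")
  for (f in 2:4)
    expect_lt(max(abs(fit$xyz[f, ] - fit$xyz[1, ])), 1e-6)
})

test_that("a known rigid transform is recovered exactly", {
  base <- node_coordinates(make_helical_bundle(1, 10, seed = 2), "CA")
  tr <- make_rigid_copies(base, list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = rot_z(0.9), t = c(1, 2, 3))))
  fit <- superpose_frames(tr, reference = "first")
  expect_lt(max(abs(fit$xyz[2, ] - fit$xyz[1, ])), 1e-6)
})

test_that("collinear frames are rejected as degenerate", {
  line <- cbind(seq(0, 30, length.out = 6), 0, 0)
  tr <- frames_trajectory(list(line, line + 1))
  # CB nodes are collinear; full-atom set includes offset CAs, so build
  # a trajectory whose atoms are all on one line
  tr$xyz <- t(vapply(1:2, function(f)
    as.vector(t(cbind(seq_len(ncol(tr$xyz) / 3), 0, 0))),
    numeric(ncol(tr$xyz))))
  expect_error(superpose_frames(tr), "degenerate|collinear")
})

test_that("the DCCM has unit diagonal, symmetry and bounded entries", {
  b <- make_helical_bundle(2, 8, seed = 3)
  tr <- make_correlated_trajectory(
    b, list(list(a = 1:4, b = 9:12, rho = 0.7)), n_frames = 400, seed = 6)
  d <- compute_dccm(tr, window = c(1, 400))
  expect_equal(unname(diag(d$values)), rep(1, 16))
  expect_identical(d$values, t(d$values))
  expect_true(all(abs(d$values) <= 1))
})

test_that("compute_dccm matches the naive direct-summation oracle", {
  b <- make_helical_bundle(1, 12, seed = 4)
  tr <- make_correlated_trajectory(
    b, list(list(a = 1:3, b = 4:6, rho = -0.5)), n_frames = 250, seed = 8)
  d <- compute_dccm(tr, window = c(1, 250))
  oracle <- naive_dccm(node_xyz(tr, "CA")[1:250, ])
  expect_lt(max(abs(d$values - oracle)), 1e-12)
})

test_that("the DCCM is invariant to a uniform rigid transform of frames", {
  b <- make_helical_bundle(1, 8, seed = 5)
  tr <- make_correlated_trajectory(b, n_frames = 60, seed = 2)
  d0 <- compute_dccm(superpose_frames(tr), window = c(1, 60))
  R <- rot_z(1.1)
  moved <- tr
  for (f in seq_len(60)) {
    m <- matrix(tr$xyz[f, ], ncol = 3L, byrow = TRUE)
    moved$xyz[f, ] <- as.vector(t(sweep(m %*% t(R), 2L, -c(10, -4, 2))))
  }
  d1 <- compute_dccm(superpose_frames(moved), window = c(1, 60))
  expect_lt(max(abs(d0$values - d1$values)), 1e-8)
})

test_that("zero-variance nodes are reported by residue", {
  frames <- lapply(1:5, function(f) {
    m <- cbind(c(0, 10, 20), c(0, 0, 0), c(0, 0, 0))
    m[2, 2] <- f; m[3, 3] <- -f  # residues 2,3 move; residue 1 frozen
    m
  })
  tr <- frames_trajectory(frames)
  expect_error(compute_dccm(tr, window = c(1, 5), scheme = "CB"),
               "A1.*zero|zero.*A1")
})

test_that("window selection validates and defaults to the final tenth", {
  b <- make_helical_bundle(1, 6, seed = 1)
  tr <- make_correlated_trajectory(b, n_frames = 100, seed = 1)
  d <- compute_dccm(tr)
  expect_equal(d$window, c(91L, 100L))
  expect_error(compute_dccm(tr, window = c(50, 500)), "window")
  expect_error(compute_dccm(tr, window = c(10, 10)), "window")
})

test_that("region classification applies ordered tiers around an anchor", {
  n <- 20
  vals <- diag(n)
  # anchor 5: strong positive run 6..8, medium 9, negative block 10..14
  vals[5, 6:8] <- vals[6:8, 5] <- 0.8
  vals[5, 9] <- vals[9, 5] <- 0.6
  vals[5, 10:14] <- vals[10:14, 5] <- -0.9
  d <- structure(list(values = vals, residues = NULL, window = c(1, 2),
                      scheme = "CA"), class = "dccm_matrix")
  rownames(d$values) <- colnames(d$values) <- paste0("A", 1:n)
  rs <- classify_regions(d, 5)
  iv <- rs$intervals
  expect_true(any(iv$tier == "red" & iv$start == 5 & iv$end == 8))
  expect_true(any(iv$tier == "orange" & iv$start == 9 & iv$end == 9))
  expect_true(any(iv$tier == "anti" & iv$start == 10 & iv$end == 14))
  expect_false(15 %in% region_residues(rs))

  # identity matrix: only the anchor classifies
  id <- d; id$values <- diag(n)
  rownames(id$values) <- colnames(id$values) <- paste0("A", 1:n)
  rs_id <- classify_regions(id, 3)
  expect_identical(region_residues(rs_id), 3L)

  expect_error(classify_regions(d, 5, thresholds = c(0.5, 0.6, 0.4)),
               "not ordered")
})

test_that("enlarging a tier threshold never grows the tier", {
  set.seed(33)
  n <- 30
  vals <- matrix(stats::runif(n * n, -1, 1), n, n)
  vals <- (vals + t(vals)) / 2; diag(vals) <- 1
  d <- structure(list(values = vals, residues = NULL, window = c(1, 2),
                      scheme = "CA"), class = "dccm_matrix")
  rownames(d$values) <- colnames(d$values) <- paste0("A", 1:n)
  for (red in c(0.5, 0.6, 0.7, 0.8)) {
    lo <- classify_regions(d, 1, thresholds = c(yellow = 0.3, orange = 0.4,
                                                red = red))
    hi <- classify_regions(d, 1, thresholds = c(yellow = 0.3, orange = 0.4,
                                                red = red + 0.1))
    expect_true(all(region_residues(hi, "red") %in%
                      region_residues(lo, "red")))
  }
})

test_that("combine_regions unions and re-merges intervals", {
  a <- region_set(data.frame(start = 1, end = 5, tier = "red"), 20)
  b <- region_set(data.frame(start = 4, end = 9, tier = "anti"), 20)
  u <- combine_regions(list(a, b))
  expect_identical(u$intervals$start, 1L)
  expect_identical(u$intervals$end, 9L)

  # idempotence
  expect_identical(combine_regions(list(a, a))$intervals[, 1:2],
                   regions_from_residues(1:5, 20)$intervals[, 1:2])

  singles <- lapply(c(2L, 7L, 15L), function(r)
    regions_from_residues(r, 20))
  u3 <- combine_regions(singles)
  expect_equal(nrow(u3$intervals), 3L)
  expect_identical(region_residues(u3), c(2L, 7L, 15L))

  mis <- region_set(data.frame(start = 1, end = 2, tier = "x"), 30)
  expect_error(combine_regions(list(a, mis)), "different residue index")
})
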