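## Synthetic fixtures with analytic ground truth: idealized helical-bundle
## structures, trajectories with a planted residue-residue correlation
## structure, toy folding systems, and random weighted graphs.  These stand
## in for MD trajectories of real proteins so that every downstream stage is
## testable without simulations or downloads.  The trajectories are
## statistical, not dynamical: frames are independent draws, there is no
## force field and no kinetics.

## Repeating sequence of common helix-forming residue types (with CB nodes
## and non-trivial alanine-scan perturbations); glycine is included so the
## CA-for-glycine fallback is exercised by every generated structure.
BUNDLE_SEQUENCE <- c("ALA", "LEU", "GLU", "LYS", "PHE",
                     "GLN", "ILE", "SER", "GLY", "VAL")

#' Generate an idealized alpha-helical bundle structure
#'
#' Helices use canonical geometry (1.5 A rise and 100 degrees twist per
#' residue, 2.3 A backbone radius, consecutive Calpha distance ~3.8 A) with a
#' pseudo-Cbeta placed 1.53 A from the Calpha along the outward helix
#' normal.  Helix axes are packed on a circle so that interface node
#' distances fall in the 4-8 A range, guaranteeing contacts both inside and
#' outside the 5.7 A and 7.0 A cutoffs used downstream.  A small seeded
#' jitter (0.01 A) breaks exact symmetry; the result is deterministic for a
#' given seed.
#'
#' @param n_helices number of helices (>= 1).
#' @param residues_per_helix residues per helix (>= 4).
#' @param seed integer seed.
#' @return a `pdb_structure` (single chain A, residues numbered 1..N).
#' @export
make_helical_bundle <- function(n_helices, residues_per_helix, seed = 1L) {
  if (n_helices < 1L || residues_per_helix < 4L)
    stop("need n_helices >= 1 and residues_per_helix >= 4")
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
  axis_sep <- 9.0   # adjacent helix axis separation, A
  n_total <- n_helices * residues_per_helix
  atoms <- vector("list", n_total)
  k <- 0L
  for (h in seq_len(n_helices)) {
    if (n_helices == 1L) {
      cx <- 0; cy <- 0
    } else {
      phi <- 2 * pi * (h - 1L) / n_helices
      rpack <- axis_sep / (2 * sin(pi / n_helices))
      cx <- rpack * cos(phi); cy <- rpack * sin(phi)
    }
    antiparallel <- h %% 2L == 0L
    for (i in seq_len(residues_per_helix)) {
      k <- k + 1L
      th <- twist * (i - 1L) + (h - 1L) * pi / 3  # per-helix phase offset
      z <- rise * (if (antiparallel) residues_per_helix - i else i - 1L)
      ca <- c(cx + radius * cos(th), cy + radius * sin(th), z)
      ## pseudo-Cbeta 1.53 A from CA, tilted 45 degrees from the radial
      ## normal toward the N-terminus: reproduces the canonical helical
      ## contact pattern (i+/-1 and i+/-3 Cbeta pairs inside 5.7 A,
      ## i+/-4 inside 7.0 A) that a purely radial placement misses
      cb <- ca + 1.53 * c(cos(th) / sqrt(2), sin(th) / sqrt(2),
                          -1 / sqrt(2))
      resid <- BUNDLE_SEQUENCE[(k - 1L) %% length(BUNDLE_SEQUENCE) + 1L]
      atoms[[k]] <- data.frame(
        chain = "A", resno = k, resid = resid,
        elety = if (resid == "GLY") "CA" else c("CA", "CB"),
        x = if (resid == "GLY") ca[1L] else c(ca[1L], cb[1L]),
        y = if (resid == "GLY") ca[2L] else c(ca[2L], cb[2L]),
        z = if (resid == "GLY") ca[3L] else c(ca[3L], cb[3L]),
        stringsAsFactors = FALSE)
    }
  }
  atom <- do.call(rbind, atoms)
  jit <- with_seed(seed, matrix(stats::rnorm(3L * nrow(atom), sd = 0.01),
                                ncol = 3L))
  atom$x <- atom$x + jit[, 1L]
  atom$y <- atom$y + jit[, 2L]
  atom$z <- atom$z + jit[, 3L]
  new_structure(atom)
}

#' Planted correlation matrix implied by a block specification
#'
#' Each block is a list with elements `a`, `b` (disjoint residue index sets)
#' and `rho` in \[-1, 1\].  The implied matrix carries correlation `rho`
#' between `a` and `b` and `|rho|` within each set (a rank-one sign
#' structure, `C = (1-|rho|) I + |rho| s s'` on the union): this is the
#' unique exchangeable completion that keeps the block positive
#' semi-definite.  Unlisted pairs have correlation 0.
#'
#' @param n_residues matrix dimension.
#' @param blocks list of blocks as above; block residue sets must be
#'   pairwise disjoint across blocks.
#' @return an N x N correlation matrix (validated PSD).
#' @export
planted_correlation_matrix <- function(n_residues, blocks) {
  C <- diag(n_residues)
  used <- integer()
  for (bl in blocks) {
    stopifnot(all(c("a", "b", "rho") %in% names(bl)))
    a <- as.integer(bl$a); b <- as.integer(bl$b); rho <- bl$rho
    if (abs(rho) > 1) stop("block correlation outside [-1, 1]")
    if (length(intersect(a, b)))
      stop("residue sets within a block must be disjoint")
    members <- c(a, b)
    if (any(members < 1L) || any(members > n_residues))
      stop("block residues outside [1, n_residues]")
    if (length(intersect(members, used)))
      stop("blocks must not share residues")
    used <- c(used, members)
    if (rho == 0) next
    s <- c(rep(1, length(a)), rep(sign(rho), length(b)))
    sub <- (1 - abs(rho)) * diag(length(members)) +
      abs(rho) * tcrossprod(s)
    C[members, members] <- sub
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", format(min(ev)), ")")
  C
}

## Factor A with A A' = C, tolerating rank deficiency (rho = +/-1 blocks).
psd_factor <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam), nrow = length(lam))
}

#' Generate a trajectory with planted residue-residue correlations
#'
#' Frames are the structure's mean coordinates plus zero-mean Gaussian
#' displacements.  Displacements are drawn per axis from a multivariate
#' normal over residues with the planted correlation matrix, identically on
#' x, y and z, and applied rigidly to all atoms of a residue; this makes the
#' vector-dot cross-correlation of any residue pair equal the planted scalar
#' in expectation, giving an analytic oracle for the DCCM stage.
#'
#' @param structure a `pdb_structure` providing the mean coordinates.
#' @param blocks planted correlation blocks
#'   (see [planted_correlation_matrix()]); `NULL` for an uncorrelated
#'   trajectory.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed (full determinism).
#' @param displacement_scale per-axis displacement standard deviation in A
#'   (must be > 0: a zero scale would zero every fluctuation variance and
#'   make the DCCM undefined).
#' @return a `pdb_trajectory` with attribute `"planted"` holding the ground
#'   truth correlation matrix.
#' @export
make_correlated_trajectory <- function(structure, blocks = NULL,
                                       n_frames = 1000L, seed = 1L,
                                       displacement_scale = 0.5) {
  stopifnot(inherits(structure, "pdb_structure"))
  if (n_frames < 2L) stop("need n_frames >= 2")
  if (displacement_scale <= 0)
    stop("displacement_scale must be > 0 (zero fluctuation variance would ",
         "make the cross-correlation denominators vanish)")
  N <- n_residues(structure)
  C <- planted_correlation_matrix(N, blocks %||% list())
  A <- psd_factor(C)
  disp <- with_seed(seed, {
    lapply(1:3, function(axis)
      matrix(stats::rnorm(n_frames * N), n_frames, N) %*% t(A) *
        displacement_scale)
  })
  ## rigid per-residue displacement: every atom of residue r moves by the
  ## residue's displacement vector, so CA and CB carry the same correlation
  atom <- structure$atom
  rmap <- match(paste(atom$chain, atom$resno),
                paste(structure$residues$chain, structure$residues$resno))
  base <- as.vector(t(as.matrix(atom[, c("x", "y", "z")])))
  xyz <- matrix(rep(base, each = n_frames), nrow = n_frames)
  acols <- function(axis) 3L * seq_len(nrow(atom)) - 3L + axis
  for (axis in 1:3)
    xyz[, acols(axis)] <- xyz[, acols(axis)] + disp[[axis]][, rmap]
  traj <- new_trajectory(xyz, atom[, c("chain", "resno", "resid", "elety")])
  attr(traj, "planted") <- C
  traj
}

#' Generate a seeded random weighted graph
#'
#' Undirected Erdos-Renyi graph with positive edge costs, used as an oracle
#' fixture for the path-search algorithms.
#'
#' @param n_nodes number of nodes.
#' @param edge_prob edge probability in (0, 1].
#' @param weight_range length-2 positive `c(low, high)` cost range.
#' @param seed integer seed.
#' @return a `residue_graph` (see [build_weighted_network()]) with attribute
#'   `"connected"`.
#' @export
make_random_graph <- function(n_nodes, edge_prob, weight_range = c(0.1, 2),
                              seed = 1L) {
  stopifnot(n_nodes >= 1L)
  if (edge_prob <= 0 || edge_prob > 1) stop("edge_prob must be in (0, 1]")
  if (weight_range[1L] <= 0 || weight_range[2L] < weight_range[1L])
    stop("edge costs must be positive (Dijkstra precondition)")
  pairs <- if (n_nodes >= 2L) utils::combn(n_nodes, 2L) else
    matrix(integer(), nrow = 2L)
  edges <- with_seed(seed, {
    keep <- stats::runif(ncol(pairs)) <= edge_prob
    w <- stats::runif(sum(keep), weight_range[1L], weight_range[2L])
    data.frame(i = pairs[1L, keep], j = pairs[2L, keep],
               correlation = rep(NA_real_, sum(keep)), cost = w,
               contact_freq = rep(NA_real_, sum(keep)))
  })
  g <- new_residue_graph(edges, n_nodes,
                         labels = as.character(seq_len(n_nodes)))
  attr(g, "connected") <- graph_is_connected(g)
  g
}

#' Write a synthetic fixture directory
#'
#' Generates a helical-bundle structure and a planted-correlation trajectory
#' and writes them as single- and multi-model PDB, a ground-truth
#' correlation matrix TSV, and a JSON manifest recording the spec and seed.
#'
#' @param out_dir output directory (created if missing).
#' @param n_helices,residues_per_helix bundle geometry.
#' @param blocks planted correlation blocks; `NULL` for the default demo
#'   spec (two coupled inter-helix blocks, one correlated, one
#'   anti-correlated).
#' @param n_frames trajectory length in frames.
#' @param seed integer seed.
#' @param displacement_scale per-axis displacement sd in A.
#' @return invisibly, a list with the fixture paths and the planted matrix.
#' @export
simulate_fixture <- function(out_dir, n_helices = 4L,
                             residues_per_helix = 20L, blocks = NULL,
                             n_frames = 200L, seed = 1L,
                             displacement_scale = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_helices * residues_per_helix
  if (is.null(blocks)) blocks <- default_demo_blocks(n)
  bundle <- make_helical_bundle(n_helices, residues_per_helix, seed = seed)
  traj <- make_correlated_trajectory(bundle, blocks, n_frames = n_frames,
                                     seed = seed + 1L,
                                     displacement_scale = displacement_scale)
  paths <- list(structure = file.path(out_dir, "structure.pdb"),
                trajectory = file.path(out_dir, "trajectory.pdb"),
                planted = file.path(out_dir, "planted_correlation.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_structure(bundle, paths$structure)
  write_trajectory(traj, paths$trajectory)
  planted <- attr(traj, "planted")
  dimnames(planted) <- list(residue_labels(bundle), residue_labels(bundle))
  write_matrix_tsv(planted, paths$planted)
  spec <- list(n_helices = n_helices,
               residues_per_helix = residues_per_helix, blocks = blocks,
               n_frames = n_frames, seed = seed,
               displacement_scale = displacement_scale)
  jsonlite::write_json(list(spec = spec, files = lapply(paths, basename)),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, planted = planted, structure = bundle,
                 trajectory = traj, spec = spec))
}

## Demo planted-correlation spec used by the shipped pipeline fixture: one
## correlated and one anti-correlated inter-helix residue pair of blocks,
## at magnitudes typical of strongly coupled regions in DCCM analyses.
default_demo_blocks <- function(n_residues) {
  q <- n_residues %/% 4L
  s <- max(1L, min(6L, q - 2L, n_residues - 3L * q - 2L))
  if (q < 3L) return(list())   # too short for inter-quarter blocks
  blk <- function(a0, b0, rho)
    list(a = a0:(a0 + s - 1L), b = b0:(b0 + s - 1L), rho = rho)
  list(blk(3L, q + 3L, 0.8),
       blk(2L * q + 3L, 3L * q + 3L, -0.6))
}
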