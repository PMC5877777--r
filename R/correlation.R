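## Dynamical cross-correlation analysis.
##
## The cross-correlation of residues i and j over a trajectory window is
##
##   C(i, j) = <dr_i . dr_j> / (<dr_i^2>^1/2 <dr_j^2>^1/2)
##
## with dr the 3-vector deviation of a residue's node atom from its
## window-mean position and <.> the average over frames.  C = +1 is fully
## correlated (same-phase) motion, -1 fully anti-correlated.  The same
## normalized covariance serves both the map used for region classification
## and the edge weights of the dynamic network; one implementation avoids
## silent divergence between the two stages.

#' Rigid-body superpose trajectory frames onto a reference
#'
#' Kabsch least-squares fit (optimal rotation + translation, no scaling) of
#' every frame onto the first frame or onto the mean structure; the mean
#' reference is iterated twice (align, recompute mean, align) so
#' fluctuations are measured relative to the average position.
#'
#' @param traj a `pdb_trajectory`.
#' @param reference `"mean"` (default) or `"first"`.
#' @return the superposed `pdb_trajectory`.
#' @export
superpose_frames <- function(traj, reference = c("mean", "first")) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  reference <- match.arg(reference)
  if (traj$n_frames < 2L) stop("need at least 2 frames to superpose")
  check_nondegenerate(traj$xyz)
  inds <- seq_len(ncol(traj$xyz))
  xyz <- traj$xyz
  if (reference == "first") {
    xyz <- bio3d::fit.xyz(fixed = xyz[1L, ], mobile = xyz,
                          fixed.inds = inds, mobile.inds = inds)
  } else {
    for (it in 1:2) {
      ref <- colMeans(xyz)
      xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                            fixed.inds = inds, mobile.inds = inds)
    }
  }
  dimnames(xyz) <- NULL
  traj$xyz <- xyz
  traj
}

## the Kabsch rotation is underdetermined for collinear point sets
check_nondegenerate <- function(xyz) {
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    m <- sweep(m, 2L, colMeans(m))
    d <- svd(m, nu = 0L, nv = 0L)$d
    if (d[2L] <= 1e-8 * max(d[1L], 1))
      stop("degenerate frame ", f, ": nodes are collinear")
  }
}

#' Compute the dynamical cross-correlation matrix of a trajectory
#'
#' @param traj a `pdb_trajectory`, already superposed
#'   (see [superpose_frames()]).
#' @param window 1-based inclusive frame interval `c(start, end)`; default
#'   is the final 10\% of frames (at least 2), replicating equilibrium-tail
#'   windowing of a production run.
#' @param scheme node scheme for the correlation, `"CA"` (default) or
#'   `"CB"`.
#' @return a `dccm_matrix`: list with `values` (N x N, symmetric, unit
#'   diagonal), `residues`, and the `window` used.
#' @export
compute_dccm <- function(traj, window = NULL, scheme = c("CA", "CB")) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  scheme <- match.arg(scheme)
  nodes <- trajectory_nodes(traj, scheme)
  FF <- nodes$n_frames
  if (is.null(window)) window <- default_window(FF)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] < 1L || window[2L] > FF ||
      window[2L] - window[1L] + 1L < 2L)
    stop("window must be a frame interval [start, end] within 1..", FF,
         " containing at least 2 frames")
  X <- nodes$xyz[window[1L]:window[2L], , drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X))
  N <- n_residues(nodes)
  num <- matrix(0, N, N)
  for (axis in 1:3) {
    cols <- 3L * seq_len(N) - 3L + axis
    num <- num + crossprod(Xc[, cols, drop = FALSE])
  }
  v <- diag(num)
  zero <- v <= .Machine$double.eps * nrow(X)
  if (any(zero))
    stop("zero fluctuation variance for residue(s) ",
         paste(residue_labels(nodes)[zero], collapse = ", "),
         ": cross-correlation undefined (division by zero)")
  C <- num / sqrt(tcrossprod(v))
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(residue_labels(nodes), residue_labels(nodes))
  structure(list(values = C, residues = nodes$residues, window = window,
                 scheme = scheme),
            class = "dccm_matrix")
}

default_window <- function(n_frames) {
  start <- min(floor(0.9 * n_frames) + 1L, n_frames - 1L)
  c(max(start, 1L), n_frames)
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat("dccm_matrix:", nrow(x$values), "residues, frames",
      x$window[1L], "-", x$window[2L], "(scheme", x$scheme, ")\n")
  invisible(x)
}

#' Classify correlated / anti-correlated regions relative to an anchor
#'
#' Residues are assigned to correlation tiers against the anchor residue's
#' row of the cross-correlation matrix: red (highest), orange, yellow for
#' positive correlation, an anti-correlated tier for strongly negative
#' values, and unclassified otherwise.  Contiguous runs are merged into
#' intervals; the anchor itself is reported in the top tier.  The tier
#' boundaries are configuration (the qualitative color scale of published
#' correlation maps carries no published numeric values) and are recorded in
#' the region set's provenance note.
#'
#' @param dccm a `dccm_matrix`.
#' @param anchor anchor residue: 1-based node index or `chain+resno` label.
#' @param thresholds increasing positive tier bounds, named
#'   `c(yellow=, orange=, red=)`.
#' @param anti_threshold negative bound; residues with correlation at or
#'   below it form the anti-correlated tier.
#' @return a `region_set` with tiers `red`, `orange`, `yellow`, `anti`.
#' @export
classify_regions <- function(dccm, anchor,
                             thresholds = c(yellow = 0.4, orange = 0.55,
                                            red = 0.7),
                             anti_threshold = -0.4) {
  stopifnot(inherits(dccm, "dccm_matrix"))
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0))
    stop("tiers not ordered: thresholds must be strictly increasing and ",
         "positive (yellow < orange < red)")
  if (anti_threshold >= 0) stop("anti_threshold must be negative")
  a <- resolve_residue(dccm, anchor)
  r <- dccm$values[a, ]
  tier <- rep(NA_character_, length(r))
  tier[r >= thresholds[1L]] <- "yellow"
  tier[r >= thresholds[2L]] <- "orange"
  tier[r >= thresholds[3L]] <- "red"
  tier[r <= anti_threshold] <- "anti"
  tier[a] <- "red"
  iv <- do.call(rbind, lapply(c("red", "orange", "yellow", "anti"),
                              function(tr)
                                runs_to_intervals(which(tier == tr), tr)))
  region_set(iv, length(r),
             note = sprintf(
               "anchor=%s method=dccm tiers=%.3g/%.3g/%.3g anti=%.3g",
               rownames(dccm$values)[a], thresholds[1L], thresholds[2L],
               thresholds[3L], anti_threshold))
}

resolve_residue <- function(obj, residue) {
  labs <- if (inherits(obj, "dccm_matrix")) rownames(obj$values) else
    obj$labels
  if (is.character(residue)) {
    i <- match(residue, labs)
    if (is.na(i)) stop("residue ", residue, " not present")
    return(i)
  }
  i <- as.integer(residue)
  if (i < 1L || i > length(labs)) stop("residue index ", i, " out of range")
  i
}
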