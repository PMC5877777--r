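## Betweenness-centrality and reachability profiling on the unweighted
## Cbeta contact network (7.0 A cutoff).
##
## Unlike the weighted pathway graph, edges here are defined purely by the
## distance cutoff and distances are hop counts.  Betweenness uses
## fractional (Brandes-style) counting over equal-length shortest paths of
## unordered node pairs with endpoints excluded, the convention of the
## standard network toolchains; the published verbal definition is
## count-based and silent on ties.

#' Build unweighted contact network(s) at a distance cutoff
#'
#' @param x a `pdb_structure` (one graph) or `pdb_trajectory` (one graph
#'   per frame).
#' @param cutoff contact cutoff in A (default 7.0).
#' @param scheme node scheme (default `"CB"`, Calpha for glycine).
#' @return a `contact_networks` object: list of igraph graphs sharing the
#'   residue node set.
#' @export
build_contact_network <- function(x, cutoff = 7.0, scheme = c("CB", "CA")) {
  scheme <- match.arg(scheme)
  stopifnot(cutoff > 0)
  if (inherits(x, "pdb_structure")) {
    coords <- list(node_coordinates(x, scheme))
    labels <- residue_labels(x)
  } else if (inherits(x, "pdb_trajectory")) {
    nodes <- trajectory_nodes(x, scheme)
    if (nodes$n_frames < 1L) stop("empty trajectory")
    coords <- lapply(seq_len(nodes$n_frames), function(f)
      matrix(nodes$xyz[f, ], ncol = 3L, byrow = TRUE))
    labels <- residue_labels(nodes)
  } else stop("x must be a pdb_structure or pdb_trajectory")
  graphs <- lapply(coords, function(m) {
    a <- as.matrix(stats::dist(m)) <= cutoff
    diag(a) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    igraph::set_vertex_attr(g, "name", value = labels)
  })
  structure(list(graphs = graphs, labels = labels, cutoff = cutoff),
            class = "contact_networks")
}

as_contact_networks <- function(graphs) {
  if (inherits(graphs, "contact_networks")) return(graphs)
  if (inherits(graphs, "igraph")) graphs <- list(graphs)
  stopifnot(is.list(graphs), length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1L), "igraph")))
  n <- igraph::vcount(graphs[[1L]])
  if (!all(vapply(graphs, igraph::vcount, numeric(1L)) == n))
    stop("graphs must share the same node set")
  labels <- igraph::V(graphs[[1L]])$name %||% as.character(seq_len(n))
  structure(list(graphs = graphs, labels = labels, cutoff = NA_real_),
            class = "contact_networks")
}

#' Betweenness centrality profile, averaged over frames
#'
#' BC(v) is the sum over unordered node pairs (s, t), s != v != t, of the
#' fraction of shortest s-t paths passing through v; the normalized variant
#' divides by (N-1)(N-2)/2, the number of pairs a node could intermediate.
#'
#' @param graphs a `contact_networks` object, an igraph graph or a list of
#'   them over a shared node set.
#' @return a `centrality_profile` with columns `residue`, `bc_raw`,
#'   `bc_norm`.
#' @export
betweenness_profile <- function(graphs) {
  cn <- as_contact_networks(graphs)
  n <- length(cn$labels)
  if (n < 3L) {
    warning("fewer than 3 nodes: betweenness is identically 0")
    bc <- rep(0, n)
  } else {
    per <- vapply(cn$graphs,
                  function(g) igraph::betweenness(g, directed = FALSE),
                  numeric(n))
    bc <- rowMeans(matrix(per, nrow = n))
  }
  norm <- if (n >= 3L) (n - 1) * (n - 2) / 2 else 1
  new_centrality_profile(
    data.frame(residue = cn$labels, bc_raw = bc, bc_norm = bc / norm,
               stringsAsFactors = FALSE),
    type = "betweenness", n_frames = length(cn$graphs))
}

#' Reachability (average shortest path length) profile
#'
#' L_i is the mean hop-count distance from residue i to every other
#' residue.  Pairs unreachable within a frame are excluded from the mean
#' (the denominator shrinks accordingly) and tallied in
#' `unreachable_pairs`; a residue isolated in every frame gets `L = NA`,
#' never a silent 0.
#'
#' @inheritParams betweenness_profile
#' @return a `centrality_profile` with columns `residue`, `L`,
#'   `unreachable_pairs`.
#' @export
reachability_profile <- function(graphs) {
  cn <- as_contact_networks(graphs)
  n <- length(cn$labels)
  sumL <- rep(0, n); cntL <- rep(0L, n); unreach <- rep(0L, n)
  for (g in cn$graphs) {
    d <- igraph::distances(g)
    for (i in seq_len(n)) {
      di <- d[i, -i]
      fin <- is.finite(di)
      unreach[i] <- unreach[i] + sum(!fin)
      if (any(fin)) {
        sumL[i] <- sumL[i] + mean(di[fin])
        cntL[i] <- cntL[i] + 1L
      }
    }
  }
  L <- ifelse(cntL > 0L, sumL / pmax(cntL, 1L), NA_real_)
  new_centrality_profile(
    data.frame(residue = cn$labels, L = L, unreachable_pairs = unreach,
               stringsAsFactors = FALSE),
    type = "reachability", n_frames = length(cn$graphs))
}

new_centrality_profile <- function(df, type, n_frames) {
  structure(list(profile = df, type = type, n_frames = n_frames),
            class = "centrality_profile")
}

#' @export
print.centrality_profile <- function(x, ...) {
  cat("centrality_profile (", x$type, "), ", nrow(x$profile),
      " residues averaged over ", x$n_frames, " frame(s)\n", sep = "")
  invisible(x)
}

metric_column <- function(profile) {
  switch(profile$type, betweenness = "bc_raw", reachability = "L",
         stop("unknown profile type"))
}

#' Per-residue change between two centrality profiles
#'
#' Delta = b - a per residue (b conventionally the mutant or later state),
#' e.g. the change in reachability that flags residues steering a
#' conformational change.
#'
#' @param profile_a,profile_b `centrality_profile` objects of the same type
#'   over the same node set.
#' @return a `centrality_profile` of type `delta_<type>` whose metric
#'   column holds the difference.
#' @export
delta_profile <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "centrality_profile"),
            inherits(profile_b, "centrality_profile"))
  if (profile_a$type != profile_b$type)
    stop("profiles are of different types")
  if (!identical(profile_a$profile$residue, profile_b$profile$residue))
    stop("profiles are over different node sets")
  col <- metric_column(profile_a)
  df <- data.frame(residue = profile_a$profile$residue,
                   stringsAsFactors = FALSE)
  df[[paste0("delta_", col)]] <-
    profile_b$profile[[col]] - profile_a$profile[[col]]
  p <- new_centrality_profile(df, paste0("delta_", profile_a$type),
                              n_frames = NA_integer_)
  p
}

#' Peak residues of a centrality profile
#'
#' Default criterion: local maxima of the profile whose z-score (against
#' the whole profile) is at least `z`; a flat profile yields no peaks.
#' `"topk"` returns the k largest values (ties broken by residue order).
#'
#' @param profile a `centrality_profile` (or a delta profile; the delta
#'   column is used).
#' @param criterion `"zscore"` (default) or `"topk"`.
#' @param z z-score threshold for `"zscore"` (default 2).
#' @param k number of residues for `"topk"`.
#' @return integer vector of residue node indices (named by residue label).
#' @export
peak_residues <- function(profile, criterion = c("zscore", "topk"),
                          z = 2, k = 4L) {
  stopifnot(inherits(profile, "centrality_profile"))
  criterion <- match.arg(criterion)
  cols <- setdiff(names(profile$profile), c("residue", "unreachable_pairs"))
  x <- profile$profile[[cols[1L]]]
  n <- length(x)
  if (n == 0L) stop("empty profile")
  if (criterion == "topk") {
    ord <- order(-x, seq_len(n))
    idx <- sort(ord[seq_len(min(k, n))])
  } else {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(integer())
    zs <- (x - mean(x)) / s
    left <- c(-Inf, x[-n]); right <- c(x[-1L], -Inf)
    idx <- which(zs >= z & x >= left & x >= right)
  }
  names(idx) <- profile$profile$residue[idx]
  idx
}

#' Write a pair of centrality profiles as one per-residue TSV
#'
#' @param bc betweenness profile.
#' @param reach reachability profile over the same nodes.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_centrality_tsv <- function(bc, reach, path) {
  stopifnot(identical(bc$profile$residue, reach$profile$residue))
  df <- cbind(bc$profile, reach$profile[, c("L", "unreachable_pairs")])
  write_tsv_file(df, path)
}
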