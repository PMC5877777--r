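## Correlation-weighted dynamic residue network and allosteric pathway
## search.
##
## Residues (Cbeta nodes, Calpha for glycine) are graph nodes; an edge is
## kept between two nodes only if their contact frequency over the
## trajectory is at least the pruning threshold (default 0.5 at a 5.7 A
## cutoff), so that dynamic coupling is carried by physical interactions.
## The edge weight is the cross-correlation C_ij; Dijkstra requires strictly
## positive costs, so the path cost is a transform of |C| (default
## -ln|C|: strong coupling, correlated or anti-correlated, makes a short
## edge).  The shortest path between a mutation site and a responding
## region is the candidate allosteric pathway.

new_residue_graph <- function(edges, n_nodes, labels = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("i", "j", "correlation", "cost", "contact_freq") %in%
                  names(edges)))
  if (nrow(edges)) {
    if (any(edges$i == edges$j)) stop("self-edges are not allowed")
    if (any(!is.finite(edges$cost)) || any(edges$cost <= 0))
      stop("path costs must be strictly positive and finite")
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, n_nodes = as.integer(n_nodes),
                 labels = labels %||% as.character(seq_len(n_nodes))),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("residue_graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

graph_is_connected <- function(graph) {
  if (graph$n_nodes <= 1L) return(TRUE)
  adj <- adjacency_list(graph)
  seen <- logical(graph$n_nodes)
  stack <- 1L; seen[1L] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (v in adj[[u]]$to) if (!seen[v]) { seen[v] <- TRUE; stack <- c(stack, v) }
  }
  all(seen)
}

adjacency_list <- function(graph) {
  adj <- lapply(seq_len(graph$n_nodes),
                function(i) list(to = integer(), w = numeric()))
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    i <- e$i[k]; j <- e$j[k]; w <- e$cost[k]
    adj[[i]]$to <- c(adj[[i]]$to, j); adj[[i]]$w <- c(adj[[i]]$w, w)
    adj[[j]]$to <- c(adj[[j]]$to, i); adj[[j]]$w <- c(adj[[j]]$w, w)
  }
  adj
}

#' Contact frequencies of residue node pairs over a trajectory
#'
#' The contact frequency f_ij is the fraction of frames in which the node
#' atoms of residues i and j lie within the distance cutoff; f_ii = 1.
#'
#' @param traj a `pdb_trajectory`.
#' @param cutoff contact distance cutoff in A (default 5.7).
#' @param scheme node scheme (default `"CB"`, Calpha for glycine).
#' @return an N x N symmetric frequency matrix in \[0, 1\].
#' @export
contact_frequencies <- function(traj, cutoff = 5.7, scheme = c("CB", "CA")) {
  stopifnot(inherits(traj, "pdb_trajectory"), cutoff > 0)
  scheme <- match.arg(scheme)
  nodes <- trajectory_nodes(traj, scheme)
  if (nodes$n_frames < 1L) stop("empty trajectory")
  N <- n_residues(nodes)
  counts <- matrix(0, N, N)
  for (f in seq_len(nodes$n_frames)) {
    m <- matrix(nodes$xyz[f, ], ncol = 3L, byrow = TRUE)
    counts <- counts + (as.matrix(stats::dist(m)) <= cutoff)
  }
  freq <- counts / nodes$n_frames
  diag(freq) <- 1
  dimnames(freq) <- list(residue_labels(nodes), residue_labels(nodes))
  freq
}

#' Build the contact-filtered, correlation-weighted residue graph
#'
#' An edge (i, j), i != j, is retained iff its contact frequency is at
#' least `freq_threshold` (the published rule removes frequencies strictly
#' below the threshold, so exactly-threshold contacts are kept).  The edge
#' carries the correlation weight E_ij = C_ij and a strictly positive path
#' cost derived from |C_ij| (|C| is floored at 1 - 1e-12 before the log so
#' perfectly correlated pairs keep a positive cost; pairs with C = 0 are
#' dropped, their cost being infinite).
#'
#' @param dccm a `dccm_matrix`.
#' @param freqs contact frequency matrix from [contact_frequencies()]
#'   (same residue index).
#' @param freq_threshold pruning threshold in \[0, 1\] (default 0.5).
#' @param transform cost rule: `"neglog"` (default, w = -ln|C|) or
#'   `"linear"` (w = 1 - |C|, floored at 1e-12).
#' @return a `residue_graph`.
#' @export
build_weighted_network <- function(dccm, freqs, freq_threshold = 0.5,
                                   transform = c("neglog", "linear")) {
  stopifnot(inherits(dccm, "dccm_matrix"))
  transform <- match.arg(transform)
  C <- dccm$values
  if (!all(dim(freqs) == dim(C)))
    stop("correlation and contact-frequency matrices differ in size")
  if (freq_threshold < 0 || freq_threshold > 1)
    stop("freq_threshold must be in [0, 1]")
  N <- nrow(C)
  keep <- upper.tri(C) & freqs >= freq_threshold & C != 0
  idx <- which(keep, arr.ind = TRUE)
  corr <- C[keep]
  a <- pmin(abs(corr), 1 - 1e-12)
  cost <- switch(transform, neglog = -log(a), linear = pmax(1 - a, 1e-12))
  edges <- data.frame(i = idx[, 1L], j = idx[, 2L], correlation = corr,
                      cost = cost, contact_freq = freqs[keep])
  g <- new_residue_graph(edges, N, labels = rownames(C))
  attr(g, "transform") <- transform
  attr(g, "freq_threshold") <- freq_threshold
  g
}

#' Deterministic shortest path between two residues
#'
#' Dijkstra's algorithm on the positive edge costs.  Ties in total cost are
#' broken by fewer hops, then by the lexicographically smallest residue
#' index sequence, so the reported pathway is reproducible.  An unreachable
#' target yields an explicit no-path result, not an error.
#'
#' @param graph a `residue_graph`.
#' @param source,target node indices or labels.
#' @return a `path_result`: list with `path` (node indices), `cost`,
#'   `edge_costs`, and `found`.
#' @export
shortest_path <- function(graph, source, target) {
  stopifnot(inherits(graph, "residue_graph"))
  s <- resolve_residue(graph, source)
  t <- resolve_residue(graph, target)
  if (s == t)
    return(new_path_result(s, 0, numeric(), TRUE, graph))
  adj <- adjacency_list(graph)
  ds <- dijkstra(adj, graph$n_nodes, s)
  if (!is.finite(ds$dist[t]))
    return(new_path_result(integer(), Inf, numeric(), FALSE, graph))
  dt <- dijkstra(adj, graph$n_nodes, t)
  total <- ds$dist[t]; total_hops <- ds$hops[t]
  tol <- 1e-9 * max(1, total)
  ## forward greedy reconstruction: among neighbors on a (cost, hops)
  ## optimal continuation, take the smallest node index
  path <- s; u <- s; acc <- 0; k <- 0L; ecosts <- numeric()
  while (u != t) {
    nb <- adj[[u]]
    ok <- which(abs(acc + nb$w + dt$dist[nb$to] - total) <= tol &
                  k + 1L + dt$hops[nb$to] == total_hops)
    v_ord <- ok[order(nb$to[ok])][1L]
    v <- nb$to[v_ord]
    acc <- acc + nb$w[v_ord]; k <- k + 1L
    ecosts <- c(ecosts, nb$w[v_ord])
    path <- c(path, v); u <- v
  }
  new_path_result(path, acc, ecosts, TRUE, graph)
}

## Dijkstra minimizing (cost, hops) lexicographically; O(n^2), ample for
## protein-sized graphs.
dijkstra <- function(adj, n, from) {
  dist <- rep(Inf, n); hops <- rep(Inf, n)
  dist[from] <- 0; hops[from] <- 0
  done <- logical(n)
  for (iter in seq_len(n)) {
    u <- NA_integer_; bd <- Inf; bh <- Inf
    for (v in which(!done)) {
      if (dist[v] < bd || (dist[v] == bd && hops[v] < bh)) {
        u <- v; bd <- dist[v]; bh <- hops[v]
      }
    }
    if (is.na(u) || !is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    for (k in seq_along(nb$to)) {
      v <- nb$to[k]; nd <- dist[u] + nb$w[k]
      tol <- 1e-12 * max(1, nd)
      if (nd < dist[v] - tol ||
          (abs(nd - dist[v]) <= tol && hops[u] + 1 < hops[v])) {
        dist[v] <- min(nd, dist[v]); hops[v] <- hops[u] + 1
      }
    }
  }
  list(dist = dist, hops = hops)
}

new_path_result <- function(path, cost, edge_costs, found, graph) {
  path <- as.integer(path)
  structure(list(path = path, cost = cost, edge_costs = edge_costs,
                 found = found,
                 labels = graph$labels[path]),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$found) {
    cat("path_result: no path\n")
  } else {
    cat("path_result:", paste(x$labels, collapse = " - "),
        sprintf("(cost %.5g, %d edges)\n", x$cost, length(x$edge_costs)))
  }
  invisible(x)
}

#' Allosteric pathways from a mutation site to a target region
#'
#' One deterministic shortest path per target residue, plus the
#' de-duplicated union of traversed edges (the bold-edge overlay used to
#' draw pathway figures).  Unreachable targets produce explicit no-path
#' entries and leave the union unchanged.
#'
#' @param graph a `residue_graph`.
#' @param site source residue (index or label).
#' @param targets a `region_set` of responding residues.
#' @return list with `paths` (named list of `path_result`), `edge_union`
#'   (data frame i, j), and `site`.
#' @export
allosteric_pathways <- function(graph, site, targets) {
  stopifnot(inherits(graph, "residue_graph"), inherits(targets, "region_set"))
  s <- resolve_residue(graph, site)
  tgt <- region_residues(targets)
  paths <- lapply(tgt, function(t) shortest_path(graph, s, t))
  names(paths) <- graph$labels[tgt]
  eu <- unique(do.call(rbind, lapply(paths, function(p) {
    if (!p$found || length(p$path) < 2L) return(NULL)
    data.frame(i = pmin(utils::head(p$path, -1L), p$path[-1L]),
               j = pmax(utils::head(p$path, -1L), p$path[-1L]))
  })))
  if (is.null(eu)) eu <- data.frame(i = integer(), j = integer())
  eu <- eu[order(eu$i, eu$j), , drop = FALSE]
  rownames(eu) <- NULL
  list(paths = paths, edge_union = eu, site = s)
}

#' Write a residue graph's edge list as TSV
#'
#' @param graph a `residue_graph`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edge_tsv <- function(graph, path) {
  e <- graph$edges
  df <- data.frame(res_i = graph$labels[e$i], res_j = graph$labels[e$j],
                   correlation = e$correlation, cost = e$cost,
                   contact_freq = e$contact_freq)
  write_tsv_file(df, path)
}
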