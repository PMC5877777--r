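# Independent oracles used across the suite.  Each re-derives the quantity
# it checks by a different route than the implementation: direct two-pass
# summation for the cross-correlation, exhaustive simple-path enumeration
# for Dijkstra, BFS path counting plus the pair-dependency formula for
# betweenness, and a state-by-state Boltzmann loop for the ensemble model.

# -- cross-correlation: naive two-pass direct summation over frames --------
naive_dccm <- function(X) {
  FF <- nrow(X)
  N <- ncol(X) / 3L
  dev <- lapply(seq_len(N), function(i) {
    m <- X[, (3L * i - 2L):(3L * i), drop = FALSE]
    sweep(m, 2L, colMeans(m))
  })
  C <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in i:N) {
      num <- sum(dev[[i]] * dev[[j]]) / FF
      den <- sqrt(sum(dev[[i]]^2) / FF) * sqrt(sum(dev[[j]]^2) / FF)
      C[i, j] <- C[j, i] <- num / den
    }
  }
  C
}

# trajectory node coordinate matrix (F x 3N) for a scheme
node_xyz <- function(traj, scheme = "CA") trajectory_nodes(traj, scheme)$xyz

# -- exhaustive simple-path search with (cost, hops, lex) ordering ---------
brute_best_path <- function(graph, s, t) {
  n <- graph$n_nodes
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]; w <- graph$edges$cost[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- list(cost = Inf, path = NULL)
  path_less <- function(c1, p1, c2, p2) {
    tol <- 1e-9 * max(1, c2)
    if (c1 < c2 - tol) return(TRUE)
    if (c1 > c2 + tol) return(FALSE)
    if (length(p1) != length(p2)) return(length(p1) < length(p2))
    d <- which(p1 != p2)
    length(d) > 0L && p1[d[1L]] < p2[d[1L]]
  }
  visited <- logical(n)
  dfs <- function(u, cost, path) {
    if (cost > best$cost + 1e-9 * max(1, best$cost)) return()
    if (u == t) {
      if (is.null(best$path) || path_less(cost, path, best$cost, best$path))
        best <<- list(cost = cost, path = path)
      return()
    }
    nb <- adj[[u]]
    if (is.null(nb)) return()
    for (r in order(nb[, 1L])) {
      v <- nb[r, 1L]
      if (!visited[v]) {
        visited[v] <<- TRUE
        dfs(v, cost + nb[r, 2L], c(path, v))
        visited[v] <<- FALSE
      }
    }
  }
  visited[s] <- TRUE
  dfs(s, 0, s)
  best
}

# -- betweenness / reachability via BFS counting + pair dependency ---------
bfs_count <- function(adjm, s) {
  n <- nrow(adjm)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in which(adjm[u, ] > 0)) {
        if (!is.finite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

brute_centrality <- function(adjm) {
  n <- nrow(adjm)
  bfs <- lapply(seq_len(n), bfs_count, adjm = adjm)
  d <- t(vapply(bfs, `[[`, numeric(n), "dist"))
  sig <- t(vapply(bfs, `[[`, numeric(n), "sigma"))
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        if (v == s || v == t || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t])
          bc[v] <- bc[v] + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
  }
  L <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    if (!any(is.finite(di))) NA_real_ else mean(di[is.finite(di)])
  }, numeric(1L))
  list(bc = bc, L = L, dist = d)
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p)
  a + t(a)
}

# -- ensemble model: state-by-state Boltzmann summation --------------------
brute_eam <- function(g, RT) {
  U <- length(g)
  wf <- numeric(U)   # summed weight, unit folded
  wu <- numeric(U)   # summed weight, unit unfolded
  Z <- 0
  for (s in 0:(2L^U - 1L)) {
    bits <- bitwAnd(s, bitwShiftL(1L, 0:(U - 1L))) != 0L
    G <- sum(g[bits])
    w <- exp(-G / RT)
    Z <- Z + w
    wf[!bits] <- wf[!bits] + w
    wu[bits] <- wu[bits] + w
  }
  kappa <- wf / wu
  list(kappa = kappa, dG = -RT * log(kappa), Z = Z)
}

# small hand-built graph constructor for path tests
edge_graph <- function(i, j, cost, n = max(c(i, j))) {
  allonet:::new_residue_graph(
    data.frame(i = i, j = j, correlation = NA_real_, cost = cost,
               contact_freq = NA_real_), n)
}

# hand-built structure: residues on given CB coordinates (CA displaced 1.5 A)
point_structure <- function(cb, resid = NULL) {
  n <- nrow(cb)
  if (is.null(resid)) resid <- rep("ALA", n)
  atom <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (resid[i] == "GLY") {
      data.frame(chain = "A", resno = i, resid = resid[i], elety = "CA",
                 x = cb[i, 1L], y = cb[i, 2L], z = cb[i, 3L])
    } else {
      data.frame(chain = "A", resno = i, resid = resid[i],
                 elety = c("CA", "CB"),
                 x = c(cb[i, 1L] + 1.5, cb[i, 1L]),
                 y = cb[i, 2L], z = cb[i, 3L])
    }
  }))
  allonet:::new_structure(atom)
}

# trajectory from an explicit list of per-frame node coordinate matrices
frames_trajectory <- function(frames, resid = NULL) {
  s <- point_structure(frames[[1L]], resid)
  xyz <- do.call(rbind, lapply(frames, function(m) {
    full <- s$atom
    key <- match(paste(full$chain, full$resno),
                 paste(s$residues$chain, s$residues$resno))
    shift <- m[key, , drop = FALSE] - frames[[1L]][key, , drop = FALSE]
    as.vector(t(as.matrix(full[, c("x", "y", "z")]) + shift))
  }))
  allonet:::new_trajectory(xyz, s$atom[, c("chain", "resno", "resid",
                                           "elety")])
}
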