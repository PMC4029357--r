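# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the functions (and library calls) they verify.

# Two-way median polish by plain iterative row/column median sweeps.
oracle_median_polish <- function(x, eps = 1e-6, maxiter = 10) {
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  resid <- x
  old_sum <- Inf
  for (it in seq_len(maxiter)) {
    rm_ <- apply(resid, 1, median)
    resid <- resid - rm_
    row_eff <- row_eff + rm_
    delta <- median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cm_ <- apply(resid, 2, median)
    resid <- sweep(resid, 2, cm_)
    col_eff <- col_eff + cm_
    delta <- median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    new_sum <- sum(abs(resid))
    converged <- new_sum == 0 || abs(new_sum - old_sum) < eps * new_sum
    old_sum <- new_sum
    if (converged) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = resid)
}

# Exhaustive betweenness centrality on a small undirected graph given as an
# edge list of vertex names: count all shortest paths between every vertex
# pair by breadth-first layering and accumulate pass-through fractions.
oracle_betweenness <- function(vertices, edge_a, edge_b) {
  n <- length(vertices)
  adj <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  for (k in seq_along(edge_a)) {
    adj[edge_a[k], edge_b[k]] <- TRUE
    adj[edge_b[k], edge_a[k]] <- TRUE
  }
  all_shortest_paths <- function(s, t) {
    # BFS distances from s
    dist <- rep(Inf, n); names(dist) <- vertices
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        nb <- vertices[adj[v, ]]
        newly <- nb[dist[nb] == Inf]
        dist[newly] <- dist[v] + 1
        nxt <- c(nxt, newly)
      }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    # enumerate paths by walking backwards along decreasing distance
    grow <- function(path) {
      head_v <- path[1]
      if (head_v == s) return(list(path))
      prevs <- vertices[adj[head_v, ] & dist == dist[head_v] - 1]
      unlist(lapply(prevs, function(p) grow(c(p, path))), recursive = FALSE)
    }
    grow(t)
  }
  btw <- setNames(numeric(n), vertices)
  pairs <- utils::combn(vertices, 2)
  for (k in seq_len(ncol(pairs))) {
    paths <- all_shortest_paths(pairs[1, k], pairs[2, k])
    if (!length(paths)) next
    through <- table(unlist(lapply(paths, function(p) p[-c(1, length(p))])))
    btw[names(through)] <- btw[names(through)] + as.numeric(through) / length(paths)
  }
  btw
}

# Single-pass average-linkage agglomeration: repeatedly merge the two
# clusters with the smallest mean pairwise distance until that minimum
# exceeds the cut height; returns the membership partition.
oracle_average_agglomeration <- function(D, height) {
  drugs <- rownames(D)
  clusters <- as.list(drugs)
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > height) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  part <- setNames(rep(NA_integer_, length(drugs)), drugs)
  for (k in seq_along(clusters)) part[clusters[[k]]] <- k
  part
}

# Chance-corrected partition agreement.
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
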