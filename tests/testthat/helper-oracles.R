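# Independent brute-force oracles for the graph-metric suite. These work
# from the dense adjacency matrix with straightforward (slow) algorithms,
# deliberately sharing no code with the package implementations.

adjmat <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  i <- match(g$edges$drug_a, g$nodes)
  j <- match(g$edges$drug_b, g$nodes)
  A[cbind(i, j)] <- 1L
  A[cbind(j, i)] <- 1L
  A
}

random_ddi_graph <- function(n, p, retain_isolated = TRUE) {
  nodes <- sprintf("drug%03d", seq_len(n))
  cmb <- utils::combn(n, 2)
  keep <- stats::runif(ncol(cmb)) < p
  edges <- data.frame(drug_a = nodes[cmb[1, keep]],
                      drug_b = nodes[cmb[2, keep]],
                      severity = sample(severity_levels(), sum(keep),
                                        replace = TRUE),
                      stringsAsFactors = FALSE)
  graph_from_edges(edges, nodes = if (retain_isolated) nodes)
}

# BFS hop distances from s (-1 = unreachable) plus shortest-path counts,
# computed layer by layer from the distance array (no predecessor lists).
oracle_bfs <- function(A, s) {
  n <- nrow(A)
  dist <- rep(-1L, n)
  dist[s] <- 0L
  frontier <- s
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & dist < 0L)
    dist[nxt] <- d
    frontier <- nxt
  }
  sigma <- numeric(n)
  sigma[s] <- 1
  for (layer in seq_len(max(dist))) {
    for (v in which(dist == layer)) {
      sigma[v] <- sum(sigma[which(A[, v] > 0 & dist == layer - 1L)])
    }
  }
  list(dist = dist, sigma = sigma)
}

oracle_dist_sigma <- function(A) {
  n <- nrow(A)
  D <- matrix(-1L, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- oracle_bfs(A, s)
    D[s, ] <- b$dist
    S[s, ] <- b$sigma
  }
  list(D = D, S = S)
}

# Pair-dependency betweenness: for every unordered pair (s,t) count, for
# every intermediate v, the fraction of s-t shortest paths through v.
oracle_betweenness <- function(A, normalized = TRUE) {
  n <- nrow(A)
  ds <- oracle_dist_sigma(A)
  D <- ds$D; S <- ds$S
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (D[s, t] < 0L) next
      v <- setdiff(which(D[s, ] >= 0L & D[t, ] >= 0L &
                           D[s, ] + D[t, ] == D[s, t]), c(s, t))
      bc[v] <- bc[v] + S[s, v] * S[t, v] / S[s, t]
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- oracle_dist_sigma(A)$D
  vapply(seq_len(n), function(v) {
    reach <- D[v, ] >= 0L
    k <- sum(reach)
    sumd <- sum(D[v, reach])
    if (k > 1 && sumd > 0) ((k - 1) / sumd) * ((k - 1) / (n - 1)) else 0
  }, numeric(1))
}

# Dominant eigenvector per connected component via dense symmetric
# eigendecomposition, non-negative, unit Euclidean norm per component.
oracle_eigenvector <- function(A) {
  n <- nrow(A)
  comp <- oracle_components(A)
  x <- numeric(n)
  for (cid in unique(comp)) {
    m <- which(comp == cid)
    if (length(m) < 2) next
    e <- eigen(A[m, m, drop = FALSE], symmetric = TRUE)
    v <- e$vectors[, which.max(e$values)]
    x[m] <- abs(v) / sqrt(sum(v^2))
  }
  x
}

# Explicit neighbor-pair loop.
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    tri <- 0L
    for (a in seq_len(d - 1)) {
      for (b in seq(a + 1, d)) {
        if (A[nb[a], nb[b]] > 0) tri <- tri + 1L
      }
    }
    2 * tri / (d * (d - 1))
  }, numeric(1))
}

# Union-find component labels (renumbered in first-seen order).
oracle_components <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in which(A[i, ] > 0)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
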