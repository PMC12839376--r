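# From-scratch graph metrics on the unweighted drug-interaction graph:
# degree, Brandes betweenness, component-scaled closeness, power-iteration
# eigenvector centrality, local/average clustering, connected components
# and density. All distances are hop counts; severity weights are stored
# edge attributes and do not enter the default centralities.

#' Network density
#'
#' Proportion of realized edges, `2m / (n (n - 1))`. Graphs with fewer than
#' two nodes have density 0 by convention.
#'
#' @param g A `ddi_graph`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "ddi_graph"))
  n <- length(g$nodes)
  if (n < 2) return(0)
  2 * nrow(g$edges) / (n * (n - 1))
}

#' Per-node degree and summary
#'
#' @param g A `ddi_graph`.
#' @return Data frame `drug`, `degree`, `degree_centrality`
#'   (degree / (n - 1)), in node order; summary attributes `min`, `max`,
#'   `mean` are attached as `attr(, "summary")`.
#' @export
degree_metrics <- function(g) {
  stopifnot(inherits(g, "ddi_graph"))
  deg <- node_degrees(g)
  n <- length(g$nodes)
  out <- data.frame(drug = g$nodes, degree = deg,
                    degree_centrality = if (n > 1) deg / (n - 1) else
                      rep(0, n),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(min = if (n) min(deg) else NA,
                            max = if (n) max(deg) else NA,
                            mean = if (n) mean(deg) else NA)
  out
}

# Single-source BFS returning hop distances (-1 unreached), shortest-path
# counts sigma, predecessor lists and the visit order. Shared by
# betweenness and closeness.
bfs_paths <- function(adj, s, n) {
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  pred <- vector("list", n)
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- integer(n)
  queue[1] <- s
  head <- 1L; tail <- 1L
  order <- integer(0)
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    order <- c(order, v)
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        pred[[w]] <- c(pred[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, pred = pred, order = order)
}

#' Betweenness centrality (Brandes)
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node, on unweighted (hop-count) shortest paths, endpoints excluded.
#' Normalization divides by `(n - 1)(n - 2) / 2`, the number of ordered
#' pairs not involving the node, halved for an undirected graph.
#'
#' @param g A `ddi_graph`.
#' @param normalized Divide by `(n - 1)(n - 2) / 2` (default `TRUE`).
#' @return Named numeric vector over `g$nodes`.
#' @export
betweenness_centrality <- function(g, normalized = TRUE) {
  stopifnot(inherits(g, "ddi_graph"))
  n <- length(g$nodes)
  bc <- numeric(n)
  if (n >= 3 && nrow(g$edges) > 0) {
    adj <- adjacency_list(g)
    for (s in seq_len(n)) {
      b <- bfs_paths(adj, s, n)
      delta <- numeric(n)
      for (v in rev(b$order)) {
        for (p in b$pred[[v]]) {
          delta[p] <- delta[p] + b$sigma[p] / b$sigma[v] * (1 + delta[v])
        }
        if (v != s) bc[v] <- bc[v] + delta[v]
      }
    }
    bc <- bc / 2  # each undirected pair visited from both endpoints
    if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(bc, g$nodes)
}

#' Closeness centrality (component-scaled)
#'
#' For a node `v` whose connected component has `k` nodes, within a graph of
#' `n` nodes: `((k - 1) / sum(d)) * ((k - 1) / (n - 1))`, where `sum(d)` is
#' the total hop distance from `v` to its reachable nodes. On a connected
#' graph this reduces to the familiar `(n - 1) / sum(d)`; isolated nodes
#' score 0.
#'
#' @param g A `ddi_graph`.
#' @return Named numeric vector over `g$nodes`.
#' @export
closeness_centrality <- function(g) {
  stopifnot(inherits(g, "ddi_graph"))
  n <- length(g$nodes)
  cc <- numeric(n)
  if (n >= 2) {
    adj <- adjacency_list(g)
    for (v in seq_len(n)) {
      d <- bfs_paths(adj, v, n)$dist
      reach <- d >= 0L
      k <- sum(reach)
      sumd <- sum(d[reach])
      if (k > 1 && sumd > 0) {
        cc[v] <- ((k - 1) / sumd) * ((k - 1) / (n - 1))
      }
    }
  }
  stats::setNames(cc, g$nodes)
}

#' Eigenvector centrality by power iteration
#'
#' Dominant eigenvector of the unweighted adjacency matrix, computed by
#' power iteration on `A + I` (the identity shift guarantees convergence on
#' bipartite components without changing the dominant eigenvector). The
#' result is non-negative and normalized to unit Euclidean norm per
#' connected component; disconnected graphs are handled per component with
#' a warning that cross-component values are not comparable. Components of
#' size 1 score 0.
#'
#' @param g A `ddi_graph` with at least one edge.
#' @param max_iter Maximum iterations (default 1000).
#' @param tol Convergence tolerance: iteration stops when the L1 change
#'   between successive iterates falls below `n * tol` (default 1e-6).
#' @return Named numeric vector over `g$nodes`.
#' @export
eigenvector_centrality <- function(g, max_iter = 1000, tol = 1e-6) {
  stopifnot(inherits(g, "ddi_graph"))
  if (nrow(g$edges) == 0) {
    stop("eigenvector centrality requires a graph with at least one edge",
         call. = FALSE)
  }
  n <- length(g$nodes)
  adj <- adjacency_list(g)
  comp <- graph_components(g)
  if (comp$n_components > 1) {
    warning("graph is disconnected: eigenvector centrality computed per ",
            "component; values are not comparable across components",
            call. = FALSE)
  }
  x <- numeric(n)
  for (members in comp$members) {
    if (length(members) < 2) next
    local <- match(members, g$nodes)
    pos <- match(seq_len(n), local)  # node index -> position in component
    nc <- length(local)
    xc <- rep(1 / nc, nc)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      xlast <- xc
      xc <- xlast  # A + I shift
      for (a in seq_len(nc)) {
        v <- local[a]
        for (w in adj[[v]]) xc[pos[w]] <- xc[pos[w]] + xlast[a]
      }
      xc <- xc / sqrt(sum(xc^2))
      if (sum(abs(xc - xlast)) < nc * tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      stop("eigenvector centrality failed to converge in ", max_iter,
           " iterations on a component of ", nc, " node(s)", call. = FALSE)
    }
    x[local] <- abs(xc)
  }
  stats::setNames(x, g$nodes)
}

#' Local clustering coefficients and their average
#'
#' For each node, the fraction of its neighbor pairs that are themselves
#' connected: `2 T(v) / (deg(v) (deg(v) - 1))`, 0 for degree < 2. The
#' average is taken over all nodes.
#'
#' @param g A `ddi_graph`.
#' @return Named numeric vector over `g$nodes`; the graph-level mean is
#'   attached as `attr(, "average")`.
#' @export
clustering_coefficients <- function(g) {
  stopifnot(inherits(g, "ddi_graph"))
  n <- length(g$nodes)
  cl <- numeric(n)
  if (n > 0 && nrow(g$edges) > 0) {
    adj <- adjacency_list(g)
    A <- matrix(FALSE, n, n)
    i <- match(g$edges$drug_a, g$nodes)
    j <- match(g$edges$drug_b, g$nodes)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
    for (v in seq_len(n)) {
      nb <- adj[[v]]
      d <- length(nb)
      if (d >= 2) cl[v] <- sum(A[nb, nb]) / (d * (d - 1))
    }
  }
  out <- stats::setNames(cl, g$nodes)
  attr(out, "average") <- if (n > 0) mean(cl) else NA_real_
  out
}

#' Connected components
#'
#' BFS partition of the node set, components ordered by size descending
#' (ties by smallest member name).
#'
#' @param g A `ddi_graph`.
#' @return List with `n_components`, `sizes` (descending), `membership`
#'   (named integer vector, component id per node) and `members` (list of
#'   node-name vectors).
#' @export
graph_components <- function(g) {
  stopifnot(inherits(g, "ddi_graph"))
  n <- length(g$nodes)
  adj <- adjacency_list(g)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  members <- split(g$nodes, comp)
  ord <- order(-lengths(members), vapply(members, min, character(1)))
  members <- members[ord]
  relabel <- match(seq_along(members), ord)
  membership <- stats::setNames(relabel[comp], g$nodes)
  list(n_components = length(members),
       sizes = unname(lengths(members)),
       membership = membership,
       members = unname(members))
}

#' Per-node metric table
#'
#' Assembles degree, normalized degree centrality, betweenness, closeness,
#' eigenvector centrality and local clustering for every drug, ranked by
#' degree descending with lexicographic tie-break.
#'
#' @param g A `ddi_graph` with at least one edge.
#' @param max_iter,tol Passed to [eigenvector_centrality()].
#' @return Data frame, one row per node.
#' @export
node_metrics <- function(g, max_iter = 1000, tol = 1e-6) {
  stopifnot(inherits(g, "ddi_graph"))
  dm <- degree_metrics(g)
  cl <- clustering_coefficients(g)
  out <- data.frame(
    drug = g$nodes,
    degree = dm$degree,
    degree_centrality = dm$degree_centrality,
    betweenness = unname(betweenness_centrality(g)),
    closeness = unname(closeness_centrality(g)),
    eigenvector = if (nrow(g$edges) > 0)
      unname(eigenvector_centrality(g, max_iter, tol)) else
      rep(0, length(g$nodes)),
    clustering = unname(cl),
    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Graph-level metric summary
#'
#' @param g A `ddi_graph`.
#' @return List with `n_nodes`, `n_edges`, `density`, `avg_degree`
#'   (`2m / n`), `degree_min`, `degree_max`, `avg_clustering`,
#'   `n_components`, `component_sizes`.
#' @export
graph_metrics <- function(g) {
  stopifnot(inherits(g, "ddi_graph"))
  n <- length(g$nodes)
  m <- nrow(g$edges)
  deg <- node_degrees(g)
  comp <- graph_components(g)
  list(n_nodes = n,
       n_edges = m,
       density = graph_density(g),
       avg_degree = if (n > 0) 2 * m / n else NA_real_,
       degree_min = if (n > 0) min(deg) else NA_integer_,
       degree_max = if (n > 0) max(deg) else NA_integer_,
       avg_clustering = attr(clustering_coefficients(g), "average"),
       n_components = comp$n_components,
       component_sizes = comp$sizes)
}
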