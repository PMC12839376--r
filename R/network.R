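# Cohort-aggregated, severity-weighted, undirected drug-interaction graph.
# One edge per distinct interacting pair observed in >= 1 patient; the edge
# carries the KB severity, the number of patients exhibiting the pair
# (occurrence_count) and the summed severity weight
# (occurrence_count * severity weight).

new_ddi_graph <- function(nodes, edges) {
  edges <- edges[order(edges$drug_a, edges$drug_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(nodes)), edges = edges),
            class = "ddi_graph")
}

#' Build the drug-interaction network from profiled patients
#'
#' Aggregates the long-format interaction table over patients: each distinct
#' canonical pair becomes one undirected edge whose weight is the sum of its
#' severity weights across patients. By default the node set is the drugs
#' appearing in at least one interaction; pass `nodes` to retain additional
#' (isolated) drugs, e.g. the full prescribed formulary.
#'
#' @param profiles A `ddi_profiles` object (or a long-format interaction
#'   data frame with columns `patient_id`, `drug_a`, `drug_b`, `severity`).
#' @param nodes Optional character vector of node names to retain even if
#'   isolated.
#' @return Object of class `ddi_graph` with elements `nodes` (sorted
#'   character) and `edges` (data frame `drug_a`, `drug_b`, `severity`,
#'   `occurrence_count`, `summed_weight`).
#' @export
build_network <- function(profiles, nodes = NULL) {
  inter <- if (inherits(profiles, "ddi_profiles")) profiles$interactions
           else profiles
  pairs <- pair_frequency_table(inter)
  edges <- data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
                      severity = pairs$severity,
                      occurrence_count = pairs$count,
                      summed_weight = pairs$count *
                        severity_weight(pairs$severity),
                      stringsAsFactors = FALSE)
  all_nodes <- unique(c(edges$drug_a, edges$drug_b,
                        if (!is.null(nodes)) canonicalize_drug(nodes)))
  g <- new_ddi_graph(all_nodes, edges)
  message("built network: ", length(g$nodes), " node(s), ",
          nrow(g$edges), " edge(s)")
  g
}

#' Construct a drug graph directly from an edge table
#'
#' Convenience constructor (used heavily in testing and for desk
#' calculations on published node/edge counts). Pairs are canonicalized and
#' de-duplicated; a duplicate pair is an error.
#'
#' @param edges Data frame with columns `drug_a`, `drug_b` and optionally
#'   `severity` (default `"moderate"`) and `occurrence_count` (default 1).
#' @param nodes Optional additional isolated nodes.
#' @return A `ddi_graph` object.
#' @export
graph_from_edges <- function(edges, nodes = NULL) {
  if (nrow(edges) == 0) {
    e <- data.frame(drug_a = character(0), drug_b = character(0),
                    severity = character(0), occurrence_count = integer(0),
                    summed_weight = numeric(0))
    return(new_ddi_graph(if (is.null(nodes)) character(0)
                         else canonicalize_drug(nodes), e))
  }
  a <- canonicalize_drug(edges$drug_a)
  b <- canonicalize_drug(edges$drug_b)
  if (any(a == b)) stop("self-loop in edge table", call. = FALSE)
  op <- order_pair(a, b)
  if (anyDuplicated(pair_key(op$drug_a, op$drug_b))) {
    stop("duplicate edge in edge table", call. = FALSE)
  }
  sev <- if ("severity" %in% names(edges)) {
    tolower(trimws(edges$severity))
  } else rep("moderate", nrow(edges))
  occ <- if ("occurrence_count" %in% names(edges)) {
    as.integer(edges$occurrence_count)
  } else rep(1L, nrow(edges))
  stopifnot(all(occ >= 1))
  e <- data.frame(drug_a = op$drug_a, drug_b = op$drug_b, severity = sev,
                  occurrence_count = occ,
                  summed_weight = occ * severity_weight(sev),
                  stringsAsFactors = FALSE)
  new_ddi_graph(c(op$drug_a, op$drug_b,
                  if (!is.null(nodes)) canonicalize_drug(nodes)), e)
}

#' Induced subgraph on the k highest-degree drugs
#'
#' Selects the `k` nodes of highest raw degree (ties broken
#' lexicographically by drug name) and keeps every edge joining two selected
#' nodes.
#'
#' @param g A `ddi_graph`.
#' @param k Number of nodes to keep (>= 1). If `k` exceeds the node count
#'   the whole graph is returned with a warning.
#' @return A `ddi_graph` on the selected nodes.
#' @export
top_k_subgraph <- function(g, k) {
  stopifnot(inherits(g, "ddi_graph"), k >= 1)
  n <- length(g$nodes)
  if (k > n) {
    warning("k = ", k, " exceeds node count ", n, "; returning whole graph",
            call. = FALSE)
    return(g)
  }
  deg <- node_degrees(g)
  keep <- g$nodes[order(-deg, g$nodes)][seq_len(k)]
  e <- g$edges[g$edges$drug_a %in% keep & g$edges$drug_b %in% keep, ,
               drop = FALSE]
  new_ddi_graph(keep, e)
}

# Raw degree per node, in g$nodes order.
node_degrees <- function(g) {
  deg <- table(factor(c(g$edges$drug_a, g$edges$drug_b), levels = g$nodes))
  as.integer(deg)
}

# Adjacency as a list of sorted integer neighbor vectors (node index into
# g$nodes); isolated nodes get integer(0).
adjacency_list <- function(g) {
  n <- length(g$nodes)
  i <- match(g$edges$drug_a, g$nodes)
  j <- match(g$edges$drug_b, g$nodes)
  adj <- split(c(j, i), factor(c(i, j), levels = seq_len(n)))
  lapply(adj, function(v) sort(as.integer(v)))
}

#' Write the network edge list as TSV
#'
#' Columns `drug_a`, `drug_b`, `severity`, `occurrence_count`,
#' `summed_weight`; lossless with respect to the graph's edge data.
#'
#' @param g A `ddi_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "ddi_graph"))
  utils::write.table(g$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export the network as GraphML
#'
#' Writes nodes and edges with `severity`, `occurrence_count` and
#' `summed_weight` edge attributes, readable by standard graph tooling.
#'
#' @param g A `ddi_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "ddi_graph"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(c("d_sev", "edge", "severity", "string"),
               c("d_occ", "edge", "occurrence_count", "int"),
               c("d_wt", "edge", "summed_weight", "double"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "ddi",
                               edgedefault = "undirected")
  for (v in g$nodes) xml2::xml_add_child(graph, "node", id = v)
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    edge <- xml2::xml_add_child(graph, "edge",
                                source = e$drug_a[i], target = e$drug_b[i])
    xml2::xml_add_child(edge, "data", e$severity[i], key = "d_sev")
    xml2::xml_add_child(edge, "data", as.character(e$occurrence_count[i]),
                        key = "d_occ")
    xml2::xml_add_child(edge, "data",
                        format(e$summed_weight[i], digits = 15),
                        key = "d_wt")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @export
print.ddi_graph <- function(x, ...) {
  cat("<ddi_graph> ", length(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s), density ", sprintf("%.3f", graph_density(x)), "\n", sep = "")
  invisible(x)
}
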