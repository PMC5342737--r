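# High-stringency interaction graph construction and Markov clustering.
# The MCL iteration (expansion/inflation of a column-stochastic matrix) is
# implemented here directly; graph bookkeeping (components, adjacency)
# uses igraph.

#' Build a high-stringency interaction graph over a gene list
#'
#' Keeps edges whose weight is strictly above `stringency` (default 0.9)
#' and whose endpoints both belong to `gene_set`. Nodes are the members
#' with at least one surviving edge; isolated members are added, flagged,
#' only when `include_isolated = TRUE`.
#'
#' @param edges Edge-list data frame (`node_a`, `node_b`, `weight`).
#' @param gene_set Gene ids defining the node universe.
#' @param stringency Strict lower weight bound for an interaction.
#' @param include_isolated Keep gene-set members with no surviving edge.
#' @return List of class `interaction_graph`: `graph` (igraph), `nodes`,
#'   `edges` (surviving edge-list rows), `isolated`, `stringency`.
#' @export
build_graph <- function(edges, gene_set, stringency = 0.9,
                        include_isolated = FALSE) {
  if (!length(gene_set)) abort("gene_set must be non-empty")
  gene_set <- unique(gene_set)
  keep <- edges$weight > stringency &
    edges$node_a %in% gene_set & edges$node_b %in% gene_set
  kept <- edges[keep, , drop = FALSE]
  connected <- unique(c(kept$node_a, kept$node_b))
  isolated <- if (include_isolated) setdiff(gene_set, connected) else character()
  nodes <- sort(c(connected, isolated))
  g <- igraph::graph_from_data_frame(kept, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, nodes = nodes, edges = kept,
                 isolated = isolated, stringency = stringency),
            class = "interaction_graph")
}

#' Markov clustering (MCL) of an interaction graph
#'
#' Adds a self-loop to each node at its maximum incident edge weight,
#' column-normalizes the weighted adjacency into a transition matrix, and
#' alternates expansion (matrix power) with inflation (entrywise power and
#' re-normalization), pruning entries below `prune`, until the largest
#' entry change falls under `tol` or `max_iter` is reached. Attractor rows
#' of the limit matrix define the clusters; a node attracted by several
#' attractors goes to the largest cluster (ties to the lexicographically
#' smallest attractor id). The iteration involves no randomness, so the
#' partition is identical across runs.
#'
#' @param graph An [build_graph()] result (or igraph object).
#' @param inflation Inflation exponent (default 2).
#' @param expansion Expansion power (default 2).
#' @param prune Entries below this are zeroed each iteration.
#' @param tol Convergence tolerance on the max entry change.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   partition with `converged = FALSE` and a warning.
#' @return List: `clusters` (named list of node-id vectors, names =
#'   attractor ids), `membership` (named vector node -> cluster index),
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2,
                        prune = 1e-5, tol = 1e-6, max_iter = 200) {
  g <- if (inherits(graph, "interaction_graph")) graph$graph else graph
  n <- igraph::vcount(g)
  if (n == 0L) abort("graph is empty")
  ids <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g))
    "weight" else NULL, sparse = TRUE))
  A <- matrix(as.numeric(A), n, n, dimnames = list(ids, ids))
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1                    # isolated node: unit self-loop
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), `/`)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Mnew <- sweep(Minf, 2, cs, `/`)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("MCL did not converge in %d iterations; returning current partition",
          max_iter)

  eps <- prune
  attractors <- ids[diag(M) > eps]
  if (!length(attractors)) attractors <- ids[apply(M, 2, which.max)]
  raw <- lapply(attractors, function(a) ids[M[a, ] > eps])
  names(raw) <- attractors

  # resolve overlaps: largest cluster wins, ties to smallest attractor id
  sizes <- lengths(raw)
  ord <- order(-sizes, names(raw))
  assignment <- setNames(rep(NA_character_, n), ids)
  for (a in names(raw)[ord]) {
    take <- raw[[a]][is.na(assignment[raw[[a]]])]
    assignment[take] <- a
  }
  orphan <- names(assignment)[is.na(assignment)]
  assignment[orphan] <- orphan            # unattracted nodes: singletons
  clusters <- split(names(assignment), assignment)
  clusters <- clusters[order(-lengths(clusters), names(clusters))]
  membership <- setNames(integer(n), ids)
  for (i in seq_along(clusters)) membership[clusters[[i]]] <- i
  list(clusters = clusters, membership = membership,
       converged = converged, iterations = iter)
}

#' Summarize an interaction graph and its clustering
#'
#' @param graph An `interaction_graph`.
#' @param clusters Optional [mcl_cluster()] result.
#' @return List: `n_nodes`, `n_edges`, `component_sizes` (descending),
#'   `cluster_sizes` (descending, when clusters are given).
#' @export
network_summary <- function(graph, clusters = NULL) {
  g <- graph$graph
  comp <- igraph::components(g)
  comp_sizes <- if (comp$no) sort(as.integer(comp$csize), decreasing = TRUE)
    else integer()
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       component_sizes = comp_sizes,
       cluster_sizes = if (is.null(clusters)) integer() else
         sort(lengths(clusters$clusters), decreasing = TRUE))
}
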