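#' Build the residue contact graph
#'
#' Residues are nodes; an edge connects two residues when their contact atoms
#' lie strictly closer than \code{cutoff} (default 8 Angstrom), and every
#' covalently adjacent pair (consecutive \code{seq_index} within a chain) is
#' an edge regardless of distance. Each edge is labeled \code{local} when the
#' sequence separation is less than six and \code{tertiary} otherwise;
#' inter-chain contacts are always \code{tertiary} since no sequence
#' separation is defined across chains.
#'
#' In \code{CA} mode the C-alpha atom is the contact atom; in \code{CB} mode
#' the C-beta is used with a C-alpha fallback (glycine). A residue missing
#' both atoms is kept as an isolated node with a warning.
#'
#' @param structure A \code{protein_structure}.
#' @param mode Contact atom, \code{"CA"} (default) or \code{"CB"}.
#' @param cutoff Contact distance cutoff in Angstrom; the test is strict
#'   (\code{distance < cutoff}).
#' @return An object of class \code{residue_graph}: \code{nodes} (residue
#'   table), \code{edges} (\code{from}, \code{to} residue ids with
#'   \code{from < to}, \code{distance}, \code{label}), \code{mode},
#'   \code{cutoff}.
#' @export
build_residue_graph <- function(structure, mode = c("CA", "CB"), cutoff = 8.0) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0)
  res <- structure$residues
  xyz <- residue_coords(structure, mode)
  missing <- !stats::complete.cases(xyz)
  if (any(missing))
    warning(sum(missing), " residue(s) lack both CA and CB atoms and are ",
            "isolated nodes")

  n <- nrow(res)
  edges <- NULL
  ok <- which(!missing)
  if (length(ok) >= 2) {
    d <- as.matrix(stats::dist(xyz[ok, , drop = FALSE]))
    hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      edges <- data.frame(from = ok[hit[, 1]], to = ok[hit[, 2]],
                          distance = d[hit])
    }
  }
  # covalent adjacency: consecutive seq_index in the same chain
  adj_from <- integer(); adj_to <- integer()
  for (ch in unique(res$chain)) {
    ids <- res$residue_id[res$chain == ch]
    ids <- ids[order(res$seq_index[match(ids, res$residue_id)])]
    if (length(ids) >= 2) {
      adj_from <- c(adj_from, ids[-length(ids)])
      adj_to <- c(adj_to, ids[-1])
    }
  }
  keep <- !missing[adj_from] & !missing[adj_to]
  if (any(keep)) {
    dcov <- sqrt(rowSums((xyz[adj_from[keep], , drop = FALSE] -
                          xyz[adj_to[keep], , drop = FALSE])^2))
    edges <- rbind(edges, data.frame(from = adj_from[keep], to = adj_to[keep],
                                     distance = dcov))
  }
  if (!is.null(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    same_chain <- res$chain[edges$from] == res$chain[edges$to]
    sep <- abs(res$seq_index[edges$from] - res$seq_index[edges$to])
    edges$label <- ifelse(same_chain & sep <= 5, "local", "tertiary")
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        distance = numeric(), label = character())
  }
  structure(list(nodes = res, edges = edges, mode = mode, cutoff = cutoff),
            class = "residue_graph")
}

#' Classify a residue pair as a local or tertiary contact
#'
#' Sequence separation below six (\code{|i - j| <= 5}) is \code{local};
#' separation greater than five is \code{tertiary}. Pairs on different
#' chains are \code{tertiary}.
#'
#' @param i,j 0-based sequence indices within a chain.
#' @param same_chain Are both residues on the same chain?
#' @return \code{"local"} or \code{"tertiary"}.
#' @export
classify_edge <- function(i, j, same_chain = TRUE) {
  stopifnot(all(i != j) || !all(same_chain))
  ifelse(same_chain & abs(i - j) <= 5, "local", "tertiary")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("residue_graph (", x$mode, ", < ", x$cutoff, " A): ", nrow(x$nodes),
      " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$label == "local"), " local, ",
      sum(x$edges$label == "tertiary"), " tertiary)\n", sep = "")
  invisible(x)
}

# igraph view of a residue_graph, with vertex names equal to residue_id
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(graph$edges$from),
                   to = as.character(graph$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$residue_id)))
}

#' Topological descriptors of the residue graph
#'
#' Computes, per residue: betweenness (fraction of shortest paths passing
#' through the node, normalized by the number of node pairs
#' \code{(n-1)(n-2)/2}), closeness (inverse of the average path length to the
#' other nodes of its connected component; isolated nodes score 0),
#' clustering coefficient (edges among the \code{n_k} neighbors divided by
#' \code{0.5 n_k (n_k - 1)}; 0 when \code{n_k < 2}), the distinct
#' neighborhood count, and local/tertiary/total contact counts.
#'
#' Shortest-path quantities use fractional (Brandes-style) path counting, so
#' multiple shortest paths contribute proportionally.
#'
#' @param graph A \code{residue_graph}.
#' @return Data frame keyed by \code{residue_id} with columns
#'   \code{betweenness}, \code{closeness}, \code{clustering_coefficient},
#'   \code{distinct_neighborhood_count}, \code{contacts_total},
#'   \code{contacts_local}, \code{contacts_tertiary}.
#' @export
network_metrics <- function(graph) {
  stopifnot(inherits(graph, "residue_graph"))
  n <- nrow(graph$nodes)
  g <- as_igraph(graph)

  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)

  # closeness per connected component: (size - 1) / sum of distances
  d <- igraph::distances(g)
  cls <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[v, reach])
  }, numeric(1))

  cc <- igraph::transitivity(g, type = "local", isolates = "zero")

  deg_local <- tabulate(c(graph$edges$from[graph$edges$label == "local"],
                          graph$edges$to[graph$edges$label == "local"]), n)
  deg_tert <- tabulate(c(graph$edges$from[graph$edges$label == "tertiary"],
                         graph$edges$to[graph$edges$label == "tertiary"]), n)

  dnc <- vapply(graph$nodes$residue_id, function(v)
    distinct_neighborhood_count(graph, v), integer(1))

  data.frame(
    residue_id = graph$nodes$residue_id,
    betweenness = unname(btw), closeness = unname(cls),
    clustering_coefficient = unname(cc),
    distinct_neighborhood_count = dnc,
    contacts_total = deg_local + deg_tert,
    contacts_local = deg_local, contacts_tertiary = deg_tert
  )
}

#' Distinct neighborhood count of a residue
#'
#' The neighbors of \code{v} are partitioned by the local edges they share
#' among themselves: the count is the number of connected components of the
#' subgraph induced on the neighbor set using only local edges between its
#' members. It expresses to how many sequence-separated regions of the
#' protein the residue is connected. Isolated nodes score 0; when no local
#' edges exist among the neighbors the count equals the degree.
#'
#' @param graph A \code{residue_graph}.
#' @param v Residue id of the node.
#' @return Integer count.
#' @export
distinct_neighborhood_count <- function(graph, v) {
  e <- graph$edges
  nb <- sort(unique(c(e$to[e$from == v], e$from[e$to == v])))
  k <- length(nb)
  if (k == 0) return(0L)
  loc <- e[e$label == "local" & e$from %in% nb & e$to %in% nb, , drop = FALSE]
  # union-find over the neighbor set
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(loc))) {
    a <- find(match(loc$from[r], nb)); b <- find(match(loc$to[r], nb))
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

#' Export graph edges as a data frame
#'
#' Edge list with author residue identifiers, suitable for CSV export.
#'
#' @param graph A \code{residue_graph}.
#' @return Data frame with \code{chain_i}, \code{resno_i}, \code{chain_j},
#'   \code{resno_j}, \code{label}, \code{distance}.
#' @export
graph_edge_list <- function(graph) {
  e <- graph$edges
  nd <- graph$nodes
  data.frame(
    chain_i = nd$chain[e$from], resno_i = nd$resno[e$from],
    chain_j = nd$chain[e$to], resno_j = nd$resno[e$to],
    label = e$label, distance = round(e$distance, 3),
    stringsAsFactors = FALSE
  )
}
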