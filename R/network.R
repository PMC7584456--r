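# Dynamical residue network: Calpha-anchored nodes, edges for residue
# pairs in persistent contact (4.5 A for >= 75% of frames), weights
# w = -log|C| from the displacement correlation matrix, Girvan-Newman
# communities and weighted shortest (allosteric) paths.

#' Build the dynamical residue network from a trajectory
#'
#' Nodes are residues (Calpha-anchored); an edge joins residues whose
#' minimal heavy-atom distance is at most `cutoff` in at least
#' `persistence_min` of the frames. Edge weights are
#' `w = -log(|C_ij|)` with `|C_ij|` clamped at 1e-6 (fully correlated
#' motion gives weight 0). Sequence-adjacent residues of the same chain
#' are excluded by default to avoid trivial backbone paths.
#'
#' @param t a `Trajectory` (>= 3 frames).
#' @param cutoff contact distance (Angstrom, default 4.5).
#' @param persistence_min minimal contact persistence (default 0.75).
#' @param exclude_adjacent drop |i-j| = 1 same-chain pairs?
#' @return a `ResidueNetwork`: list with `graph` (igraph), `nodes` and
#'   `edges` data frames, `correlation` matrix.
#' @export
build_network <- function(t, cutoff = 4.5, persistence_min = 0.75,
                          exclude_adjacent = TRUE) {
  blocks <- residue_blocks(t$topology)
  n <- length(blocks$labels)
  C <- correlation_matrix(t)
  cidx <- match(blocks$labels, rownames(C))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (exclude_adjacent) {
    same_chain <- blocks$chain[pairs[, 1]] == blocks$chain[pairs[, 2]]
    adjacent <- abs(blocks$resid[pairs[, 1]] - blocks$resid[pairs[, 2]]) == 1
    pairs <- pairs[!(same_chain & adjacent), , drop = FALSE]
  }
  pdf <- data.frame(
    chain_a = blocks$chain[pairs[, 1]], res_a = blocks$resid[pairs[, 1]],
    chain_b = blocks$chain[pairs[, 2]], res_b = blocks$resid[pairs[, 2]]
  )
  pers <- contact_persistence(t, pairs = pdf, cutoff = cutoff)$persistence
  keep <- pers >= persistence_min
  if (!any(keep)) stop("no residue pair meets the persistence criterion")
  ei <- pairs[keep, 1]; ej <- pairs[keep, 2]
  corr <- C[cbind(cidx[ei], cidx[ej])]
  corr[is.na(corr)] <- 0
  w <- -log(pmax(abs(corr), 1e-6))
  # perfectly rigid limit: a pair of zero-variance nodes moves as one
  # body (correlation 1 in the limit), so its edge gets weight 0
  zero_var <- diag(C) == 0
  both_rigid <- zero_var[cidx[ei]] & zero_var[cidx[ej]]
  w[both_rigid] <- 0
  corr[both_rigid] <- 1
  edges <- data.frame(
    from = blocks$labels[ei], to = blocks$labels[ej],
    persistence = pers[keep], correlation = corr, weight = w,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = blocks$labels, chain = blocks$chain,
                          resid = blocks$resid)
  )
  structure(
    list(graph = g, nodes = data.frame(
      label = blocks$labels, chain = blocks$chain, resid = blocks$resid,
      stringsAsFactors = FALSE
    ), edges = edges, correlation = C),
    class = "ResidueNetwork"
  )
}

#' @export
print.ResidueNetwork <- function(x, ...) {
  cat(sprintf("ResidueNetwork: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "ResidueNetwork")) net$graph
  else if (igraph::is_igraph(net)) net
  else stop("expected a ResidueNetwork or igraph graph")
}

# igraph's weighted routines need strictly positive weights; fully
# correlated pairs (w = 0) are kept at a negligible epsilon.
positive_weights <- function(g) {
  w <- igraph::E(g)$weight
  if (is.null(w)) rep(1, igraph::ecount(g)) else pmax(w, 1e-12)
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest betweenness and returns the
#' partition of maximal modularity along the resulting dendrogram
#' (igraph's edge-betweenness clustering).
#'
#' @param net a `ResidueNetwork` or igraph graph.
#' @return list with `membership` (named integer vector) and
#'   `modularity` (at the chosen partition).
#' @export
network_communities <- function(net) {
  g <- as_igraph(net)
  cl <- suppressWarnings(igraph::cluster_edge_betweenness(
    g, weights = positive_weights(g), modularity = TRUE
  ))
  list(
    membership = igraph::membership(cl),
    modularity = max(cl$modularity)
  )
}

#' k shortest allosteric paths between residue sets
#'
#' Weighted shortest paths (Dijkstra) plus loopless next-shortest
#' alternatives (Yen's scheme) from any source to any target node;
#' path length is the sum of edge weights `-log|C|`, so short paths
#' follow chains of correlated persistent contacts.
#'
#' @param net a `ResidueNetwork` or igraph graph.
#' @param source,target node names (e.g. `"E|58"`) or igraph vertex ids.
#' @param k number of paths to return (default 3).
#' @return list with `paths` (list of node-name vectors) and `lengths`;
#'   zero paths when the sets are disconnected. A source node that is
#'   also a target yields a single zero-length path.
#' @export
allosteric_paths <- function(net, source, target, k = 3) {
  g <- as_igraph(net)
  w <- positive_weights(g)
  nm <- igraph::V(g)$name
  resolve <- function(x) {
    if (is.character(x)) {
      miss <- setdiff(x, nm)
      if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
    }
    x
  }
  source <- resolve(source); target <- resolve(target)
  found_paths <- list(); found_len <- numeric(0)
  for (s in source) {
    for (tg in target) {
      if (identical(s, tg)) {
        found_paths[[length(found_paths) + 1]] <- s
        found_len <- c(found_len, 0)
        next
      }
      res <- tryCatch(
        suppressWarnings(
          igraph::k_shortest_paths(g, from = s, to = tg, k = k,
                                   weights = w)),
        error = function(e) NULL
      )
      if (is.null(res) || !length(res$vpaths)) next
      for (p in res$vpaths) {
        labs <- igraph::V(g)$name[p]
        eids <- igraph::get_edge_ids(g, rep(labs, each = 2)[-c(1, 2 * length(labs))])
        len <- sum(igraph::E(g)$weight[eids])
        found_paths[[length(found_paths) + 1]] <- labs
        found_len <- c(found_len, len)
      }
    }
  }
  if (!length(found_paths)) {
    return(list(paths = list(), lengths = numeric(0)))
  }
  keys <- vapply(found_paths, paste, character(1), collapse = ">")
  first <- !duplicated(keys)
  found_paths <- found_paths[first]; found_len <- found_len[first]
  ord <- utils::head(order(found_len), k)
  list(paths = found_paths[ord], lengths = found_len[ord])
}

#' Write the network as an edge-list TSV
#' @param net a `ResidueNetwork`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
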