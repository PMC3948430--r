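#' Resource budget for pathway mining
#'
#' Enumerating all simple paths between two nodes is NP-complete in dense
#' networks, so the miners run under an explicit budget: exceeding it raises
#' a classed error (`trp_budget_error`) naming the exceeded limit and the
#' partial count — never a silent truncation.
#'
#' @param max_subgraph_nodes Largest admissible node count of the extracted
#'   source-target subgraph.
#' @param max_paths Largest admissible number of enumerated pathways.
#' @param max_path_length Optional cap on pathway length in edges
#'   (`Inf` = unlimited).
#' @return A list of class `trp_budget`.
#' @export
mining_budget <- function(max_subgraph_nodes = 5000L, max_paths = 100000L,
                          max_path_length = Inf) {
  stopifnot(max_subgraph_nodes >= 1, max_paths >= 1, max_path_length >= 1)
  structure(list(max_subgraph_nodes = as.integer(max_subgraph_nodes),
                 max_paths = as.integer(max_paths),
                 max_path_length = max_path_length),
            class = "trp_budget")
}

#' Extract the subgraph spanned by all source-to-target paths
#'
#' First stage of the divide-and-conquer mining procedure: the kept node set
#' is the intersection of the forward-reachable set of `source` and the
#' backward-reachable set of `target` (two breadth-first sweeps), with the
#' induced edges. The set of simple source-to-target paths in the subgraph
#' equals that in the full network, so enumeration can run on the (much
#' sparser) subgraph without loss.
#'
#' A missing source or target is not an exception: an empty network is
#' returned carrying an `absent_nodes` attribute, so batch queries proceed.
#'
#' @param network A [trp_network].
#' @param source,target Node symbols (normalized internally); must differ.
#' @return A [trp_network] restricted to the kept nodes.
#' @export
extract_path_subgraph <- function(network, source, target) {
  source <- normalize_symbol(source)
  target <- normalize_symbol(target)
  if (source == target) {
    abort("source and target must differ", class = "trp_query_error")
  }
  absent <- setdiff(c(source, target), network$nodes)
  if (length(absent) > 0) {
    sub <- new_trp_network(network$kind, network$condition,
                           network$edges[0, , drop = FALSE])
    attr(sub, "absent_nodes") <- absent
    return(sub)
  }
  fwd <- reachable(adjacency(network$edges), source)
  bwd <- reachable(adjacency(network$edges, reverse = TRUE), target)
  keep <- intersect(fwd, bwd)
  edges <- network$edges[network$edges$tf %in% keep &
                           network$edges$target %in% keep, , drop = FALSE]
  # drop self-loops: they cannot participate in any simple path
  edges <- edges[edges$tf != edges$target, , drop = FALSE]
  new_trp_network(network$kind, network$condition, edges)
}

#' Enumerate all transcriptional regulatory pathways for a TF-gene pair
#'
#' Second stage of the mining procedure intended for the sparse
#' direct-regulatory network: a depth-first search over the extracted
#' subgraph returns every simple directed path from `source` to `target`
#' (no node revisited; the direct edge, when present, is a valid length-1
#' pathway). Output is sorted by (length, lexicographic node sequence) and
#' deterministic.
#'
#' @inheritParams extract_path_subgraph
#' @param budget A [mining_budget()].
#' @return A pathway tibble with columns `path_id`, `source`, `target`,
#'   `length` (edges) and `nodes` (list of node vectors), plus a `path`
#'   display string. Empty with an `absent_nodes` attribute when an endpoint
#'   is missing from the network.
#' @examples
#' fx <- gln3_fixture()
#' net <- build_direct_regulatory_network(fx$tfb, fx$tfr,
#'   condition = "nitrogen source quality/availability")
#' enumerate_all_trps(net, "GLN3", "GZF3")
#' @export
enumerate_all_trps <- function(network, source, target,
                               budget = mining_budget()) {
  source <- normalize_symbol(source)
  target <- normalize_symbol(target)
  sub <- extract_path_subgraph(network, source, target)
  if (length(sub$nodes) == 0) {
    return(empty_paths(source, target, attr(sub, "absent_nodes")))
  }
  if (length(sub$nodes) > budget$max_subgraph_nodes) {
    abort(sprintf(
      "mining budget exceeded: extracted subgraph has %d nodes (limit max_subgraph_nodes = %d)",
      length(sub$nodes), budget$max_subgraph_nodes),
      class = "trp_budget_error")
  }
  paths <- dfs_simple_paths(adjacency(sub$edges), source, target,
                            max_len = budget$max_path_length,
                            max_paths = budget$max_paths)
  as_trp_paths(sort_paths(paths), source, target)
}

#' Shortest pathway length between a TF-gene pair
#'
#' Breadth-first distance labeling on the unweighted digraph (every edge
#' has weight 1). Returns `Inf` when the target is unreachable; a missing
#' endpoint also yields `Inf`, flagged with an `absent_nodes` attribute.
#'
#' @inheritParams extract_path_subgraph
#' @return A single number: the minimal edge count, or `Inf`.
#' @export
shortest_trp_length <- function(network, source, target) {
  source <- normalize_symbol(source)
  target <- normalize_symbol(target)
  if (source == target) {
    abort("source and target must differ", class = "trp_query_error")
  }
  absent <- setdiff(c(source, target), network$nodes)
  if (length(absent) > 0) {
    return(structure(Inf, absent_nodes = absent))
  }
  d <- bfs_distances(adjacency(network$edges), source)
  unname(d[target])
}

#' Enumerate all shortest pathways for a TF-gene pair
#'
#' Intended for the dense binding network, where full enumeration is
#' intractable: first the shortest path length L is found by breadth-first
#' distance labeling, then a depth-first branch-and-bound search enumerates
#' exactly the simple paths of length L. The bound uses precomputed
#' backward distance-to-target labels: a branch at node v and depth d is
#' pruned whenever d + dist(v, target) exceeds L, so only edges on shortest
#' paths are ever traversed (polynomial preprocessing, output-polynomial
#' enumeration).
#'
#' @inheritParams enumerate_all_trps
#' @return A pathway tibble (see [enumerate_all_trps()]); all rows share the
#'   minimal length. Empty when the pair is unreachable.
#' @export
enumerate_shortest_trps <- function(network, source, target,
                                    budget = mining_budget()) {
  source <- normalize_symbol(source)
  target <- normalize_symbol(target)
  if (source == target) {
    abort("source and target must differ", class = "trp_query_error")
  }
  absent <- setdiff(c(source, target), network$nodes)
  if (length(absent) > 0) {
    return(empty_paths(source, target, absent))
  }
  back <- bfs_distances(adjacency(network$edges, reverse = TRUE), target)
  L <- unname(back[source])
  if (!is.finite(L) || L > budget$max_path_length) {
    return(empty_paths(source, target, NULL))
  }
  adj <- adjacency(network$edges)
  paths <- list()
  n_found <- 0L
  prefix <- character()
  on_path <- stats::setNames(rep(FALSE, length(back)), names(back))
  descend <- function(v, depth) {
    if (v == target) {
      n_found <<- n_found + 1L
      if (n_found > budget$max_paths) {
        abort(sprintf(
          "mining budget exceeded: more than max_paths = %d shortest pathways (partial count %d)",
          budget$max_paths, budget$max_paths),
          class = "trp_budget_error")
      }
      paths[[n_found]] <<- c(prefix, v)
      return(invisible())
    }
    on_path[[v]] <<- TRUE
    prefix[depth + 1L] <<- v
    for (w in adj[[v]] %||% character()) {
      # branch-and-bound: never leave the shortest-path DAG
      if (!on_path[[w]] && depth + 1 + back[[w]] <= L) {
        descend(w, depth + 1L)
      }
    }
    prefix <<- prefix[-(depth + 1L)]
    on_path[[v]] <<- FALSE
    invisible()
  }
  descend(source, 0L)
  as_trp_paths(sort_paths(paths), source, target)
}

#' All ordered TF-gene pairs along a pathway
#'
#' A pathway of L edges implies L(L+1)/2 ordered (upstream, downstream)
#' pairs: perturbing any upstream TF should influence every node downstream
#' of it along the pathway, so each such pair is an independently testable
#' regulation claim. For Gln3 -> Gat1 -> GZF3 the three pairs are
#' (GLN3, GAT1), (GLN3, GZF3) and (GAT1, GZF3).
#'
#' @param nodes Character vector of pathway nodes (length >= 2), or a
#'   one-row pathway tibble.
#' @return A tibble with columns `upstream` and `downstream`, in (i, j)
#'   index order.
#' @export
pairs_along <- function(nodes) {
  nodes <- path_nodes(nodes)
  n <- length(nodes)
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(NA, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble(upstream = nodes[idx[, "row"]], downstream = nodes[idx[, "col"]])
}

path_nodes <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && nrow(x) == 1 && "nodes" %in% names(x)) {
    return(x$nodes[[1]])
  }
  abort("expected a character vector of nodes or a one-row pathway tibble",
        class = "trp_query_error")
}

# ---- internal graph primitives ------------------------------------------

# adjacency(): named list of sorted out-neighbor vectors. reverse = TRUE
# swaps edge direction (backward sweeps).
adjacency <- function(edges, reverse = FALSE) {
  from <- if (reverse) edges$target else edges$tf
  to <- if (reverse) edges$tf else edges$target
  adj <- split(to, from)
  lapply(adj, function(v) sort(unique(v)))
}

reachable <- function(adj, start) {
  seen <- stats::setNames(TRUE, start)
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!(nxt %in% names(seen))]
    if (length(nxt) > 0) seen[nxt] <- TRUE
    frontier <- nxt
  }
  names(seen)
}

bfs_distances <- function(adj, start) {
  nodes <- unique(c(names(adj), unlist(adj, use.names = FALSE)))
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  if (!start %in% nodes) return(stats::setNames(Inf, start))
  d[start] <- 0
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(d)[is.finite(d)])
    if (length(nxt) > 0) d[nxt] <- d[frontier[1]] + 1
    frontier <- nxt
  }
  d
}

dfs_simple_paths <- function(adj, source, target, max_len = Inf,
                             max_paths = Inf) {
  paths <- list()
  n_found <- 0L
  prefix <- character()
  all_nodes <- unique(c(names(adj), unlist(adj, use.names = FALSE)))
  visited <- stats::setNames(rep(FALSE, length(all_nodes)), all_nodes)
  descend <- function(v, depth) {
    if (v == target) {
      n_found <<- n_found + 1L
      if (n_found > max_paths) {
        abort(sprintf(
          "mining budget exceeded: more than max_paths = %d pathways (partial count %d)",
          max_paths, max_paths),
          class = "trp_budget_error")
      }
      paths[[n_found]] <<- c(prefix, v)
      return(invisible())
    }
    if (depth >= max_len) return(invisible())
    visited[[v]] <<- TRUE
    prefix[depth + 1L] <<- v
    for (w in adj[[v]] %||% character()) {
      if (!visited[[w]]) descend(w, depth + 1L)
    }
    prefix <<- prefix[-(depth + 1L)]
    visited[[v]] <<- FALSE
    invisible()
  }
  descend(source, 0L)
  paths
}

# stable (length, then element-wise lexicographic) order; radix = C locale
sort_paths <- function(nodes_list) {
  if (length(nodes_list) <= 1) return(nodes_list)
  lens <- lengths(nodes_list)
  out <- list()
  for (L in sort(unique(lens))) {
    grp <- nodes_list[lens == L]
    m <- do.call(rbind, grp)
    ord <- do.call(order, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                            list(method = "radix")))
    out <- c(out, grp[ord])
  }
  out
}

as_trp_paths <- function(nodes_list, source, target) {
  n <- length(nodes_list)
  out <- tibble(
    path_id = seq_len(n),
    source = rep(source, n),
    target = rep(target, n),
    length = lengths(nodes_list) - 1L,
    path = vapply(nodes_list, paste, "", collapse = " -> "),
    nodes = nodes_list
  )
  class(out) <- c("trp_paths", class(out))
  out
}

empty_paths <- function(source, target, absent_nodes = NULL) {
  out <- as_trp_paths(list(), source, target)[0, ]
  if (length(absent_nodes) > 0) attr(out, "absent_nodes") <- absent_nodes
  out
}
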