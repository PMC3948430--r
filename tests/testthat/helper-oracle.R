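# Independent brute-force oracles for the path miners. These deliberately
# share no code with the package: plain recursive enumeration on the FULL
# edge list (never an extracted subgraph), so agreement also certifies that
# subgraph extraction preserves the path set.

oracle_all_simple_paths <- function(edges, source, target) {
  adj <- split(as.character(edges$target), as.character(edges$tf))
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == target) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
    invisible()
  }
  if (source != target) walk(source)
  out
}

oracle_shortest_paths <- function(edges, source, target) {
  all <- oracle_all_simple_paths(edges, source, target)
  if (length(all) == 0) return(all)
  lens <- lengths(all)
  all[lens == min(lens)]
}

# canonical multiset representation for comparing path sets
path_set <- function(paths) {
  if (is.data.frame(paths)) paths <- paths$nodes
  sort(vapply(paths, paste, "", collapse = ">"))
}

# Random digraph wrapped as evidence tables in which every edge carries both
# evidence kinds, so the direct-regulatory network is exactly the digraph.
random_case <- function(seed, n_max = 12) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  nodes <- sprintf("N%02d", seq_len(n))
  p <- stats::runif(1, 0.1, 0.35)
  grid <- expand.grid(tf = nodes, target = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$tf != grid$target, , drop = FALSE]
  edges <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  st <- sample(nodes, 2)
  net <- if (nrow(edges) == 0) {
    build_direct_regulatory_network(empty_pair_table(), empty_pair_table())
  } else {
    mk <- function(kind) as_evidence_pairs(tibble::tibble(
      tf = edges$tf, target = edges$target, evidence_kind = kind,
      publications = paste0("P", seq_len(nrow(edges)))))
    build_direct_regulatory_network(mk("TFB"), mk("TFR"))
  }
  list(edges = edges, net = net, source = st[1], target = st[2])
}

empty_pair_table <- function() {
  as_evidence_pairs(tibble::tibble(
    tf = character(), target = character(), evidence_kind = character(),
    publications = character()))
}
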