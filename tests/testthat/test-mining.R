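test_that("subgraph extraction keeps exactly the nodes on source-target paths", {
  fx <- gln3_fixture()
  net <- build_direct_regulatory_network(fx$tfb, fx$tfr, fx$condition)
  sub <- extract_path_subgraph(net, "GLN3", "GZF3")
  expect_setequal(sub$nodes, c("GLN3", "GAT1", "DAL80", "GZF3"))
  expect_equal(nrow(sub$edges), 4)

  chain <- mk_net(c("A", "B", "C"), c("B", "C", "D"))
  sub2 <- extract_path_subgraph(chain, "A", "C")
  expect_setequal(sub2$nodes, c("A", "B", "C"))  # dangling D dropped

  expect_equal(length(extract_path_subgraph(chain, "D", "A")$nodes), 0)
  absent <- extract_path_subgraph(chain, "A", "NOPE")
  expect_equal(length(absent$nodes), 0)
  expect_equal(attr(absent, "absent_nodes"), "NOPE")
  expect_error(extract_path_subgraph(chain, "A", "A"),
               class = "trp_query_error")
})

test_that("all-pathway enumeration reproduces the worked nitrogen example", {
  fx <- gln3_fixture()
  net <- build_direct_regulatory_network(fx$tfb, fx$tfr, fx$condition)
  paths <- enumerate_all_trps(net, "GLN3", "GZF3")
  expect_equal(paths$nodes,
               list(c("GLN3", "GAT1", "GZF3"),
                    c("GLN3", "DAL80", "GAT1", "GZF3")))
  expect_equal(paths$length, c(2L, 3L))
})

test_that("enumeration counts match closed forms on canonical graphs", {
  # single edge: one length-1 pathway
  single <- mk_net("A", "B")
  expect_equal(enumerate_all_trps(single, "A", "B")$nodes, list(c("A", "B")))

  # complete DAG on 5 topologically ordered nodes: 2^(n-2) = 8 paths
  grid <- expand.grid(i = 1:5, j = 1:5)
  grid <- grid[grid$i < grid$j, ]
  dag <- mk_net(paste0("V", grid$i), paste0("V", grid$j))
  expect_equal(nrow(enumerate_all_trps(dag, "V1", "V5")), 8)

  # 3-cycle plus exit edge: the visited-set forbids revisits
  cyc <- mk_net(c("A", "B", "C", "C"), c("B", "C", "A", "T"))
  expect_equal(enumerate_all_trps(cyc, "A", "T")$nodes,
               list(c("A", "B", "C", "T")))
})

test_that("shortest pathway length is BFS distance, Inf when unreachable", {
  fx <- gln3_fixture()
  net <- build_direct_regulatory_network(fx$tfb, fx$tfr, fx$condition)
  expect_equal(shortest_trp_length(net, "GLN3", "GZF3"), 2)
  expect_equal(shortest_trp_length(net, "GLN3", "GAT1"), 1)
  expect_equal(shortest_trp_length(net, "GZF3", "GLN3"), Inf)
  absent <- shortest_trp_length(net, "GLN3", "NOPE")
  expect_equal(unclass(absent), Inf, ignore_attr = TRUE)
  expect_equal(attr(absent, "absent_nodes"), "NOPE")
})

test_that("shortest enumeration returns exactly the minimum-length pathways", {
  diamond <- mk_net(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  got <- enumerate_shortest_trps(diamond, "A", "D")
  expect_equal(got$nodes, list(c("A", "B", "D"), c("A", "C", "D")))

  fx <- gln3_fixture()
  net <- build_direct_regulatory_network(fx$tfb, fx$tfr, fx$condition)
  expect_equal(enumerate_shortest_trps(net, "GLN3", "GZF3")$nodes,
               list(c("GLN3", "GAT1", "GZF3")))

  # a direct edge dominates any detour
  detour <- mk_net(c("A", "A", "B"), c("B", "D", "D"))
  expect_equal(enumerate_shortest_trps(detour, "A", "D")$nodes,
               list(c("A", "D")))

  none <- enumerate_shortest_trps(detour, "D", "A")
  expect_equal(nrow(none), 0)
})

test_that("budget overruns raise classed errors naming the limit", {
  grid <- expand.grid(i = 1:6, j = 1:6)
  grid <- grid[grid$i < grid$j, ]
  dag <- mk_net(paste0("V", grid$i), paste0("V", grid$j))
  expect_error(
    enumerate_all_trps(dag, "V1", "V6", mining_budget(max_paths = 3)),
    regexp = "max_paths", class = "trp_budget_error")
  expect_error(
    enumerate_all_trps(dag, "V1", "V6",
                       mining_budget(max_subgraph_nodes = 2)),
    regexp = "max_subgraph_nodes", class = "trp_budget_error")
  # max_path_length truncates the admissible set without error
  short_only <- enumerate_all_trps(dag, "V1", "V6",
                                   mining_budget(max_path_length = 2))
  expect_true(all(short_only$length <= 2))
  expect_equal(nrow(short_only), 5)  # direct edge + 4 one-stop routes
})

test_that("miners agree with the brute-force oracle on random digraphs", {
  for (seed in 1:60) {
    case <- random_case(seed)
    if (case$source == case$target) next
    expected <- oracle_all_simple_paths(case$edges, case$source, case$target)
    got <- enumerate_all_trps(case$net, case$source, case$target)
    expect_identical(path_set(got), path_set(expected))
    expect_identical(
      path_set(enumerate_shortest_trps(case$net, case$source, case$target)),
      path_set(oracle_shortest_paths(case$edges, case$source, case$target)))
  }
})

test_that("miners agree with igraph as a second, independent oracle", {
  skip_if_not_installed("igraph")
  for (seed in c(101, 202, 303, 404, 505)) {
    case <- random_case(seed)
    if (nrow(case$edges) == 0) next
    g <- igraph::graph_from_data_frame(case$edges)
    expected <- if (case$source %in% case$net$nodes &&
                    case$target %in% case$net$nodes) {
      lapply(igraph::all_simple_paths(g, case$source, case$target,
                                      mode = "out"),
             function(p) names(p))
    } else list()
    got <- enumerate_all_trps(case$net, case$source, case$target)
    expect_identical(path_set(got), path_set(expected))
  }
})

test_that("mined pathways satisfy their structural invariants", {
  for (seed in 1:20) {
    case <- random_case(seed)
    paths <- enumerate_all_trps(case$net, case$source, case$target)
    if (nrow(paths) == 0) next
    edge_keys <- paste(case$net$edges$tf, case$net$edges$target)
    for (nd in paths$nodes) {
      expect_false(anyDuplicated(nd) > 0)        # simple
      steps <- paste(nd[-length(nd)], nd[-1])
      expect_true(all(steps %in% edge_keys))     # edges exist
    }
    expect_true(all(paths$length >= 1))
    # deterministic ordered output
    again <- enumerate_all_trps(case$net, case$source, case$target)
    expect_identical(paths, again)
  }
})
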