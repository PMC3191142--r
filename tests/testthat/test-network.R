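complete_edges <- function(nodes) {
  e <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  e[e$source != e$target, ]
}

test_that("hub index on canonical graphs matches hand counts", {
  nodes <- dmn_node_labels()
  full <- causal_graph(nodes, complete_edges(nodes))
  hi <- hub_index(full)
  expect_identical(hi$d_all, 56L)
  expect_identical(hi$d_outer, 32L)
  expect_equal(hi$ratio, 32 / 56)
  expect_identical(sum(hi$d_out), 56L)
  expect_identical(sum(hi$d_in), 56L)

  one <- causal_graph(nodes, data.frame(source = "PCC", target = "lITC"))
  hi1 <- hub_index(one)
  expect_identical(hi1$d_outer, 1L)
  expect_identical(hi1$d_all, 1L)
  expect_equal(hi1$ratio, 1)

  empty <- causal_graph(nodes)
  hie <- hub_index(empty)
  expect_identical(hie$d_all, 0L)
  expect_false(hie$ratio_defined)
  expect_true(is.na(hie$ratio))
})

test_that("hub index equals exhaustive counting on random graphs", {
  set.seed(20)
  for (i in 1:100) {
    g <- random_graph(n_nodes = sample(4:9, 1), n_hubs = sample(1:3, 1),
                      p = runif(1, 0.05, 0.6))
    hi <- hub_index(g)
    oracle <- oracle_hub_counts(g$edges, g$hub_labels)
    expect_identical(hi$d_all, oracle$d_all)
    expect_identical(hi$d_outer, oracle$d_outer)
    # degree conservation and the partition identity
    expect_identical(sum(hi$d_out), hi$d_all)
    expect_identical(sum(hi$d_in), hi$d_all)
    expect_identical(hi$d_all,
                     hi$d_outer + oracle$within_hub + oracle$within_nonhub)
    if (hi$ratio_defined) {
      expect_gte(hi$ratio, 0)
      expect_lte(hi$ratio, 1)
    }
  }
})

test_that("graphs are built edge-for-edge from significance tables", {
  nodes <- c("PCC", "MPFC", "lITC")
  tab <- expand.grid(source = nodes, target = nodes,
                     stringsAsFactors = FALSE)
  tab <- tab[tab$source != tab$target, ]
  set.seed(21)
  tab$significant <- runif(nrow(tab)) < 0.5
  g <- build_graph(tab, nodes, hub_labels = c("PCC", "MPFC"))
  expect_identical(nrow(g$edges), sum(tab$significant))
  for (r in which(tab$significant))
    expect_true(any(g$edges$source == tab$source[r] &
                      g$edges$target == tab$target[r]))

  all_sig <- tab; all_sig$significant <- TRUE
  expect_identical(nrow(build_graph(all_sig, nodes)$edges), 6L)
  none <- tab; none$significant <- FALSE
  expect_identical(nrow(build_graph(none, nodes)$edges), 0L)

  expect_error(build_graph(rbind(tab, tab[1, ]), nodes), "duplicate")
  expect_error(causal_graph(nodes, data.frame(source = "PCC",
                                              target = "PCC")),
               "self-loops")
})

test_that("group edge proportions count subjects per ordered pair", {
  nodes <- c("A", "B", "C")
  gs <- list(
    causal_graph(nodes, data.frame(source = c("A", "B"),
                                   target = c("B", "C")),
                 hub_labels = "A"),
    causal_graph(nodes, data.frame(source = "A", target = "B"),
                 hub_labels = "A"),
    causal_graph(nodes, NULL, hub_labels = "A"),
    causal_graph(nodes, data.frame(source = c("A", "C"),
                                   target = c("B", "A")),
                 hub_labels = "A"),
    causal_graph(nodes, data.frame(source = "A", target = "B"),
                 hub_labels = "A"))
  pr <- group_edge_proportions(gs)
  expect_identical(nrow(pr), 6L)
  get <- function(s, t) pr$proportion[pr$source == s & pr$target == t]
  expect_equal(get("A", "B"), 0.8)
  expect_equal(get("B", "C"), 0.2)
  expect_equal(get("C", "A"), 0.2)
  expect_equal(get("B", "A"), 0)
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1))

  other <- causal_graph(c("A", "B"), NULL, hub_labels = "A")
  expect_error(group_edge_proportions(list(gs[[1]], other)), "node labels")
})

test_that("degree counts agree with igraph", {
  set.seed(40)
  for (i in 1:20) {
    g <- random_graph(n_nodes = sample(4:9, 1), n_hubs = 2,
                      p = runif(1, 0.2, 0.8))
    if (nrow(g$edges) == 0) next
    ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                        vertices = g$node_labels)
    hi <- hub_index(g)
    expect_equal(hi$d_out[g$node_labels],
                 igraph::degree(ig, mode = "out")[g$node_labels],
                 tolerance = 1e-12)
    expect_equal(hi$d_in[g$node_labels],
                 igraph::degree(ig, mode = "in")[g$node_labels],
                 tolerance = 1e-12)
  }
})

test_that("proportion bands follow the documented boundaries", {
  expect_identical(as.character(categorize_proportion(0.85)), "above_80")
  expect_identical(as.character(categorize_proportion(0.5)), "50_to_60")
  expect_identical(as.character(categorize_proportion(0.49)), "below_50")
  expect_identical(as.character(categorize_proportion(0.6)), "60_to_80")
  expect_identical(as.character(categorize_proportion(0.8)), "60_to_80")
  expect_identical(as.character(categorize_proportion(0.801)), "above_80")
  expect_identical(as.character(categorize_proportion(1)), "above_80")
  expect_identical(as.character(categorize_proportion(0)), "below_50")
  expect_error(categorize_proportion(1.2), "\\[0, 1\\]")
})
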