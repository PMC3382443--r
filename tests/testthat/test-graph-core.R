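test_that("edge-list parsing builds a simple symmetric graph", {
  tf <- withr::local_tempfile(lines = c("# comment", "1 2", "2 3", ""))
  g <- read_graph(tf, "edge_list")
  expect_equal(n_vertices(g), 3L)
  expect_equal(n_edges(g), 2L)
  expect_true(has_edge(g, "1", "2"))
  expect_false(has_edge(g, "1", "3"))

  # duplicates and reversals collapse to one edge
  tf2 <- withr::local_tempfile(lines = c("1 2", "1 2", "2 1"))
  g2 <- read_graph(tf2, "edge_list")
  expect_equal(n_vertices(g2), 2L)
  expect_equal(n_edges(g2), 1L)

  tf3 <- withr::local_tempfile(lines = c("1 2", "1 2 3"))
  expect_error(read_graph(tf3, "edge_list"), "line 2")
})

test_that("dimacs parsing honors the header and 1-based labels", {
  tf <- withr::local_tempfile(lines = c("c triangle", "p edge 3 3",
                                        "e 1 2", "e 1 3", "e 2 3"))
  g <- read_graph(tf, "auto")
  expect_equal(n_vertices(g), 3L)
  expect_equal(n_edges(g), 3L)
  expect_true(is_clique(g, c("1", "2", "3")))

  bad <- withr::local_tempfile(lines = c("p edge 3 5", "e 1 2"))
  expect_error(read_graph(bad, "dimacs"), "declares 5 edges")
  oor <- withr::local_tempfile(lines = c("p edge 3 1", "e 1 4"))
  expect_error(read_graph(oor, "dimacs"), "out of range")
})

test_that("self-loops are rejected and labels must exist", {
  expect_error(mce_graph(cbind("1", "1")), "self-loop")
  g <- g_path3()
  expect_error(remove_vertex(g, "9"), "not in the graph")
  expect_error(is_clique(g, c("1", "9")), "not in the graph")
})

test_that("write/read round-trips preserve the graph, including isolates", {
  g <- mce_graph(cbind(c("b", "b"), c("a", "c")), vertices = c("a", "b", "c", "z"))
  for (fmt in c("edge_list", "dimacs")) {
    tf <- withr::local_tempfile()
    write_graph(g, tf, fmt)
    h <- read_graph(tf, fmt)
    expect_equal(n_vertices(h), 4L)
    expect_equal(n_edges(h), 2L)
    if (fmt == "edge_list") expect_identical(vertex_names(h), vertex_names(g))
  }
})

test_that("remove_vertex removes incident edges and leaves input unchanged", {
  g <- g_k(3)
  h <- remove_vertex(g, "1")
  expect_equal(n_edges(h), 1L)
  expect_equal(n_edges(g), 3L)

  p <- g_path3()
  mid <- remove_vertex(p, "2")
  expect_equal(n_vertices(mid), 2L)
  expect_equal(n_edges(mid), 0L)

  # deleting every vertex in any order empties the graph
  h <- g_k(4)
  for (v in sample(vertex_names(h))) h <- remove_vertex(h, v)
  expect_equal(n_vertices(h), 0L)
})

test_that("removing a clique vertex from the sensitivity example drops omega", {
  g <- clique_sensitivity_graph("a")
  expect_equal(length(brute_force_maximum(g)[[1]]), 5L)
  h <- remove_vertex(g, "3")
  expect_equal(length(brute_force_maximum(h)[[1]]), 4L)
})

test_that("is_clique matches the definition, including vacuous cases", {
  expect_true(is_clique(g_k(3), c("1", "2", "3")))
  expect_false(is_clique(g_path3(), c("1", "2", "3")))
  expect_true(is_clique(g_path3(), character(0)))
  expect_true(is_clique(g_path3(), "2"))
})

test_that("every generated graph satisfies the structural invariants", {
  graphs <- list(g_path3(), g_k(5), g_shared_edge(), moon_moser_graph(3),
                 clique_sensitivity_graph("a"), clique_sensitivity_graph("b"),
                 gnp_graph(15, 0.4, seed = 3),
                 planted_overlap_graph(16, 5, 2, 2, 0.1, seed = 2)$graph,
                 degree_weighted_graph(rep(4, 20), seed = 4))
  for (g in graphs) expect_silent(mcenum:::validate_graph(g))
})

test_that("clique collections canonicalize, deduplicate, and write stably", {
  cs <- clique_set(list(c("2", "1"), c("3", "2"), c("1", "2")))
  expect_length(cs, 2L)
  expect_identical(format(cs), c("1 2", "2 3"))
  expect_equal(attr(cs, "uniform_size"), 2L)

  tf <- withr::local_tempfile()
  write_cliques(cs, tf)
  expect_identical(readLines(tf), c("1 2", "2 3"))
  expect_identical(format(read_cliques(tf)), format(cs))

  tf0 <- withr::local_tempfile()
  write_cliques(clique_set(), tf0)
  expect_identical(readLines(tf0), character(0))
})
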