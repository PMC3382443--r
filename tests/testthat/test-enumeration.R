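algorithms <- c("basic", "intelligent", "parameterized")

test_that("all three strategies solve the sensitivity example identically", {
  for (alg in algorithms) {
    ra <- enumerate_maximum_cliques(clique_sensitivity_graph("a"), alg)
    expect_equal(ra$k, 5L)
    expect_identical(format(ra$cliques), "1 2 3 4 5")

    rb <- enumerate_maximum_cliques(clique_sensitivity_graph("b"), alg)
    expect_equal(rb$k, 4L)
    expect_identical(format(rb$cliques),
                     c("1 3 4 5", "2 3 4 5", "2 3 4 7", "3 4 5 8"))
  }
})

test_that("simple shapes come out right under every strategy", {
  for (alg in algorithms) {
    r <- enumerate_maximum_cliques(g_path3(), alg)
    expect_equal(r$k, 2L)
    expect_identical(format(r$cliques), c("1 2", "2 3"))

    r <- enumerate_maximum_cliques(g_two_triangles(), alg)
    expect_equal(r$k, 3L)
    expect_length(r$cliques, 2L)

    r <- enumerate_maximum_cliques(g_shared_edge(), alg)
    expect_identical(format(r$cliques), c("a b c", "a b d"))

    # Moon-Moser q=2: all 9 maximal cliques are maximum
    r <- enumerate_maximum_cliques(moon_moser_graph(2), alg)
    expect_equal(r$k, 2L)
    expect_length(r$cliques, 9L)
  }
})

test_that("the 4-cycle shows why the n-2 rule is unsound for enumeration", {
  # every vertex has degree n-2; applying the lone-non-neighbor rule would
  # discard co-maximum cliques, so enumeration must report all 4 edges
  g <- g_cycle4()
  expect_same_cliques(brute_force_maximum(g),
                      list(c("1", "2"), c("2", "3"), c("3", "4"), c("1", "4")))
  for (alg in algorithms) {
    r <- enumerate_maximum_cliques(g, alg)
    expect_equal(r$k, 2L)
    expect_length(r$cliques, 4L)
  }
})

test_that("strategies agree with the oracle across the randomized suite", {
  cases <- suite_cases(60L)
  for (i in seq_len(nrow(cases))) {
    g <- gnp_graph(cases$n[i], cases$p[i], seed = cases$seed[i])
    bf <- brute_force_maximum(g)
    for (alg in algorithms) {
      r <- enumerate_maximum_cliques(g, alg)
      expect_identical(format(r$cliques), format(bf))
      expect_equal(r$k, length(bf[[1]]))
    }
  }
})

test_that("the k-cut only ever shrinks the search tree", {
  cases <- suite_cases(30L)
  for (i in seq_len(nrow(cases))) {
    g <- gnp_graph(cases$n[i], cases$p[i], seed = cases$seed[i])
    expect_lte(enumerate_maximum_cliques(g, "intelligent")$nodes,
               enumerate_maximum_cliques(g, "basic")$nodes)
  }
})

test_that("node budgets halt with a subset of the true answer", {
  g <- moon_moser_graph(3)
  for (alg in algorithms) {
    r <- enumerate_maximum_cliques(g, alg, budget_nodes = 3)
    expect_equal(r$status, "halted")
    full <- enumerate_maximum_cliques(g, alg)
    expect_true(all(format(r$cliques) %in% format(full$cliques)))
    expect_equal(full$status, "complete")
  }
})

test_that("empty and edgeless graphs are handled", {
  for (alg in algorithms) {
    r0 <- enumerate_maximum_cliques(mce_graph(NULL), alg)
    expect_equal(r0$k, 0L)
    expect_length(r0$cliques, 0L)

    r1 <- enumerate_maximum_cliques(mce_graph(NULL, vertices = c("a", "b")), alg)
    expect_equal(r1$k, 1L)
    expect_length(r1$cliques, 2L)
  }
})

test_that("clique sets agree with an independent library implementation", {
  # cross-check against igraph's maximal-clique engine (entirely separate
  # code path from both our R kernels and the C++ subset oracle)
  for (i in 1:10) {
    g <- gnp_graph(15, 0.5, seed = 600 + i)
    ig <- igraph::graph_from_edgelist(as.matrix(do.call(rbind, lapply(
      seq_len(g$n), function(v) {
        nb <- g$adj[[v]]
        nb <- nb[nb > v]
        if (length(nb)) cbind(g$labels[v], g$labels[nb])
      }
    ))), directed = FALSE)
    ig_max <- lapply(igraph::max_cliques(ig),
                     function(cl) igraph::V(ig)$name[cl])
    expect_same_cliques(enumerate_maximal_cliques(g)$cliques, ig_max)

    ig_big <- lapply(igraph::largest_cliques(ig),
                     function(cl) igraph::V(ig)$name[cl])
    expect_same_cliques(enumerate_maximum_cliques(g, "parameterized")$cliques,
                        ig_big)
  }
})
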