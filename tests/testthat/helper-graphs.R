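# Shared fixtures: all graphs are built in code, none loaded from disk.

g_path3 <- function() mce_graph(cbind(c("1", "2"), c("2", "3")))

g_k <- function(n) {
  labels <- as.character(seq_len(n))
  if (n < 2) return(mce_graph(NULL, vertices = labels))
  e <- t(combn(n, 2))
  mce_graph(matrix(as.character(e), ncol = 2), vertices = labels)
}

# two triangles sharing the edge {a, b}
g_shared_edge <- function() {
  mce_graph(cbind(c("a", "a", "b", "a", "b"), c("b", "c", "c", "d", "d")))
}

g_two_triangles <- function() {
  mce_graph(cbind(c("1", "1", "2", "4", "4", "5"),
                  c("2", "3", "3", "5", "6", "6")))
}

g_star <- function(leaves) {
  mce_graph(cbind(rep("c", leaves), paste0("l", seq_len(leaves))))
}

g_cycle4 <- function() {
  mce_graph(cbind(c("1", "2", "3", "1"), c("2", "3", "4", "4")))
}

clique_labels <- function(cs) format(cs)

expect_same_cliques <- function(a, b) {
  expect_identical(clique_labels(clique_set(a)), clique_labels(clique_set(b)))
}

# independent maximality check: a clique with no single-vertex augmentation
is_maximal_clique <- function(g, members) {
  if (!is_clique(g, members)) return(FALSE)
  outside <- setdiff(vertex_names(g), members)
  !any(vapply(outside, function(v) all(members %in% graph_neighbors(g, v)), TRUE))
}

# the randomized suite: deterministic list of (n, p, seed) cases
suite_cases <- function(n_graphs = 200L) {
  ns <- c(12L, 16L, 20L)
  ps <- c(0.3, 0.5, 0.7)
  data.frame(
    n = ns[(seq_len(n_graphs) - 1L) %% 3L + 1L],
    p = ps[((seq_len(n_graphs) - 1L) %/% 3L) %% 3L + 1L],
    seed = 5000L + seq_len(n_graphs)
  )
}
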