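# Synthetic graph generators and the exhaustive small-graph oracle.  Every
# algorithm in the package is testable against these without any external
# dataset.

# run `code` under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

pad_labels <- function(n) formatC(seq_len(n), width = nchar(n), flag = "0")

#' Moon-Moser graph
#'
#' The complete q-partite graph with all parts of size 3 (n = 3q vertices).
#' Its maximal cliques are exactly the \eqn{3^q} transversals of the parts,
#' which realizes the worst-case bound of \eqn{3^{n/3}} maximal cliques a
#' graph on n vertices can contain.
#'
#' @param q Number of parts (`>= 1`).
#' @return An `mce_graph` with vertices labelled `"1" .. "3q"`; part `i`
#'   holds vertices `3i-2, 3i-1, 3i`.
#' @export
moon_moser_graph <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != trunc(q)) {
    stop("`q` must be a positive integer")
  }
  n <- 3L * as.integer(q)
  part <- rep(seq_len(q), each = 3L)
  edges <- NULL
  for (u in seq_len(n - 1L)) {
    vs <- which(part != part[u])
    vs <- vs[vs > u]
    if (length(vs)) edges <- rbind(edges, cbind(u, vs))
  }
  em <- if (is.null(edges)) NULL else matrix(as.character(edges), ncol = 2)
  mce_graph(em, vertices = as.character(seq_len(n)))
}

#' The eight-vertex clique-sensitivity example
#'
#' A complete graph \eqn{K_5} on vertices 1..5 (a putative network of size
#' k = 5) plus three extra vertices each adjacent to k - 2 = 3 of its
#' members: 6 to \{1,2,3\}, 7 to \{2,3,4\}, 8 to \{3,4,5\} (the extras are
#' mutually non-adjacent).  Variant `"a"` has a single maximum clique of
#' size 5; variant `"b"` deletes the single edge \{1,2\}, after which the
#' maximum cliques have size 4 — a minimal illustration of how sensitive
#' the number of maximum cliques is to one edge of noise.
#'
#' @param variant `"a"` (intact) or `"b"` (edge \{1,2\} deleted).
#' @return An `mce_graph` on 8 vertices.
#' @export
clique_sensitivity_graph <- function(variant = c("a", "b")) {
  variant <- match.arg(variant)
  k5 <- t(combn(5, 2))
  extras <- rbind(cbind(6, c(1, 2, 3)), cbind(7, c(2, 3, 4)), cbind(8, c(3, 4, 5)))
  edges <- rbind(k5, extras)
  if (variant == "b") edges <- edges[!(edges[, 1] == 1 & edges[, 2] == 2), ]
  mce_graph(matrix(as.character(edges), ncol = 2),
            vertices = as.character(1:8))
}

#' Erdos-Renyi random graph
#'
#' Each vertex pair receives an edge independently with probability `p`;
#' deterministic for a fixed seed.  Used as the randomized test-suite
#' source.
#'
#' @param n Vertex count.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer random seed.
#' @return An `mce_graph` with zero-padded numeric labels.
#' @export
gnp_graph <- function(n, p, seed) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  labels <- pad_labels(n)
  if (n < 2L) return(mce_graph(NULL, vertices = labels))
  pairs <- t(combn(n, 2))
  keep <- with_local_seed(seed, runif(nrow(pairs)) < p)
  mce_graph(cbind(labels[pairs[keep, 1]], labels[pairs[keep, 2]]),
            vertices = labels)
}

#' Planted overlapping maximum cliques
#'
#' Emulates the clique structure seen in thresholded correlation graphs:
#' one dense region holding several heavily overlapping maximum cliques.
#' `num_cliques` cliques of `clique_size` vertices are planted so that they
#' pairwise share exactly a common core of `core_size` vertices; every
#' remaining vertex pair receives a background edge independently with
#' probability `background_p`.  The construction is post-validated (by the
#' brute-force oracle for n <= 25, else by Bron-Kerbosch enumeration) to
#' guarantee the planted cliques are exactly the maximum cliques of the
#' drawn graph; background edges are re-drawn, deterministically from the
#' seed, until validation passes.
#'
#' @param n Total vertex count.
#' @param clique_size Size of each planted clique (`> core_size`).
#' @param num_cliques Number of planted cliques (`>= 1`).
#' @param core_size Vertices shared by all planted cliques
#'   (`0 <= core_size < clique_size`).
#' @param background_p Background edge probability (keep small).
#' @param seed Integer random seed.
#' @param max_retries Re-draws allowed before giving up.
#' @return A list with `graph` (the `mce_graph`) and `planted` (a
#'   [clique_set()] of the planted cliques).
#' @export
planted_overlap_graph <- function(n, clique_size, num_cliques = 1L,
                                  core_size = 0L, background_p = 0,
                                  seed = 1L, max_retries = 50L) {
  stopifnot(core_size >= 0, core_size < clique_size, num_cliques >= 1,
            background_p >= 0, background_p < 1)
  priv <- clique_size - core_size
  need <- core_size + num_cliques * priv
  if (need > n) stop("n too small: need at least ", need, " vertices")
  labels <- pad_labels(n)
  core <- seq_len(core_size)
  members <- lapply(seq_len(num_cliques), function(i) {
    c(core, core_size + (i - 1L) * priv + seq_len(priv))
  })
  planted_edges <- unique(do.call(rbind, lapply(members, function(m) {
    if (length(m) < 2L) matrix(integer(0), ncol = 2) else t(combn(m, 2))
  })))
  in_planted <- matrix(FALSE, n, n)
  in_planted[planted_edges] <- TRUE
  in_planted[planted_edges[, 2:1, drop = FALSE]] <- TRUE
  free_pairs <- t(combn(n, 2))
  free_pairs <- free_pairs[!in_planted[free_pairs], , drop = FALSE]
  planted <- clique_set(lapply(members, function(m) labels[m]))

  for (attempt in seq_len(max_retries)) {
    bg <- if (background_p > 0 && nrow(free_pairs)) {
      keep <- with_local_seed(seed + (attempt - 1L) * 1009L,
                              runif(nrow(free_pairs)) < background_p)
      free_pairs[keep, , drop = FALSE]
    } else {
      matrix(integer(0), ncol = 2)
    }
    edges <- rbind(planted_edges, bg)
    g <- mce_graph(cbind(labels[edges[, 1]], labels[edges[, 2]]),
                   vertices = labels)
    maxima <- if (n <= 25L) {
      brute_force_maximum(g)
    } else {
      res <- enumerate_maximal_cliques(g)$cliques
      sizes <- lengths(res)
      clique_set(res[sizes == max(sizes)])
    }
    if (same_cliques(maxima, planted)) {
      return(list(graph = g, planted = planted))
    }
  }
  stop("could not realize the planted cliques as the exact maximum cliques ",
       "within ", max_retries, " draws; lower `background_p`")
}

#' Expected-degree (Chung-Lu style) random graph
#'
#' Places each edge \{u, v\} independently with probability
#' \eqn{d_u d_v / \sum_w d_w}, capped at 1, so vertex degrees concentrate
#' around the supplied targets.  This is the null model contrasted with
#' planted-overlap graphs: even with a heavy-tailed (power-law) degree
#' sequence, random placement yields only small, scattered maximum cliques,
#' unlike the large overlapping cliques of correlation graphs.
#'
#' @param degrees Non-negative numeric vector of target degrees.  When
#'   `max(degrees)^2 > sum(degrees)` some pair probabilities hit the cap and
#'   realized degrees fall below target for the largest hubs.
#' @param seed Integer random seed.
#' @return An `mce_graph` on `length(degrees)` vertices.
#' @export
degree_weighted_graph <- function(degrees, seed) {
  if (any(degrees < 0)) stop("degrees must be non-negative")
  n <- length(degrees)
  labels <- pad_labels(n)
  if (n < 2L || sum(degrees) == 0) return(mce_graph(NULL, vertices = labels))
  s <- sum(degrees)
  pairs <- t(combn(n, 2))
  p <- pmin(degrees[pairs[, 1]] * degrees[pairs[, 2]] / s, 1)
  keep <- with_local_seed(seed, runif(nrow(pairs)) < p)
  mce_graph(cbind(labels[pairs[keep, 1]], labels[pairs[keep, 2]]),
            vertices = labels)
}

#' Power-law degree sequence
#'
#' Samples `n` integer degrees from a truncated discrete power law
#' \eqn{P(d) \propto d^{-\gamma}} on `dmin..dmax`; the conventional
#' heavy-tailed stand-in for scale-free degree sequences.
#'
#' @param n Number of degrees.
#' @param exponent Power-law exponent \eqn{\gamma} (default 2.5).
#' @param dmin,dmax Degree range.
#' @param seed Integer random seed.
#' @return Integer vector of length `n`.
#' @export
power_law_degrees <- function(n, exponent = 2.5, dmin = 1L, dmax = 50L, seed = 1L) {
  support <- dmin:dmax
  prob <- support^(-exponent)
  with_local_seed(seed, sample(support, n, replace = TRUE, prob = prob))
}

#' Exhaustive maximal / maximum clique oracle
#'
#' Enumerates every vertex subset of the graph (so n is guarded at 25) and
#' keeps the cliques that no single vertex can extend.  This is the ground
#' truth all enumeration algorithms are tested against; it shares no code
#' with them.
#'
#' @param g An `mce_graph` with `n <= 25`.
#' @return A [clique_set()] of all maximal cliques
#'   (`brute_force_maximum()`: only the largest).
#' @export
brute_force_maximal <- function(g) {
  if (g$n > 25L) stop("brute-force oracle guard: n must be <= 25")
  if (g$n == 0L) return(clique_set())
  adj <- vapply(g$adj, function(a) sum(bitwShiftL(1L, a - 1L)), 0L)
  masks <- bf_maximal_masks(adj, g$n)
  clique_set(lapply(masks, function(m) {
    g$labels[which(bitwAnd(bitwShiftR(m, seq_len(g$n) - 1L), 1L) == 1L)]
  }))
}

#' @rdname brute_force_maximal
#' @export
brute_force_maximum <- function(g) {
  cs <- brute_force_maximal(g)
  if (!length(cs)) return(cs)
  sizes <- lengths(cs)
  clique_set(unclass(cs)[sizes == max(sizes)])
}
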