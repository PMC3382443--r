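# Maximum Clique Finder (MCF): a single maximum clique via a greedy lower
# bound, degree / universal-vertex / coloring preprocessing, and recursive
# in-or-out vertex branching in the style of fixed-parameter vertex-cover
# solvers.

#' Greedy clique heuristic (lower bound on the clique number)
#'
#' Starts from the highest-degree vertex and its highest-degree neighbor,
#' then repeatedly adds the highest-degree vertex adjacent to all current
#' members, discarding non-adjacent vertices each round, until no vertex
#' outside the clique remains.  Degrees are taken in the shrinking residual
#' subgraph; all ties break toward the lowest canonical vertex index, so the
#' result is deterministic.  The clique found is a lower bound \eqn{k \le
#' \omega(G)} used to seed every preprocessing rule.
#'
#' @param g An `mce_graph` with at least one edge (an edgeless graph yields
#'   the single lowest-index vertex as a documented degenerate case).
#' @return Character vector of clique members (sorted labels).
#' @export
greedy_clique <- function(g) {
  if (g$n == 0L) return(character(0))
  if (g$m == 0L) return(g$labels[1])
  nb <- neighbor_masks(g)
  # pool = C (clique so far) plus P (vertices adjacent to all of C);
  # degrees are counted inside the induced subgraph on the pool
  C <- integer(0)
  P <- seq_len(g$n)
  repeat {
    pool_mask <- logical(g$n)
    pool_mask[c(C, P)] <- TRUE
    deg <- vapply(P, function(v) sum(nb[[v]] & pool_mask), 0L)
    pick <- P[deg == max(deg)][1]
    C <- c(C, pick)
    P <- P[nb[[pick]][P]]
    if (!length(P)) break
  }
  sort_labels(g$labels[C])
}

#' Peel vertices of insufficient degree
#'
#' With a known lower bound `k` on the maximum clique size, any vertex of
#' degree `< k - 1` cannot be in a clique of size `k` and is removed;
#' removals cascade until a fixed point.
#'
#' @param g An `mce_graph`.
#' @param k Clique-size lower bound (`>= 1`).
#' @return A list with `graph` (the peeled graph) and `removed` (a data
#'   frame of removed vertex labels and the rule tag `"low_degree"`).
#' @export
peel_low_degree <- function(g, k) {
  stopifnot(k >= 1)
  removed <- character(0)
  repeat {
    low <- g$labels[lengths(g$adj) < k - 1]
    if (!length(low)) break
    removed <- c(removed, low)
    g <- remove_vertex(g, low)
  }
  list(graph = g, removed = reduction_log(removed, "low_degree"))
}

#' Extract universal vertices
#'
#' A vertex adjacent to all other vertices (degree `n - 1`) belongs to every
#' maximum clique; such vertices are moved to a `forced` list and removed,
#' repeatedly, so the branching search runs on the residual graph only.
#' Every clique reported downstream re-attaches the forced vertices.
#'
#' @param g An `mce_graph`.
#' @return A list with `graph` (residual) and `forced` (character vector of
#'   universal vertex labels, possibly empty).
#' @export
extract_universal <- function(g) {
  forced <- character(0)
  repeat {
    if (g$n <= 1L) break
    uni <- g$labels[lengths(g$adj) == g$n - 1L]
    if (!length(uni)) break
    forced <- c(forced, uni)
    g <- remove_vertex(g, uni)
  }
  list(graph = g, forced = sort_labels(forced))
}

# first-fit greedy coloring of the induced subgraph on `idx` (internal
# indices); vertices considered in descending induced degree, ties by lowest
# index.  Returns the number of colors used -- an upper bound on the clique
# number of that subgraph.
greedy_color_count <- function(g, nb, idx) {
  if (!length(idx)) return(0L)
  deg <- vapply(idx, function(v) sum(nb[[v]][idx]), 0L)
  ord <- idx[order(-deg, idx)]
  color <- integer(g$n)
  ncol <- 0L
  for (v in ord) {
    used <- unique(color[idx[nb[[v]][idx] & color[idx] > 0L]])
    cv <- 1L
    while (cv %in% used) cv <- cv + 1L
    color[v] <- cv
    if (cv > ncol) ncol <- cv
  }
  ncol
}

#' Coloring-based vertex exclusion
#'
#' For each vertex `v`, greedily color the closed neighborhood of `v`
#' (first-fit, descending degree).  If fewer than `k` colors suffice then no
#' clique of size `k` contains `v` (a `k`-clique needs `k` distinct colors),
#' so `v` is removed.  Passes repeat until one removes nothing.
#'
#' @param g An `mce_graph`.
#' @param k Clique-size lower bound (`>= 1`).
#' @return A list with `graph` and `removed` (data frame with rule tag
#'   `"color"`).
#' @export
color_exclude <- function(g, k) {
  stopifnot(k >= 1)
  removed <- character(0)
  repeat {
    nb <- neighbor_masks(g)
    drop <- logical(g$n)
    for (v in seq_len(g$n)) {
      closed <- c(v, g$adj[[v]])
      if (greedy_color_count(g, nb, closed) < k) drop[v] <- TRUE
    }
    if (!any(drop)) break
    removed <- c(removed, g$labels[drop])
    g <- induce_idx(g, which(!drop))
  }
  list(graph = g, removed = reduction_log(removed, "color"))
}

# small helper shared by the preprocessing rules
reduction_log <- function(vertices, rule) {
  data.frame(vertex = as.character(vertices), rule = rep(rule, length(vertices)),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Branching search

# In-or-out vertex branching shared by find_maximum_clique (single witness)
# and the parameterized enumerator (all maximum cliques).
#
# mode "single": prune branches with |C| + |P| <= best; apply the degree
#   n-2 lone-non-neighbor rule (sound only when one witness is wanted).
# mode "all": prune strictly (< k) so ties survive; keep a global list that
#   is flushed whenever a strictly larger clique turns up; no n-2 rule.
branch_search <- function(g, k_init, mode = c("single", "all"),
                          budget_nodes = NULL, use_n2_rule = TRUE) {
  mode <- match.arg(mode)
  nb <- neighbor_masks(g)
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$halted <- FALSE
  env$best <- as.integer(k_init)
  env$witness <- NULL
  env$found <- list()

  record <- function(C) {
    if (mode == "single") {
      if (length(C) > env$best) {
        env$best <- length(C)
        env$witness <- C
      }
    } else {
      if (length(C) > env$best) {
        env$best <- length(C)
        env$found <- list(C)       # larger clique: flush and refresh
      } else if (length(C) == env$best) {
        env$found[[length(env$found) + 1L]] <- C
      }
    }
  }

  can_prune <- function(total) {
    if (mode == "single") total <= env$best else total < env$best
  }

  recurse <- function(C, P) {
    env$nodes <- env$nodes + 1L
    if (!is.null(budget_nodes) && env$nodes > budget_nodes) {
      env$halted <- TRUE
      return(invisible(NULL))
    }
    repeat {
      if (can_prune(length(C) + length(P))) return(invisible(NULL))
      if (!length(P)) {
        record(C)
        return(invisible(NULL))
      }
      changed <- FALSE
      # common-neighbor counts inside P
      cnt <- vapply(P, function(v) sum(nb[[v]][P]), 0L)
      # low-degree rule relative to the bound: v cannot head a good clique
      need <- env$best - length(C) - 1L   # neighbors v needs inside P
      lim <- if (mode == "single") need else need - 1L
      dropv <- cnt < lim
      if (any(dropv)) {
        P <- P[!dropv]
        changed <- TRUE
      } else {
        # universal-in-P rule: v adjacent to all of P \ {v} must join C
        uni <- P[cnt == length(P) - 1L]
        if (length(uni)) {
          C <- c(C, uni[1])
          P <- P[nb[[uni[1]]][P]]
          changed <- TRUE
        } else if (mode == "single" && use_n2_rule) {
          # degree n-2 rule: v missing exactly one neighbor in P; its lone
          # non-neighbor can be discarded when only one witness is wanted
          n2 <- which(cnt == length(P) - 2L)
          if (length(n2)) {
            v <- P[n2[1]]
            lone <- P[!nb[[v]][P] & P != v]
            P <- P[P != lone[1]]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    # branch vertex: most neighbors inside P, ties by lowest index
    cnt <- vapply(P, function(v) sum(nb[[v]][P]), 0L)
    v <- P[order(-cnt, P)][1]
    recurse(c(C, v), P[nb[[v]][P]])            # v in the clique
    if (env$halted) return(invisible(NULL))
    recurse(C, P[P != v])                      # v out of the clique
    invisible(NULL)
  }

  if (g$n) recurse(integer(0), seq_len(g$n))
  list(
    best = env$best,
    witness = env$witness,
    found = env$found,
    nodes = env$nodes,
    status = if (env$halted) "halted" else "complete"
  )
}

#' Find one maximum clique and the clique number
#'
#' The full Maximum Clique Finder pipeline: greedy lower bound, universal
#' vertex extraction, low-degree peeling, optional coloring exclusion at the
#' root, then recursive in-or-out vertex branching with the bound
#' \eqn{|C| + |P| \le k_{best}} pruning.  Because only one witness is
#' needed, the degree \eqn{n-2} lone-non-neighbor rule is also applied
#' during branching; it must be (and is) disabled when all maximum cliques
#' are wanted (see [enumerate_maximum_cliques()]).
#'
#' @param g An `mce_graph`.
#' @param root_color Apply [color_exclude()] once at the root (default
#'   `TRUE`); per-node coloring is not done, as its cost exceeds its benefit
#'   on small residual graphs.
#' @param use_n2_rule Apply the degree \eqn{n-2} rule during branching
#'   (default `TRUE`; valid only for a single witness).
#' @return An object of class `mcf_result`: `clique` (character vector),
#'   `k` (its size, equal to the clique number \eqn{\omega(G)}), `nodes`
#'   (branching nodes), and `log` (a data frame of preprocessing removals).
#' @examples
#' find_maximum_clique(clique_sensitivity_graph("a"))$clique  # "1" "2" "3" "4" "5"
#' @export
find_maximum_clique <- function(g, root_color = TRUE, use_n2_rule = TRUE) {
  if (g$n == 0L) {
    return(structure(list(clique = character(0), k = 0L, nodes = 0L,
                          log = reduction_log(character(0), character(0))),
                     class = "mcf_result"))
  }
  C0 <- greedy_clique(g)
  k <- length(C0)
  log <- reduction_log(character(0), character(0))

  uni <- extract_universal(g)
  forced <- uni$forced
  h <- uni$graph
  k_res <- k - length(forced)      # bound translated to the residual graph

  if (k_res >= 1) {
    pl <- peel_low_degree(h, k_res)
    h <- pl$graph
    log <- rbind(log, pl$removed)
    if (root_color && k_res >= 2 && h$n) {
      ce <- color_exclude(h, k_res)
      h <- ce$graph
      log <- rbind(log, ce$removed)
    }
  }

  bs <- branch_search(h, k_init = max(k_res, 0L), mode = "single",
                      use_n2_rule = use_n2_rule)
  if (!is.null(bs$witness)) {
    clique <- sort_labels(c(forced, h$labels[bs$witness]))
  } else {
    clique <- C0                    # greedy clique was already optimal
  }
  structure(
    list(clique = clique, k = length(clique), nodes = bs$nodes, log = log),
    class = "mcf_result"
  )
}

#' @export
print.mcf_result <- function(x, ...) {
  cat("<mcf_result> k = ", x$k, "; clique: ",
      paste(x$clique, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Clique number of a graph
#'
#' Convenience wrapper returning just \eqn{\omega(G)} from
#' [find_maximum_clique()].
#' @param g An `mce_graph`.
#' @return Integer clique number.
#' @export
clique_number <- function(g) find_maximum_clique(g)$k
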