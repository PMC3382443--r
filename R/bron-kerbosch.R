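# Bron-Kerbosch backtracking over the COMPSUB / CANDIDATES / NOT triple.
#
# This is the improved (second) variant: a pivot vertex u is chosen from
# CANDIDATES %union% NOT so that as many candidates as possible are adjacent
# to it, and only candidates NOT adjacent to u are branched on.  A branch in
# which some member of NOT is adjacent to every candidate therefore dies
# without recursing, which is exactly the early-termination rule that keeps
# duplicate maximal cliques from being generated.

# Per-vertex neighbor membership masks; O(n^2) logical storage, built once
# per enumeration.  For the graph sizes the R kernels are run on this is the
# fastest way to intersect a neighborhood with an arbitrary vertex set.
neighbor_masks <- function(g) {
  n <- g$n
  lapply(g$adj, function(a) {
    x <- logical(n)
    x[a] <- TRUE
    x
  })
}

# Shared recursion for basic and intelligent backtracking.  `min_size` is
# the clique-size cut: branches with |COMPSUB| + |CANDIDATES| < min_size are
# abandoned (NULL disables the cut, giving plain maximal enumeration).
bk_run <- function(g, min_size = NULL, budget_nodes = NULL, callback = NULL) {
  nb <- neighbor_masks(g)
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$halted <- FALSE
  env$out <- vector("list", 64L)
  env$nout <- 0L
  cut <- !is.null(min_size)

  emit <- function(members) {
    if (env$nout == length(env$out)) length(env$out) <- 2L * length(env$out)
    env$nout <- env$nout + 1L
    env$out[[env$nout]] <- members
    if (!is.null(callback)) callback(g$labels[members])
  }

  extend <- function(compsub, cand, notv) {
    env$nodes <- env$nodes + 1L
    if (!is.null(budget_nodes) && env$nodes > budget_nodes) {
      env$halted <- TRUE
      return(invisible(NULL))
    }
    if (cut && length(compsub) + length(cand) < min_size) return(invisible(NULL))
    if (!length(cand)) {
      if (!length(notv)) emit(compsub)
      return(invisible(NULL))
    }
    # pivot: vertex of CANDIDATES %union% NOT with most neighbors in
    # CANDIDATES; ties broken by lowest internal index
    pool <- sort(c(cand, notv))
    best_u <- pool[1]
    best_cnt <- -1L
    for (u in pool) {
      cnt <- sum(nb[[u]][cand])
      if (cnt > best_cnt) {
        best_cnt <- cnt
        best_u <- u
      }
      if (best_cnt == length(cand)) break
    }
    if (best_cnt == length(cand) && best_u %in% notv) return(invisible(NULL))
    branch <- cand[!nb[[best_u]][cand]]
    for (v in branch) {
      if (env$halted) return(invisible(NULL))
      nbv <- nb[[v]]
      new_cand <- cand[nbv[cand]]
      # with the clique-size cut, a child that cannot reach min_size is
      # never visited at all (it contributes no search node)
      if (!cut || length(compsub) + 1L + length(new_cand) >= min_size) {
        extend(c(compsub, v), new_cand, notv[nbv[notv]])
      }
      cand <- cand[cand != v]
      notv <- c(notv, v)
    }
    invisible(NULL)
  }

  if (g$n) extend(integer(0), seq_len(g$n), integer(0))
  list(
    cliques = env$out[seq_len(env$nout)],
    nodes = env$nodes,
    status = if (env$halted) "halted" else "complete"
  )
}

#' Enumerate all maximal cliques (Bron-Kerbosch backtracking)
#'
#' Depth-first enumeration of every maximal clique of a graph using the
#' classic three-set (COMPSUB / CANDIDATES / NOT) recursion with pivot-based
#' pruning.  A graph on \eqn{n} vertices can hold up to \eqn{3^{n/3}}
#' maximal cliques (attained by the Moon-Moser graphs), so exhaustive
#' enumeration is used here mainly as the benchmark that the maximum-clique
#' strategies in [enumerate_maximum_cliques()] improve on.
#'
#' @param g An `mce_graph`.
#' @param budget_nodes Optional cap on the number of search-tree nodes; when
#'   exhausted the run stops with `status = "halted"` and the cliques found
#'   so far.
#' @param callback Optional function called with each maximal clique (a
#'   character vector of labels) as it is emitted, for streaming output.
#' @return An object of class `maximal_cliques`: a list with `cliques` (a
#'   [clique_set()]), `nodes` (search-tree node count), and `status`
#'   (`"complete"` or `"halted"`).
#' @examples
#' g <- mce_graph(cbind(c("1", "2"), c("2", "3")))
#' enumerate_maximal_cliques(g)$cliques  # {1 2}, {2 3}
#' @export
enumerate_maximal_cliques <- function(g, budget_nodes = NULL, callback = NULL) {
  res <- bk_run(g, min_size = NULL, budget_nodes = budget_nodes, callback = callback)
  structure(
    list(
      cliques = clique_set(lapply(res$cliques, function(m) g$labels[m])),
      nodes = res$nodes,
      status = res$status
    ),
    class = "maximal_cliques"
  )
}

#' @export
print.maximal_cliques <- function(x, ...) {
  cat("<maximal_cliques> ", length(x$cliques), " clique(s), ",
      x$nodes, " search nodes, status: ", x$status, "\n", sep = "")
  invisible(x)
}
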