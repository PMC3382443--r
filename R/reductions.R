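# Maximum clique covers (MCC) and essential vertex sets (ES): reductions
# that shrink a graph while preserving every maximum clique.  Both exploit
# the structure typical of thresholded correlation graphs, where maximum
# cliques overlap heavily -- very often a single maximum clique covers all
# of them.

#' Greedy maximum clique cover
#'
#' A maximum clique cover is a vertex set that intersects every maximum
#' clique of the graph.  This computes one greedily: find a maximum clique
#' with [find_maximum_clique()], delete its vertices, and iterate until the
#' clique number of the residual drops below the original \eqn{\omega(G)}.
#' The union of the disjoint maximum cliques so collected covers every
#' maximum clique, since any maximum clique must intersect a maximal family
#' of pairwise disjoint ones.
#'
#' @param g An `mce_graph`.
#' @return An object of class `cover_report`: `cover` (character vector of
#'   cover vertices), `disjoint_cliques` (a [clique_set()] of the pairwise
#'   disjoint maximum cliques, each of size `k`), `removed` (vertices deleted
#'   while iterating), and `k` (the clique number of `g`).
#' @export
mcc_cover <- function(g) {
  k <- find_maximum_clique(g)$k
  cliques <- list()
  residual <- g
  removed <- character(0)
  while (residual$n) {
    res <- find_maximum_clique(residual)
    if (res$k < k) break
    cliques[[length(cliques) + 1L]] <- res$clique
    removed <- c(removed, res$clique)
    residual <- remove_vertex(residual, res$clique)
  }
  structure(
    list(cover = sort_labels(unlist(cliques, use.names = FALSE)),
         disjoint_cliques = clique_set(cliques),
         removed = sort_labels(removed),
         k = k),
    class = "cover_report"
  )
}

#' @export
print.cover_report <- function(x, ...) {
  cat("<cover_report> k = ", x$k, "; ", length(x$disjoint_cliques),
      " disjoint maximum clique(s); cover size ", length(x$cover), "\n", sep = "")
  invisible(x)
}

#' Reduce a graph by a maximum clique cover
#'
#' Any vertex that is neither in a maximum clique cover nor adjacent to at
#' least one cover member cannot lie in a maximum clique and is removed.
#' Every maximum clique of the input survives in the output.
#'
#' @param g An `mce_graph`.
#' @return A list with `graph` (the reduced graph) and `report` (the
#'   [mcc_cover()] `cover_report`, with `removed` replaced by the vertices
#'   this reduction deleted).
#' @export
mcc_reduce <- function(g) {
  cr <- mcc_cover(g)
  cover_idx <- vertex_index(g, cr$cover)
  keep <- logical(g$n)
  keep[cover_idx] <- TRUE
  for (v in cover_idx) keep[g$adj[[v]]] <- TRUE
  cr$removed <- sort_labels(g$labels[!keep])
  list(graph = induce_idx(g, which(keep)), report = cr)
}

#' Essential vertex set
#'
#' An essential vertex is one contained in every maximum clique,
#' characterized by \eqn{\omega(G) > \omega(G - v)}: deleting it lowers the
#' clique number if and only if it covers all maximum cliques.  Since every
#' essential vertex lies in every maximum clique, it suffices to test only
#' the members of one maximum clique found by the Maximum Clique Finder —
#' \eqn{k} deletion tests instead of \eqn{n}.
#'
#' @param g An `mce_graph`.
#' @return An object of class `essential_report`: `essential` (character
#'   vector, possibly empty), `k` (the clique number of `g`), and `witness`
#'   (the maximum clique whose members were tested).
#' @examples
#' # two triangles sharing an edge: the shared edge is essential
#' g <- mce_graph(cbind(c("a","a","b","a","b"), c("b","c","c","d","d")))
#' essential_set(g)$essential  # "a" "b"
#' @export
essential_set <- function(g) {
  res <- find_maximum_clique(g)
  k <- res$k
  essential <- character(0)
  if (k >= 1 && g$n > 1L) {
    for (v in res$clique) {
      if (find_maximum_clique(remove_vertex(g, v))$k < k) {
        essential <- c(essential, v)
      }
    }
  } else if (k == 1L && g$n == 1L) {
    essential <- g$labels
  }
  structure(
    list(essential = sort_labels(essential), k = k, witness = res$clique),
    class = "essential_report"
  )
}

#' @export
print.essential_report <- function(x, ...) {
  cat("<essential_report> k = ", x$k, "; ", length(x$essential),
      " essential vertex(es)",
      if (length(x$essential)) paste0(": ", paste(x$essential, collapse = " ")),
      "\n", sep = "")
  invisible(x)
}

#' Essential Set (ES) reduction
#'
#' Finds all essential vertices and removes every non-neighbor of each of
#' them.  A non-neighbor of an essential vertex cannot be in any maximum
#' clique (all maximum cliques contain the essential vertex), so the output
#' graph contains exactly the maximum cliques of the input.  Essential
#' vertices are mutually adjacent (they share every maximum clique), so no
#' essential vertex is ever removed.
#'
#' @param g An `mce_graph`.
#' @param iterate Re-run the reduction on its own output until a fixed
#'   point (default `FALSE`; a single pass already preserves all maximum
#'   cliques, iteration is purely an optimization).
#' @return A list with `graph` (reduced graph) and `report` (the
#'   `essential_report`, with a `removed` field added).
#' @export
es_reduce <- function(g, iterate = FALSE) {
  removed_all <- character(0)
  first_report <- NULL
  repeat {
    er <- essential_set(g)
    if (is.null(first_report)) first_report <- er
    if (!length(er$essential)) break
    ess_idx <- vertex_index(g, er$essential)
    keep <- logical(g$n)
    keep[ess_idx] <- TRUE                       # never remove an essential vertex
    common <- !logical(g$n)
    for (v in ess_idx) {
      nbm <- logical(g$n)
      nbm[g$adj[[v]]] <- TRUE
      nbm[v] <- TRUE
      common <- common & nbm                    # neighbors of every essential vertex
    }
    keep <- keep | common
    removed <- g$labels[!keep]
    if (!length(removed)) break
    removed_all <- c(removed_all, removed)
    g <- induce_idx(g, which(keep))
    if (!iterate) break
  }
  first_report$removed <- sort_labels(removed_all)
  list(graph = g, report = first_report)
}

#' Coloring reduction at a known clique number
#'
#' Convenience wrapper: computes \eqn{k = \omega(G)} with
#' [find_maximum_clique()] and applies [color_exclude()] with it.  With the
#' true clique number, no vertex of any maximum clique is ever removed.
#'
#' @param g An `mce_graph`.
#' @return A list with `graph` and `report` (data frame of removals plus the
#'   `k` used).
#' @export
color_reduce <- function(g) {
  k <- find_maximum_clique(g)$k
  if (k < 2) return(list(graph = g, report = list(k = k, removed = character(0))))
  ce <- color_exclude(g, k)
  list(graph = ce$graph, report = list(k = k, removed = ce$removed$vertex))
}
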