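# Simple undirected graph container used by every algorithm in the package.
#
# Vertices carry opaque string labels externally; internally they are mapped
# to dense 1-based integer indices in a fixed, deterministic order (numeric
# order when every label parses as an integer, lexicographic otherwise).
# All algorithms iterate in ascending internal index order, so results are
# reproducible for a given labelled graph.

# Deterministic label order: numeric when all labels are integral strings.
label_order <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num) && all(num == trunc(num))) order(num, labels) else order(labels)
}

sort_labels <- function(labels) labels[label_order(labels)]

new_mce_graph <- function(labels, adj) {
  stopifnot(is.character(labels), is.list(adj), length(adj) == length(labels))
  g <- list(
    labels = labels,
    adj = adj,
    n = length(labels),
    m = sum(lengths(adj)) %/% 2L
  )
  class(g) <- "mce_graph"
  g
}

#' Construct a simple undirected graph from an edge list
#'
#' Builds the graph container shared by all clique algorithms in the package:
#' a finite simple undirected graph with string vertex labels.  Duplicate and
#' reversed edge pairs collapse to a single edge; self-loops are rejected.
#'
#' @param edges A two-column matrix or data frame of vertex labels (one edge
#'   per row), or `NULL` for an edgeless graph.
#' @param vertices Optional character vector of vertex labels; must include
#'   every endpoint in `edges`.  Use this to carry isolated vertices.
#' @return An object of class `mce_graph` with fields `labels` (vertex
#'   labels in canonical order), `adj` (adjacency lists of integer indices),
#'   `n` (vertex count) and `m` (edge count).
#' @examples
#' g <- mce_graph(cbind(c("1", "2"), c("2", "3")))
#' n_vertices(g)  # 3
#' n_edges(g)     # 2
#' @seealso [read_graph()], [remove_vertex()], [is_clique()]
#' @export
mce_graph <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges)) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2) stop("`edges` must have exactly two columns")
    storage.mode(em) <- "character"
  }
  labels <- unique(c(as.character(vertices), em[, 1], em[, 2]))
  if (anyNA(labels)) stop("vertex labels must not be NA")
  labels <- sort_labels(labels)
  if (nrow(em) && any(em[, 1] == em[, 2])) {
    bad <- which(em[, 1] == em[, 2])[1]
    stop("self-loop on vertex '", em[bad, 1], "' is not allowed")
  }
  i <- match(em[, 1], labels)
  j <- match(em[, 2], labels)
  adj <- rep(list(integer(0)), length(labels))
  if (length(i)) {
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    keep <- !duplicated(cbind(lo, hi))
    lo <- lo[keep]
    hi <- hi[keep]
    for (v in seq_along(labels)) adj[[v]] <- sort(c(hi[lo == v], lo[hi == v]))
  }
  new_mce_graph(labels, adj)
}

#' @export
print.mce_graph <- function(x, ...) {
  cat("<mce_graph> ", x$n, " vertices, ", x$m, " edges\n", sep = "")
  if (x$n) {
    shown <- head(x$labels, 10L)
    cat("vertices: ", paste(shown, collapse = " "),
        if (x$n > 10L) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Number of vertices / edges of a graph
#' @param g An `mce_graph`.
#' @return An integer count.
#' @export
n_vertices <- function(g) g$n

#' @rdname n_vertices
#' @export
n_edges <- function(g) g$m

#' Vertex labels in canonical order
#' @param g An `mce_graph`.
#' @return Character vector of labels.
#' @export
vertex_names <- function(g) g$labels

# label -> internal index, with a domain error on absent vertices
vertex_index <- function(g, v) {
  idx <- match(as.character(v), g$labels)
  if (anyNA(idx)) {
    stop("vertex '", as.character(v)[which(is.na(idx))[1]], "' is not in the graph")
  }
  idx
}

#' Vertex degrees
#' @param g An `mce_graph`.
#' @param v Optional vertex labels; defaults to all vertices.
#' @return Named integer vector of degrees.
#' @export
graph_degree <- function(g, v = NULL) {
  idx <- if (is.null(v)) seq_len(g$n) else vertex_index(g, v)
  d <- lengths(g$adj)[idx]
  names(d) <- g$labels[idx]
  d
}

#' Neighbors of a vertex
#' @param g An `mce_graph`.
#' @param v A single vertex label.
#' @return Character vector of neighbor labels.
#' @export
graph_neighbors <- function(g, v) {
  g$labels[g$adj[[vertex_index(g, v)]]]
}

#' Test whether an edge is present
#' @param g An `mce_graph`.
#' @param u,v Vertex labels.
#' @return Logical.
#' @export
has_edge <- function(g, u, v) {
  iu <- vertex_index(g, u)
  iv <- vertex_index(g, v)
  iv %in% g$adj[[iu]]
}

# induced subgraph on internal indices `keep` (sorted), relabelled to the
# original labels -- the workhorse behind remove_vertex and the reductions
induce_idx <- function(g, keep) {
  keep <- sort(unique(as.integer(keep)))
  newid <- integer(g$n)
  newid[keep] <- seq_along(keep)
  adj <- lapply(g$adj[keep], function(a) newid[a[newid[a] > 0L]])
  new_mce_graph(g$labels[keep], adj)
}

#' Delete vertices from a graph
#'
#' Returns a new graph without the named vertices and without any incident
#' edges; the input graph is unchanged.  Deleting a vertex can only lower the
#' maximum clique size, which is what the essential-vertex test
#' \eqn{\omega(G) > \omega(G - v)} exploits.
#'
#' @param g An `mce_graph`.
#' @param v Vertex labels to delete (one or more).
#' @return A new `mce_graph`.
#' @export
remove_vertex <- function(g, v) {
  idx <- vertex_index(g, v)
  induce_idx(g, setdiff(seq_len(g$n), idx))
}

#' Delete an edge from a graph
#'
#' Returns a new graph without the edge `{u, v}`; both endpoints remain.
#' Deleting a single edge can reshape the maximum clique landscape
#' dramatically — see [clique_sensitivity_graph()].
#'
#' @param g An `mce_graph`.
#' @param u,v Vertex labels of an existing edge.
#' @return A new `mce_graph`.
#' @export
remove_edge <- function(g, u, v) {
  iu <- vertex_index(g, u)
  iv <- vertex_index(g, v)
  if (!(iv %in% g$adj[[iu]])) {
    stop("edge {", u, ", ", v, "} is not in the graph")
  }
  g$adj[[iu]] <- g$adj[[iu]][g$adj[[iu]] != iv]
  g$adj[[iv]] <- g$adj[[iv]][g$adj[[iv]] != iu]
  g$m <- g$m - 1L
  g
}

#' Induced subgraph on a vertex subset
#' @param g An `mce_graph`.
#' @param v Vertex labels to keep.
#' @return A new `mce_graph` on exactly those vertices.
#' @export
induced_subgraph <- function(g, v) {
  induce_idx(g, vertex_index(g, v))
}

#' Test whether a vertex set is a clique
#'
#' A clique is a fully connected subgraph: every pair of members must be
#' adjacent.  Sets of size 0 or 1 are vacuously cliques.
#'
#' @param g An `mce_graph`.
#' @param s Character vector of vertex labels (must all be in the graph).
#' @return Logical.
#' @export
is_clique <- function(g, s) {
  idx <- unique(vertex_index(g, s))
  if (length(idx) <= 1L) return(TRUE)
  for (a in seq_along(idx)) {
    rest <- idx[-seq_len(a)]
    if (!all(rest %in% g$adj[[idx[a]]])) return(FALSE)
  }
  TRUE
}

# internal sanity assertions, used in tests and after parsing
validate_graph <- function(g) {
  stopifnot(inherits(g, "mce_graph"))
  for (v in seq_len(g$n)) {
    a <- g$adj[[v]]
    if (v %in% a) stop("self-loop at vertex ", g$labels[v])
    if (is.unsorted(a, strictly = TRUE)) stop("adjacency list not strictly sorted")
    for (u in a) if (!(v %in% g$adj[[u]])) stop("asymmetric adjacency")
  }
  if (g$m != sum(lengths(g$adj)) %/% 2L) stop("edge count out of sync")
  invisible(g)
}

# ---------------------------------------------------------------------------
# File I/O

#' Read a graph from a file
#'
#' Two plain-text formats are supported: a whitespace-separated edge list
#' (one `u v` pair per line, `#` comments allowed) and the DIMACS ascii
#' clique format (`c` comment lines, a `p edge <n> <m>` header, and
#' `e <u> <v>` edge lines with 1-based vertex numbers).
#'
#' @param path Path to the file (or a connection).
#' @param format `"edge_list"`, `"dimacs"`, or `"auto"` (DIMACS when the
#'   first non-comment line starts with `p `).
#' @return An `mce_graph`.
#' @export
read_graph <- function(path, format = c("auto", "edge_list", "dimacs")) {
  format <- match.arg(format)
  if (is.character(path) && !file.exists(path)) {
    stop("cannot open graph file '", path, "'")
  }
  lines <- readLines(path)
  if (format == "auto") {
    body <- grep("^\\s*(#|c( |$)|$)", lines, invert = TRUE)
    format <- if (length(body) && grepl("^\\s*p\\s", lines[body[1]])) "dimacs" else "edge_list"
  }
  if (format == "edge_list") parse_edge_list(lines) else parse_dimacs(lines)
}

parse_edge_list <- function(lines) {
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  edges <- matrix(character(0), ncol = 2)
  verts <- character(0)
  for (ln in keep) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) == 1L) {
      verts <- c(verts, tok)           # lone label: isolated vertex
    } else if (length(tok) == 2L) {
      edges <- rbind(edges, tok)
    } else {
      stop("edge list parse error at line ", ln, ": expected 'u v', got '",
           trimws(lines[ln]), "'")
    }
  }
  mce_graph(edges, vertices = verts)
}

parse_dimacs <- function(lines) {
  n <- NA_integer_
  m_decl <- NA_integer_
  edges <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "c")) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "p") {
      if (length(tok) != 4L || tok[2] != "edge") {
        stop("dimacs parse error at line ", ln, ": bad problem line")
      }
      n <- as.integer(tok[3])
      m_decl <- as.integer(tok[4])
    } else if (tok[1] == "e") {
      if (length(tok) != 3L) stop("dimacs parse error at line ", ln, ": bad edge line")
      u <- as.integer(tok[2])
      v <- as.integer(tok[3])
      if (is.na(u) || is.na(v)) stop("dimacs parse error at line ", ln, ": non-integer vertex")
      if (is.na(n)) stop("dimacs parse error at line ", ln, ": edge before problem line")
      if (u < 1L || u > n || v < 1L || v > n) {
        stop("dimacs parse error at line ", ln, ": vertex out of range 1..", n)
      }
      edges[[length(edges) + 1L]] <- c(u, v)
    } else {
      stop("dimacs parse error at line ", ln, ": unknown line type '", tok[1], "'")
    }
  }
  if (is.na(n)) stop("dimacs format error: missing 'p edge' header")
  em <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2)
  g <- mce_graph(matrix(as.character(em), ncol = 2), vertices = as.character(seq_len(n)))
  if (!is.na(m_decl) && g$m != m_decl) {
    stop("dimacs format error: header declares ", m_decl, " edges but ",
         g$m, " distinct edges were read")
  }
  g
}

#' Write a graph to a file
#'
#' @param g An `mce_graph`.
#' @param path Output path or connection.
#' @param format `"edge_list"` or `"dimacs"`.  Isolated vertices are written
#'   as lone labels in edge-list format; DIMACS carries them via the header
#'   count (labels are replaced by 1-based canonical indices).
#' @return Invisibly, `g`.
#' @export
write_graph <- function(g, path, format = c("edge_list", "dimacs")) {
  format <- match.arg(format)
  lines <- character(0)
  if (format == "edge_list") {
    for (v in seq_len(g$n)) {
      nb <- g$adj[[v]]
      nb <- nb[nb > v]
      if (length(nb)) lines <- c(lines, paste(g$labels[v], g$labels[nb]))
    }
    iso <- which(lengths(g$adj) == 0L)
    lines <- c(lines, g$labels[iso])
  } else {
    lines <- paste("p edge", g$n, g$m)
    for (v in seq_len(g$n)) {
      nb <- g$adj[[v]]
      nb <- nb[nb > v]
      if (length(nb)) lines <- c(lines, paste("e", v, nb))
    }
  }
  writeLines(lines, path)
  invisible(g)
}
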