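# Canonical, duplicate-free collections of cliques.
#
# A clique is stored as a character vector of vertex labels sorted in the
# graph's canonical label order; a collection is sorted lexicographically by
# those sorted member sequences.  This makes every collection produced by the
# package (and everything written to disk) bit-reproducible.

#' Build a canonical clique collection
#'
#' @param cliques A list of character vectors of vertex labels.
#' @return An object of class `clique_set`: a list of sorted label vectors in
#'   canonical order, with duplicates removed.  The attribute `uniform_size`
#'   holds the common cardinality when all cliques have one (e.g. for
#'   maximum-clique collections), otherwise `NA`.
#' @export
clique_set <- function(cliques = list()) {
  cliques <- lapply(cliques, function(m) sort_labels(unique(as.character(m))))
  keys <- vapply(cliques, paste, "", collapse = "\x1f")
  cliques <- cliques[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  cliques <- cliques[order(keys)]
  sizes <- lengths(cliques)
  us <- if (length(sizes) && length(unique(sizes)) == 1L) sizes[1] else NA_integer_
  structure(cliques, uniform_size = us, class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat("<clique_set> ", length(x), " clique(s)",
      if (!is.na(attr(x, "uniform_size"))) {
        paste0(", uniform size ", attr(x, "uniform_size"))
      }, "\n", sep = "")
  for (cl in head(unclass(x), 10L)) cat(" ", paste(cl, collapse = " "), "\n")
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
format.clique_set <- function(x, ...) {
  vapply(unclass(x), paste, "", collapse = " ")
}

# set equality of two collections (both already canonical)
same_cliques <- function(a, b) {
  identical(format(clique_set(a)), format(clique_set(b)))
}

#' Write a clique collection
#'
#' One clique per line, members sorted by label, lines in canonical
#' collection order; output is bit-identical across runs.
#'
#' @param cliques A `clique_set` (or list coercible to one).
#' @param path Output path or connection.
#' @return Invisibly, the canonical `clique_set` written.
#' @export
write_cliques <- function(cliques, path) {
  cs <- clique_set(cliques)
  writeLines(format(cs), path)
  invisible(cs)
}

#' Read a clique collection written by [write_cliques()]
#' @param path Input path or connection.
#' @return A `clique_set`.
#' @export
read_cliques <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  clique_set(strsplit(trimws(lines), "\\s+"))
}
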