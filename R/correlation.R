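# Building unweighted graphs from expression matrices: Pearson correlation
# (or correlation p-values, preferred when values are missing) across
# experimental conditions, then thresholding "at or above" t.

#' Construct an expression matrix
#'
#' A probes-by-conditions numeric table with an explicit `NA` missing
#' marker.  Graphs built from correlations over very few conditions carry
#' high false positive/negative rates, so fewer than 12 conditions triggers
#' a prominent warning (an error with `strict = TRUE`); toy inputs still
#' run.
#'
#' @param values Numeric matrix, rows = probes, columns = conditions, with
#'   unique row and column names (names are generated when absent).
#' @param strict Error rather than warn when there are fewer than 12
#'   conditions.
#' @return An object of class `expression_matrix` wrapping the matrix.
#' @export
expression_matrix <- function(values, strict = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L) stop("an expression matrix needs at least 2 conditions")
  if (is.null(rownames(values))) rownames(values) <- paste0("probe", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("cond", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("probe ids must be unique")
  if (anyDuplicated(colnames(values))) stop("condition ids must be unique")
  if (ncol(values) < 12L) {
    msg <- paste0("only ", ncol(values), " conditions: correlations over fewer ",
                  "than 12 conditions are unreliable (high false edge rates)")
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  structure(list(values = values), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " probes x ",
      ncol(x$values), " conditions, ", sum(is.na(x$values)),
      " missing value(s)\n", sep = "")
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expected layout: header row of condition ids, first column of probe ids,
#' numeric cells; empty cells or `NA` mark missing values.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_matrix
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, strict = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                   na.strings = c("NA", ""), check.names = FALSE)
  expression_matrix(as.matrix(df), strict = strict)
}

#' Log-transform an expression matrix
#'
#' Replaces every non-missing value by its logarithm (base 2 by default, as
#' is conventional for microarray intensities); missing entries are
#' preserved.  Non-positive values are a domain error and are reported with
#' their probe and condition.
#'
#' @param x An `expression_matrix`.
#' @param base Logarithm base (2 or `exp(1)`).
#' @return A transformed `expression_matrix`.
#' @export
log_transform <- function(x, base = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("cannot log-transform non-positive value at probe '",
         rownames(v)[bad[1, 1]], "', condition '", colnames(v)[bad[1, 2]], "'")
  }
  x$values <- log(v, base = base)
  x
}

#' Pairwise Pearson correlations (or correlation p-values) between probes
#'
#' Computes, for every pair of probes, the Pearson correlation across
#' pairwise-complete conditions, or — with `weight_kind = "pvalue"` — the
#' two-sided p-value of the correlation under the null of zero correlation,
#' from the t transform \eqn{t = r\sqrt{(s-2)/(1-r^2)}} with \eqn{s - 2}
#' degrees of freedom (s = number of complete condition pairs).  Pairs with
#' fewer than 3 complete observations or zero variance have no defined
#' weight; they are omitted from the result and listed in the `omitted`
#' attribute.
#'
#' @param x An `expression_matrix`.
#' @param weight_kind `"correlation"` or `"pvalue"`.
#' @return An object of class `weighted_edge_set`: a data frame with columns
#'   `probe1`, `probe2`, `weight`, `support` (complete condition pairs), one
#'   row per unordered probe pair, plus attributes `weight_kind` and
#'   `omitted` (data frame of degenerate pairs and reasons).
#' @export
correlate <- function(x, weight_kind = c("correlation", "pvalue")) {
  stopifnot(inherits(x, "expression_matrix"))
  weight_kind <- match.arg(weight_kind)
  v <- x$values
  probes <- rownames(v)
  np <- nrow(v)
  # pairwise-complete correlations and per-pair support counts
  r <- suppressWarnings(cor(t(v), use = "pairwise.complete.obs"))
  support <- crossprod(!is.na(t(v)))
  ut <- upper.tri(r)
  i <- row(r)[ut]
  j <- col(r)[ut]
  rv <- r[ut]
  sv <- support[ut]
  ok <- !is.na(rv) & sv >= 3L
  omitted <- data.frame(
    probe1 = probes[i[!ok]], probe2 = probes[j[!ok]],
    reason = ifelse(sv[!ok] < 3L, "support < 3", "zero variance"),
    stringsAsFactors = FALSE
  )
  w <- rv[ok]
  if (weight_kind == "pvalue") {
    s <- sv[ok]
    tt <- w * sqrt((s - 2) / pmax(1 - w^2, 0))
    w <- 2 * pt(-abs(tt), df = s - 2)
    w[!is.finite(tt)] <- 0                # |r| = 1: p-value 0
  }
  res <- data.frame(
    probe1 = probes[i[ok]], probe2 = probes[j[ok]],
    weight = w, support = as.integer(sv[ok]),
    stringsAsFactors = FALSE
  )
  structure(res, weight_kind = weight_kind, omitted = omitted,
            probes = probes, class = c("weighted_edge_set", "data.frame"))
}

#' Threshold a weighted edge set into an unweighted graph
#'
#' For correlation weights, an edge is kept iff its weight is at or above
#' the threshold `t` (inclusive); for p-value weights the direction flips
#' and an edge is kept iff its weight is at or below `t`.  Thresholding is
#' on the signed correlation by default; set `absolute = TRUE` to threshold
#' on `|r|`.
#'
#' @param w A `weighted_edge_set` from [correlate()].
#' @param t Threshold, within the weight kind's range (`[-1, 1]` for
#'   correlations, `[0, 1]` for p-values).
#' @param drop_isolated Drop probes with no surviving edge (default keeps
#'   them as isolated vertices).
#' @param absolute Threshold `|weight|` instead of the signed weight
#'   (correlation kind only).
#' @return An `mce_graph`.
#' @export
threshold_graph <- function(w, t, drop_isolated = FALSE, absolute = FALSE) {
  stopifnot(inherits(w, "weighted_edge_set"))
  kind <- attr(w, "weight_kind")
  if (kind == "correlation") {
    if (t < -1 || t > 1) stop("correlation threshold must lie in [-1, 1]")
    val <- if (absolute) abs(w$weight) else w$weight
    keep <- val >= t
  } else {
    if (t < 0 || t > 1) stop("p-value threshold must lie in [0, 1]")
    keep <- w$weight <= t
  }
  edges <- cbind(w$probe1[keep], w$probe2[keep])
  vertices <- if (drop_isolated) unique(c(edges)) else attr(w, "probes")
  mce_graph(edges, vertices = vertices)
}

#' Build a thresholded correlation graph from an expression matrix
#'
#' One-call pipeline: optional log transform, [correlate()], then
#' [threshold_graph()].
#'
#' @inheritParams correlate
#' @inheritParams threshold_graph
#' @param log2_transform Log-transform the values first.
#' @return An `mce_graph`.
#' @export
build_correlation_graph <- function(x, t, weight_kind = c("correlation", "pvalue"),
                                    log2_transform = FALSE, drop_isolated = FALSE,
                                    absolute = FALSE) {
  if (log2_transform) x <- log_transform(x)
  threshold_graph(correlate(x, weight_kind), t,
                  drop_isolated = drop_isolated, absolute = absolute)
}
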