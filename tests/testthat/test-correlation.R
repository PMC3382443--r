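make_expr <- function(values, nr) {
  suppressWarnings(expression_matrix(matrix(values, nrow = nr, byrow = TRUE)))
}

test_that("log transform is base-2, keeps NA, rejects non-positive values", {
  x <- make_expr(c(8, 1, 4, NA, 2, 16), 2)
  lt <- log_transform(x)
  expect_equal(lt$values[1, ], c(3, 0, 2), ignore_attr = TRUE)
  expect_true(is.na(lt$values[2, 1]))

  bad <- make_expr(c(1, 0, 2, 1, 1, 1), 2)
  expect_error(log_transform(bad), "probe1.*cond2")
})

test_that("fewer than 12 conditions warns (or errors under strict)", {
  m <- matrix(1:20, nrow = 2)
  expect_warning(expression_matrix(m), "fewer than 12")
  expect_error(expression_matrix(m, strict = TRUE), "fewer than 12")
  expect_silent(expression_matrix(matrix(rnorm(24), nrow = 2)))
})

test_that("pearson weights match closed forms", {
  x <- make_expr(c(1, 2, 3, 2, 4, 6, 3, 2, 1), 3)
  w <- correlate(x)
  key <- paste(w$probe1, w$probe2)
  expect_equal(w$weight[key == "probe1 probe2"], 1.0)
  expect_equal(w$weight[key == "probe1 probe3"], -1.0)
  expect_equal(w$support, rep(3L, 3))
})

test_that("correlation p-values follow the t transform of r", {
  # frozen oracle: r = cor((1..5),(1,2,3,4,6)), t = r*sqrt(3/(1-r^2)),
  # p = 2*P(T_3 < -|t|) = 0.001901274660196 (cor.test agrees)
  x <- make_expr(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 6), 2)
  w <- correlate(x, "pvalue")
  expect_equal(w$weight, 0.001901274660196, tolerance = 1e-12)
  # perfectly correlated rows get p = 0
  x2 <- make_expr(c(1, 2, 3, 2, 4, 6), 2)
  expect_equal(correlate(x2, "pvalue")$weight, 0)
})

test_that("missing values use pairwise-complete observations; thin pairs drop", {
  v <- matrix(c(1, 2, 3, 4, 5,
                2, 4, NA, 8, 10,
                NA, NA, NA, 1, 2), nrow = 3, byrow = TRUE)
  x <- suppressWarnings(expression_matrix(v))
  w <- correlate(x)
  key <- paste(w$probe1, w$probe2)
  expect_equal(w$support[key == "probe1 probe2"], 4L)
  expect_equal(w$weight[key == "probe1 probe2"], 1.0)
  # probe3 has only 2 complete pairs with anyone: omitted and logged
  expect_false(any(grepl("probe3", key)))
  omitted <- attr(w, "omitted")
  expect_true(all(grepl("probe3", paste(omitted$probe1, omitted$probe2))))
  expect_true(all(omitted$reason == "support < 3"))
})

test_that("constant probes are omitted as zero variance", {
  x <- make_expr(c(1, 2, 3, 4, 5, 5, 5, 5), 2)
  w <- correlate(x)
  expect_equal(nrow(w), 0L)
  expect_equal(attr(w, "omitted")$reason, "zero variance")
})

test_that("thresholding is inclusive and direction flips for p-values", {
  x <- suppressWarnings(expression_matrix(rbind(
    a = c(1, 2, 3, 4),
    b = c(1.1, 2, 3.2, 3.9),
    c = c(2, 1, 4, 3)
  )))
  w <- correlate(x)
  key <- paste(w$probe1, w$probe2)
  t_ab <- w$weight[key == "a b"]
  g <- threshold_graph(w, t_ab)           # exactly at threshold: kept
  expect_true(has_edge(g, "a", "b"))
  g2 <- threshold_graph(w, t_ab + 1e-12)
  expect_false(has_edge(g2, "a", "b"))
  expect_equal(n_vertices(g), 3L)         # isolated vertices retained
  expect_error(threshold_graph(w, 1.5), "-1, 1")

  wp <- correlate(x, "pvalue")
  keyp <- paste(wp$probe1, wp$probe2)
  p_ab <- wp$weight[keyp == "a b"]
  gp <- threshold_graph(wp, p_ab)         # inclusive, small p survives
  expect_true(has_edge(gp, "a", "b"))
})

test_that("thresholding is monotone and correlate is affine-invariant", {
  x <- suppressWarnings(expression_matrix(matrix(rnorm(60), nrow = 5)))
  w <- correlate(x)
  prev <- Inf
  for (t in c(-1, -0.5, 0, 0.3, 0.8, 1)) {
    m <- n_edges(threshold_graph(w, t))
    expect_lte(m, prev)
    prev <- m
  }
  # positive-slope affine transform of a probe leaves correlations unchanged
  y <- x
  y$values[2, ] <- 3 * y$values[2, ] + 7
  expect_equal(correlate(y)$weight, w$weight)
  # complete data: pairwise-complete equals full-vector correlation
  full <- cor(t(x$values))
  expect_equal(w$weight[1], full[1, 2], ignore_attr = TRUE)
})

test_that("the expression TSV reader handles missing cells", {
  tf <- withr::local_tempfile(lines = c(
    paste(c("id", paste0("c", 1:4)), collapse = "\t"),
    "p1\t1\t2\t3\t4",
    "p2\t2\t\t6\t8",
    "p3\tNA\t1\t2\t3"
  ))
  x <- suppressWarnings(read_expression(tf))
  expect_equal(dim(x$values), c(3L, 4L))
  expect_equal(sum(is.na(x$values)), 2L)
  expect_identical(rownames(x$values), c("p1", "p2", "p3"))
})
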