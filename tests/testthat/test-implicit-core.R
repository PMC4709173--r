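test_that("plane_value is the signed dot product against the widget plane", {
  w <- plane_widget(c(0, 0, 0), c(0, 0, 1))
  expect_equal(plane_value(w, c(0, 0, 0)), 0)
  expect_equal(plane_value(w, c(0, 0, 3)), 3)
  expect_equal(plane_value(w, c(5, -2, -1)), -1)
  expect_error(plane_value(w, c(0, 0, NaN)), "non-finite")
  # normal is normalized on construction
  w2 <- plane_widget(c(1, 1, 1), c(0, 0, 10))
  expect_equal(sqrt(sum(w2$normal^2)), 1, tolerance = 1e-12)
  expect_equal(plane_value(w2, c(0, 0, 4)), 3)
})

test_that("widget corners must be coplanar with the widget plane", {
  co <- rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0))
  expect_silent(plane_widget(c(0, 0, 0), c(0, 0, 1), corners = co))
  co_bad <- co
  co_bad[1L, 3L] <- 0.5
  expect_error(plane_widget(c(0, 0, 0), c(0, 0, 1), corners = co_bad),
               "plane")
})

test_that("eval_expr folds min over unions and max over intersections", {
  a <- imp_leaf(plane_widget(c(0, 0, 0), c(0, 0, 1), id = 1))
  b <- imp_leaf(plane_widget(c(0, 0, -1), c(0, 0, 1), id = 2))
  p <- c(0, 0, -0.5)
  expect_equal(eval_expr(a, p), plane_value(a$widget, p))
  expect_equal(eval_expr(imp_union(a, b), p), -0.5)
  expect_equal(eval_expr(imp_intersection(a, b), p), 0.5)
})

test_that("classify maps signed values to region labels with an ON band", {
  w <- imp_leaf(plane_widget(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(classify(w, c(0, 0, -1), eps = 1e-9), "INSIDE")
  expect_equal(classify(w, c(0, 0, 0), eps = 1e-9), "ON")
  expect_equal(classify(w, c(0, 0, 3e-10), eps = 1e-9), "ON")
  expect_equal(classify(w, c(0, 0, 2), eps = 1e-9), "OUTSIDE")
  expect_error(classify(w, c(0, 0, 0), eps = 0), "positive")
})

test_that("reverse_widget negates the field and is an involution", {
  set.seed(11)
  w <- plane_widget(runif(3), runif(3) + 0.1)
  r <- reverse_widget(w)
  pts <- matrix(runif(30, -5, 5), ncol = 3L)
  expect_equal(plane_value(r, pts), -plane_value(w, pts))
  expect_equal(reverse_widget(r), w)
})

# random expression tree over `n` random widgets
random_expr <- function(n, widgets = NULL) {
  if (is.null(widgets))
    widgets <- lapply(seq_len(n), function(i)
      plane_widget(runif(3, -2, 2), runif(3, -1, 1) + 0.05, id = i))
  build <- function(ids) {
    if (length(ids) == 1L) return(imp_leaf(widgets[[ids]]))
    k <- if (length(ids) == 2L) 1L else sample(length(ids) - 1L, 1L)
    node <- if (runif(1) < 0.5) imp_union else imp_intersection
    node(build(ids[seq_len(k)]), build(ids[-seq_len(k)]))
  }
  build(seq_len(n))
}

test_that("eval_expr agrees with a brute-force fold on random trees", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:16, 1L)
    ex <- random_expr(n)
    pts <- matrix(runif(60, -4, 4), ncol = 3L)
    brute <- vapply(seq_len(nrow(pts)), function(i)
      oracle_eval(ex, pts[i, ]), numeric(1L))
    expect_equal(eval_expr(ex, pts), brute)
    expect_equal(expr_n_leaves(ex), n)
    expect_equal(expr_n_nodes(ex), n - 1L)
  }
})

test_that("union is a lower bound and intersection an upper bound", {
  set.seed(43)
  for (rep in 1:10) {
    l <- random_expr(sample(1:6, 1L))
    r <- random_expr(sample(1:6, 1L))
    pts <- matrix(runif(60, -4, 4), ncol = 3L)
    vu <- eval_expr(imp_union(l, r), pts)
    vi <- eval_expr(imp_intersection(l, r), pts)
    vl <- eval_expr(l, pts)
    vr <- eval_expr(r, pts)
    expect_true(all(vu <= vl + 1e-12 & vu <= vr + 1e-12))
    expect_true(all(vi >= vl - 1e-12 & vi >= vr - 1e-12))
    # idempotence at the value level
    expect_equal(eval_expr(imp_union(l, l), pts), vl)
    expect_equal(eval_expr(imp_intersection(l, l), pts), vl)
  }
})

test_that("De Morgan duality holds at the value level", {
  # negating all leaves and swapping ops negates the evaluated field
  swap_and_reverse <- function(ex) {
    if (ex$op == "plane") return(imp_leaf(reverse_widget(ex$widget)))
    node <- if (ex$op == "union") imp_intersection else imp_union
    node(swap_and_reverse(ex$left), swap_and_reverse(ex$right))
  }
  set.seed(44)
  for (rep in 1:5) {
    ex <- random_expr(sample(2:10, 1L))
    pts <- matrix(runif(3000, -4, 4), ncol = 3L)  # 1000 points
    expect_equal(eval_expr(swap_and_reverse(ex), pts), -eval_expr(ex, pts))
  }
})

test_that("expressions serialize to canonical text, lists and JSON", {
  w <- lapply(1:3, function(i)
    plane_widget(c(i, 0, 0), c(1, 0, 0), id = i))
  ex <- imp_union(imp_leaf(w[[1L]]),
                  imp_intersection(imp_leaf(w[[2L]]), imp_leaf(w[[3L]])))
  expect_equal(expr_to_string(ex),
               paste0("(a1 ", "\u222a", " (a2 ", "\u2229", " a3))"))
  lst <- expr_to_list(ex)
  expect_equal(as.character(jsonlite::toJSON(lst, auto_unbox = TRUE)),
               '["union",["plane",1],["intersection",["plane",2],["plane",3]]]')
  back <- expr_from_list(jsonlite::fromJSON(
    jsonlite::toJSON(lst, auto_unbox = TRUE), simplifyVector = FALSE), w)
  expect_equal(expr_to_string(back), expr_to_string(ex))
  pts <- matrix(runif(30), ncol = 3L)
  expect_equal(eval_expr(back, pts), eval_expr(ex, pts))
  expect_error(expr_from_list(list("nand", lst, lst), w), "op")
})
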