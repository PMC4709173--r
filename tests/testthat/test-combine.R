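U <- "\u222a"
X <- "\u2229"

test_that("the three worked four-widget examples combine as published", {
  expect_equal(expr_to_string(combine_path(gen_path("EXAMPLE1"))$expr),
               sprintf("(a1 %s (a2 %s (a3 %s a4)))", U, U, X))
  expect_equal(expr_to_string(combine_path(gen_path("EXAMPLE2"))$expr),
               sprintf("(a1 %s ((a2 %s a3) %s a4))", U, U, X))
  expect_equal(expr_to_string(combine_path(gen_path("EXAMPLE3"))$expr),
               sprintf("(a1 %s ((a2 %s a3) %s a4))", U, U, X))
})

test_that("the example fixtures fire the intended loop conditions", {
  # EXAMPLE1: the top-level loop walks k from 4 down to 2 (two line-test
  # hits); EXAMPLE2 stops after the same walk but its (2,4) subcall
  # never loops; EXAMPLE3's walk needs the ray test at k = 3
  c1 <- combine_path(gen_path("EXAMPLE1"))$cost
  c2 <- combine_path(gen_path("EXAMPLE2"))$cost
  c3 <- combine_path(gen_path("EXAMPLE3"))$cost
  expect_equal(c1$loop_iters, 3L)  # 2 at top level + 1 in the subcall
  expect_equal(c2$loop_iters, 2L)  # 2 at top level only
  expect_equal(c3$loop_iters, 2L)  # line hit at k=4, ray hit at k=3
  expect_equal(c1$total, 8L)
  expect_equal(c2$total, 7L)
  expect_equal(c3$total, 7L)
})

test_that("single- and two-widget paths cost exactly 1", {
  w1 <- plane_widget(c(0, 0, 0), c(0, 0, 1), id = 1)
  res1 <- combine_path(clipping_path(list(w1)))
  expect_equal(res1$cost$total, 1L)
  expect_equal(expr_to_string(res1$expr), "a1")
  res2 <- combine_path(gen_path("CONVEX", list(n = 2)))
  expect_equal(res2$cost$total, 1L)
  expect_equal(expr_n_leaves(res2$expr), 2L)
})

test_that("convex paths cost 2N - 3 and form a one-sided chain", {
  for (n in 3:30) {
    comb <- combine_path(gen_path("CONVEX", list(n = n)))
    expect_equal(comb$cost$total, 2L * n - 3L, info = paste("n =", n))
    expect_equal(comb$cost$loop_iters, 0L, info = paste("n =", n))
    expect_equal(expr_n_leaves(comb$expr), n)
    expect_equal(expr_depth(comb$expr), n)  # left-deep chain of n leaves
  }
})

test_that("the inward-spiral family costs (N+3)(N-2)/2 + 1", {
  for (n in 4:20) {
    comb <- combine_path(gen_path("STAIRCASE_WORST", list(n = n)))
    expect_equal(comb$cost$total, (n + 3L) * (n - 2L) / 2L + 1L,
                 info = paste("n =", n))
    expect_equal(expr_depth(comb$expr), n)  # right-deep chain
  }
})

test_that("cost totals decompose into base, composite and loop counts", {
  for (kind in c("EXAMPLE1", "CONVEX", "STAIRCASE_WORST")) {
    cost <- combine_path(gen_path(kind, list(n = 7)))$cost
    expect_equal(cost$total,
                 cost$base_calls + cost$composite_calls + cost$loop_iters)
  }
})

test_that("combined expressions classify points like the 2D side oracle", {
  set.seed(31)
  sizes <- sample(3:12, 30, replace = TRUE)
  for (i in seq_along(sizes)) {
    path <- gen_random_chain(sizes[i], seed = 1000 + i)
    res <- oracle_agreement(path, npts = 300, seed = 2000 + i)
    expect_equal(res[["agreed"]], res[["checked"]],
                 info = sprintf("chain %d (n = %d)", i, sizes[i]))
  }
})

test_that("every combination has N leaves in order and N - 1 nodes", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(2:10, 1L)
    comb <- combine_path(gen_random_chain(n, seed = 3000 + i))
    expect_equal(expr_n_leaves(comb$expr), n)
    expect_equal(expr_n_nodes(comb$expr), n - 1L)
    ids <- vapply(expr_widgets(comb$expr), `[[`, integer(1L), "id")
    expect_equal(ids, seq_len(n))  # left-to-right leaf order is a1..aN
  }
})

test_that("reversing a path complements the classification", {
  for (i in 1:5) {
    path <- gen_random_chain(6, seed = 4000 + i)
    comb <- combine_path(path)
    rev_path <- path
    rev_path$reverse <- TRUE
    comb_r <- combine_path(rev_path)
    pts2 <- sample_box_points(comb$polyline, 200, seed = 5000 + i)
    pts3 <- frame_to_3d(comb$frame, pts2)
    v <- eval_expr(comb$expr, pts3)
    eps <- 1e-9 * (1 + sqrt(rowSums(pts3^2)))
    keep <- abs(v) > 10 * eps
    lab <- classify(comb$expr, pts3[keep, , drop = FALSE])
    lab_r <- classify(comb_r$expr, pts3[keep, , drop = FALSE])
    expect_true(all((lab == "INSIDE") == (lab_r == "OUTSIDE")))
  }
})

test_that("closed enclosures classify like point-in-polygon", {
  for (n in c(8L, 29L)) {
    path <- gen_path("ENCLOSURE", list(n = n, radius = 0.6))
    comb <- combine_path(path)
    ring <- comb$polyline$points[seq_len(n), , drop = FALSE]
    set.seed(n)
    pts2 <- cbind(runif(400, -1.2, 1.2), runif(400, -1.2, 1.2))
    # point-in-polygon by even-odd ray crossing (independent oracle)
    pip <- vapply(seq_len(nrow(pts2)), function(i) {
      x <- pts2[i, 1L]; y <- pts2[i, 2L]
      cr <- 0L
      for (k in seq_len(n)) {
        a <- ring[k, ]; b <- ring[if (k == n) 1L else k + 1L, ]
        if ((a[2L] > y) != (b[2L] > y)) {
          xi <- a[1L] + (y - a[2L]) / (b[2L] - a[2L]) * (b[1L] - a[1L])
          if (xi > x) cr <- cr + 1L
        }
      }
      cr %% 2L == 1L
    }, TRUE)
    pts3 <- frame_to_3d(comb$frame, pts2)
    v <- eval_expr(comb$expr, pts3)
    keep <- abs(v) > 1e-6
    expect_gt(sum(keep & pip), 50)   # sample covers both sides
    expect_gt(sum(keep & !pip), 50)
    expect_equal(v[keep] < 0, pip[keep])
  }
})

test_that("invalid index ranges are contract errors", {
  path <- gen_path("CONVEX", list(n = 4))
  frame <- transection_frame(path)
  poly <- transect(path, frame)
  oriented <- orient_normals(path, poly)
  expect_error(comb_imp_funs(oriented, poly, frame, 3, 2), "index range")
  expect_error(comb_imp_funs(oriented, poly, frame, 1, 5), "index range")
})
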