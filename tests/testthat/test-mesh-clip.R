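unit_tet <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

test_that("triangle_mesh validates its indices", {
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 2))), "twice")
})

test_that("a plane missing the mesh leaves one part empty", {
  tet <- unit_tet()
  below <- imp_leaf(plane_widget(c(0, 0, -5), c(0, 0, 1)))
  res <- clip_mesh(tet, below)
  expect_equal(nrow(res$inside$faces), 0L)
  expect_equal(res$cut_vertex_count, 0L)
  expect_equal(mesh_area(res$outside), mesh_area(tet))
  expect_equal(vertex_key(res$outside$vertices), vertex_key(tet$vertices))
})

test_that("clipping a tetrahedron at z = 0.5 interpolates the rising edges", {
  tet <- unit_tet()
  res <- clip_mesh(tet, imp_leaf(plane_widget(c(0, 0, 0.5), c(0, 0, 1))))
  # hand interpolation t = s_a / (s_a - s_b) on edges 1-4, 2-4, 3-4:
  # all s_base = -0.5, s_apex = +0.5, so t = 0.5
  cuts <- rbind(c(0, 0, 0.5), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  for (p in seq_len(3L)) {
    k <- paste(sprintf("%.12g", cuts[p, ]), collapse = "_")
    expect_true(k %in% vertex_key(res$inside$vertices), info = paste(p))
    expect_true(k %in% vertex_key(res$outside$vertices), info = paste(p))
  }
  expect_equal(res$cut_vertex_count, 3L)
  expect_equal(mesh_area(res$inside) + mesh_area(res$outside),
               mesh_area(tet), tolerance = 1e-12)
  # parts respect the field sign; cut vertices sit on the zero set
  expr <- imp_leaf(plane_widget(c(0, 0, 0.5), c(0, 0, 1)))
  expect_true(all(eval_expr(expr, res$inside$vertices) <= 1e-12))
  expect_true(all(eval_expr(expr, res$outside$vertices) >= -1e-12))
  expect_equal(max(abs(eval_expr(expr, cuts))), 0)
})

test_that("clipping a sphere through its centre splits the area evenly", {
  s <- gen_mesh("SPHERE", list(subdiv = 3))
  res <- clip_mesh(s, imp_leaf(plane_widget(c(0, 0, 0), c(0, 0, 1))))
  total <- mesh_area(s)
  expect_equal(mesh_area(res$inside) + mesh_area(res$outside), total,
               tolerance = 1e-9)
  expect_lt(abs(mesh_area(res$inside) - mesh_area(res$outside)),
            0.01 * total)
})

test_that("area is conserved over random mesh/expression pairs", {
  set.seed(77)
  kinds <- c("SPHERE", "ELLIPSOID", "BLOB_BUMP", "TWO_LOBES")
  for (rep in 1:20) {
    mesh <- gen_mesh(sample(kinds, 1L), list(subdiv = 2))
    n <- sample(1:5, 1L)
    widgets <- lapply(seq_len(n), function(i)
      plane_widget(runif(3, -0.8, 0.8), runif(3, -1, 1) + 0.05, id = i))
    ex <- Reduce(function(acc, w) {
      if (runif(1) < 0.5) imp_union(acc, imp_leaf(w))
      else imp_intersection(acc, imp_leaf(w))
    }, widgets[-1L], imp_leaf(widgets[[1L]]))
    res <- clip_mesh(mesh, ex)
    expect_equal(mesh_area(res$inside) + mesh_area(res$outside),
                 mesh_area(mesh), tolerance = 1e-6)
    # sign correctness for the original vertices (interpolated cut
    # vertices on a kinked min/max field carry a small residual, as
    # with any scalar clip that interpolates the combined field)
    key_of <- function(v) apply(v, 1L, function(r)
      paste(sprintf("%.12g", r), collapse = "_"))
    orig <- key_of(mesh$vertices)
    if (nrow(res$inside$vertices)) {
      keep <- key_of(res$inside$vertices) %in% orig
      expect_true(all(eval_expr(ex, res$inside$vertices[keep, ,
                                                        drop = FALSE])
                      <= 1e-6))
    }
    if (nrow(res$outside$vertices)) {
      keep <- key_of(res$outside$vertices) %in% orig
      expect_true(all(eval_expr(ex, res$outside$vertices[keep, ,
                                                         drop = FALSE])
                      >= -1e-6))
    }
  }
})

test_that("clipping by a reversed plane swaps the two parts", {
  s <- gen_mesh("SPHERE", list(subdiv = 2))
  w <- plane_widget(c(0.1, 0.2, 0.1), c(1, 2, 3))
  a <- clip_mesh(s, imp_leaf(w))
  b <- clip_mesh(s, imp_leaf(reverse_widget(w)))
  expect_equal(vertex_key(a$inside$vertices), vertex_key(b$outside$vertices))
  expect_equal(vertex_key(a$outside$vertices), vertex_key(b$inside$vertices))
})

test_that("re-clipping the inside part is a no-op", {
  s <- gen_mesh("SPHERE", list(subdiv = 2))
  # exact for a planar cut: the field is linear along every cut edge
  ex <- imp_leaf(plane_widget(c(0, 0.1, 0.2), c(1, 1, 3), id = 1))
  once <- clip_mesh(s, ex)
  again <- clip_mesh(once$inside, ex)
  expect_equal(again$cut_vertex_count, 0L)
  expect_equal(nrow(again$inside$faces), nrow(once$inside$faces))
  expect_equal(nrow(again$outside$faces), 0L)
  # across a min/max corner the interpolated cut leaves only a sliver
  # residual (the combined field is kinked along the crossed edges)
  ex2 <- imp_union(imp_leaf(plane_widget(c(0, 0, 0.2), c(0, 0, 1), id = 1)),
                   imp_leaf(plane_widget(c(0.2, 0, 0), c(1, 0, 0), id = 2)))
  once2 <- clip_mesh(s, ex2)
  again2 <- clip_mesh(once2$inside, ex2)
  expect_lt(mesh_area(again2$outside), mesh_area(s) / nrow(s$faces))
})

test_that("connected components partition faces by vertex sharing", {
  s <- gen_mesh("SPHERE", list(subdiv = 2))
  expect_length(connected_components(s), 1L)
  expect_length(connected_components(gen_mesh("BLOB_BUMP",
                                              list(subdiv = 2))), 1L)
  two <- triangle_mesh(
    rbind(s$vertices, s$vertices + matrix(c(5, 0, 0), nrow(s$vertices),
                                          3L, byrow = TRUE)),
    rbind(s$faces, s$faces + nrow(s$vertices)))
  comps <- connected_components(two)
  expect_length(comps, 2L)
  expect_equal(sum(vapply(comps, function(m) nrow(m$faces), numeric(1L))),
               nrow(two$faces))
})

test_that("a dominated thickness plane does not change the field", {
  ex <- imp_leaf(plane_widget(c(0, 0, 0), c(0, 0, 1), id = 1))
  thick <- plane_widget(c(0, 0, 100), c(0, 0, 1))  # inside covers z < 100
  combined <- apply_thickness(ex, thick)
  pts <- matrix(runif(60, -3, 3), ncol = 3L)
  expect_equal(eval_expr(combined, pts), eval_expr(ex, pts))
  # reversing flips which side survives: value of the reversed
  # thickness plane at z = -1 is dot((0,0,-1), (0,0,-101)) = 101
  rev_comb <- apply_thickness(ex, thick, reverse = TRUE)
  p <- c(0, 0, -1)
  expect_equal(eval_expr(rev_comb, p), 101)
  expect_gt(eval_expr(rev_comb, p), 0)  # z = -1 now outside the slab
})

test_that("thickness limits the removed part to one side of the plane", {
  blob <- gen_mesh("BLOB_BUMP", list(subdiv = 3))
  enc <- gen_path("ENCLOSURE", list(n = 29, radius = 0.6))
  expr_full <- combine_path(enc)$expr
  full <- clip_mesh(blob, expr_full)
  # without a thickness plane the enclosure cuts through the whole body
  expect_lt(min(full$inside$vertices[, 3L]), -0.8)
  expect_gt(max(full$inside$vertices[, 3L]), 1.4)
  encT <- gen_path("ENCLOSURE", list(n = 29, radius = 0.6,
                                     thickness_offset = 0.5))
  expr_thick <- apply_thickness(combine_path(encT)$expr, encT$thickness)
  lim <- clip_mesh(blob, expr_thick)
  expect_gt(min(lim$inside$vertices[, 3L]), 0.5 - 1e-6)
  # far side of the thickness plane: remainder vertices unchanged
  far_orig <- blob$vertices[blob$vertices[, 3L] < 0.5 - 1e-9, , drop = FALSE]
  far_rem <- lim$outside$vertices[lim$outside$vertices[, 3L] < 0.5 - 1e-9, ,
                                  drop = FALSE]
  expect_equal(vertex_key(far_rem), vertex_key(far_orig))
})

test_that("sequential clipping peels parts off the remainder in order", {
  s <- gen_mesh("SPHERE", list(subdiv = 3))
  stages <- gen_path("COMPLEX4")
  # one stage is equivalent to a plain clip
  one <- sequential_clip(s, stages[1L])
  direct <- clip_mesh(s, combine_path(stages[[1L]])$expr)
  expect_equal(vertex_key(one$part1$vertices),
               vertex_key(direct$inside$vertices))
  expect_equal(vertex_key(one$remainder$vertices),
               vertex_key(direct$outside$vertices))
  # three stages yield three parts plus remainder, all non-empty
  all4 <- sequential_clip(s, stages)
  expect_length(all4, 4L)
  expect_true(all(vapply(all4, function(m) nrow(m$faces) > 0L, TRUE)))
  # stage areas sum to the input area
  expect_equal(sum(vapply(all4, mesh_area, numeric(1L))), mesh_area(s),
               tolerance = 1e-6)
})

test_that("disjoint stages commute in their part multiset", {
  s <- gen_mesh("SPHERE", list(subdiv = 2))
  stages <- gen_path("COMPLEX4")
  fwd <- sequential_clip(s, stages)
  rev <- sequential_clip(s, stages[c(3L, 1L, 2L)])
  key_areas <- function(parts)
    sort(round(unname(vapply(parts, mesh_area, numeric(1L))), 9))
  expect_equal(key_areas(fwd), key_areas(rev), tolerance = 1e-6)
  expect_equal(vapply(fwd, function(m) length(connected_components(m)), 1L),
               c(part1 = 1L, part2 = 1L, part3 = 1L, remainder = 1L))
})

test_that("empty meshes clip to empty results", {
  empty <- triangle_mesh(matrix(0, 0L, 3L), matrix(integer(0), 0L, 3L))
  res <- clip_mesh(empty, imp_leaf(plane_widget(c(0, 0, 0), c(0, 0, 1))))
  expect_equal(nrow(res$inside$faces), 0L)
  expect_equal(nrow(res$outside$faces), 0L)
})
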