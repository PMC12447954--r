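test_that("the hull of a triangle is the triangle, canonically ordered", {
  poly <- convex_polygon(c(10, 1000, 100), c(1, 1, 10), label = "tri")
  v <- poly$vertices
  expect_equal(nrow(v), 3)
  # starts at the lexicographic minimum, runs counter-clockwise
  expect_equal(v[1, ], c(log10_P = 1, log10_E = 0))
  expect_equal(v[2, ], c(log10_P = 3, log10_E = 0))
  expect_equal(v[3, ], c(log10_P = 2, log10_E = 1))
  expect_error(convex_polygon(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(convex_polygon(c(1, 10, 100), c(1, 10, 100)), "collinear")
})

test_that("hulls are idempotent and invariant to permutation and duplication", {
  set.seed(21)
  x <- runif(40, 1, 6); y <- runif(40, 0, 3)
  h1 <- convex_polygon(x, y, log10_input = TRUE)
  h2 <- convex_polygon(h1$vertices[, 1], h1$vertices[, 2], log10_input = TRUE)
  expect_equal(h2$vertices, h1$vertices)
  perm <- sample(40)
  h3 <- convex_polygon(c(x[perm], x[1:10]), c(y[perm], y[1:10]),
                       log10_input = TRUE)
  expect_equal(h3$vertices, h1$vertices)
  expect_equal(polygon_area(h3), polygon_area(h1))
})

test_that("hull vertices and containment agree with the all-pairs brute force", {
  set.seed(99)
  P <- 10^runif(200, 0.5, 6.5)
  E <- 10^runif(200, -1, 3)
  poly <- convex_polygon(P, E, label = "cloud")
  oracle_idx <- brute_hull_vertices(log10(P), log10(E))
  oracle <- cbind(log10(P)[oracle_idx], log10(E)[oracle_idx])
  # same vertex set (order-free comparison)
  key <- function(m) sort(paste(signif(m[, 1], 12), signif(m[, 2], 12)))
  expect_equal(key(poly$vertices), key(oracle))
  # every vertex is an input point
  expect_true(all(key(poly$vertices) %in%
                    sort(paste(signif(log10(P), 12), signif(log10(E), 12)))))
  # no generating point strictly outside
  cls <- vapply(seq_along(P), function(i) classify_point(P[i], E[i], poly), "")
  expect_true(all(cls %in% c("inside", "on_boundary")))
})

test_that("point classification distinguishes the five placements", {
  poly <- convex_polygon(c(1, 3, 3, 1), c(0, 0, 1, 1), log10_input = TRUE)
  centroid <- colMeans(poly$vertices)
  expect_equal(classify_point(10^centroid[1], 10^centroid[2], poly), "inside")
  expect_equal(classify_point(10^1, 10^0, poly), "on_boundary") # a vertex
  expect_equal(classify_point(10^2, 10^0, poly), "on_boundary") # an edge
  expect_equal(classify_point(10^2, 10^2, poly), "above")
  expect_equal(classify_point(10^2, 10^-2, poly), "below")
  expect_equal(classify_point(10^5, 10^0.5, poly), "outside_range")
})

test_that("polygon extension reproduces the axis-aligned construction", {
  square <- convex_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1), log10_input = TRUE)
  ext <- extend_polygon(square, 2, slope = 0)
  expect_equal(sort(ext$vertices[, 1]), c(0, 0, 2, 2))
  expect_equal(sort(ext$vertices[, 2]), c(0, 0, 1, 1))
  expect_equal(polygon_area(ext), 2)
  # zero-length extension changes nothing
  same <- extend_polygon(square, 1)
  expect_equal(same$vertices, square$vertices)
  expect_error(extend_polygon(square, 0.5), "must not be less")
})

test_that("extension always contains the original and never sheds area", {
  for (seed in 1:20) {
    set.seed(seed)
    poly <- convex_polygon(runif(10, 0, 4), runif(10, -2, 2),
                           log10_input = TRUE)
    ext <- extend_polygon(poly, max(poly$vertices[, 1]) + runif(1, 0.1, 3))
    for (k in seq_len(nrow(poly$vertices))) {
      expect_true(classify_point(10^poly$vertices[k, 1],
                                 10^poly$vertices[k, 2], ext)
                  %in% c("inside", "on_boundary"))
    }
    expect_gte(polygon_area(ext), polygon_area(poly) - 1e-9)
    # extending further still never removes area
    ext2 <- extend_polygon(ext, max(ext$vertices[, 1]) + 1)
    expect_gte(polygon_area(ext2), polygon_area(ext) - 1e-9)
  }
})

test_that("the earliest large-bodied mammal sits above a reptile-grade polygon", {
  cloud <- synthetic_reptile_cloud(seed = 4)
  poly <- convex_polygon(cloud$P_g, cloud$E_g, label = "reptiles")
  ext <- extend_polygon(poly, 7, slope = 2 / 3)
  # at 16 kg a reptile-grade 2/3 line through the alligator anchor predicts
  # roughly a 2.6 g brain; this mammal carries 7.14 ml
  expect_equal(classify_point(16144, 7.14, poly), "above")
  expect_equal(classify_point(16144, 7.14, ext), "above")
  # the printed crocodilian anchors are on the polygon itself
  expect_equal(classify_point(205000, 14.08, poly), "on_boundary")
})
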