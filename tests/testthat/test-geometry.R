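# Polygon primitives against closed forms and independently written oracles.

test_that("edge_distance handles touching, gapped and crossing polygons", {
  expect_identical(edge_distance(square_poly(0, 0), square_poly(1, 0)), 0)
  expect_equal(edge_distance(square_poly(0, 0), square_poly(3, 0)), 2)
  # containment (no boundary contact) is distance zero
  inner <- square_poly(0.4, 0.4, 0.2)
  expect_identical(edge_distance(square_poly(0, 0), inner), 0)
  # crossing boundaries
  expect_identical(edge_distance(square_poly(0, 0), square_poly(0.5, 0.5)), 0)
})

test_that("edge_distance matches segment-pair and boundary-sampling oracles", {
  set.seed(41)
  for (k in 1:200) {
    A <- random_triangle(2)
    B <- random_triangle(2, shift = runif(2, -3, 3))
    expect_equal(edge_distance(A, B), o_edge_distance(A, B),
                 tolerance = 1e-12)
  }
  # dense 1 mm boundary sampling on a handful of separated triangle pairs
  for (k in 1:8) {
    A <- random_triangle(1.5)
    B <- random_triangle(1.5, shift = c(4, 0))
    expect_equal(edge_distance(A, B), o_sampled_distance(A, B, 0.001),
                 tolerance = 2e-3)
  }
})

test_that("edge_distance is symmetric and obeys the relaxed triangle bound", {
  set.seed(42)
  for (k in 1:50) {
    A <- random_convex(6, shift = runif(2, -4, 4))
    B <- random_convex(6, shift = runif(2, -4, 4))
    C <- random_convex(6, shift = runif(2, -4, 4))
    expect_identical(edge_distance(A, B), edge_distance(B, A))
    diamB <- max(dist(B))
    expect_lte(edge_distance(A, C),
               edge_distance(A, B) + diamB + edge_distance(B, C) + 1e-12)
  }
})

test_that("centre_point matches closed forms and the shoelace oracle", {
  expect_equal(centre_point(square_poly()), c(0.5, 0.5))
  expect_equal(centre_point(cbind(c(0, 3, 0), c(0, 0, 3))), c(1, 1))
  set.seed(43)
  for (k in 1:100) {
    P <- random_convex(10, scale = runif(1, 0.5, 5), shift = runif(2, -9, 9))
    expect_equal(centre_point(P), o_shoelace_centroid(P), tolerance = 1e-12)
  }
})

test_that("overlap requires positive interior intersection area", {
  expect_false(overlaps(square_poly(0, 0), square_poly(1, 0))) # shared edge
  expect_true(overlaps(square_poly(), square_poly()))          # identical
  a <- square_poly(0, 0); b <- square_poly(0.5, 0.5)
  expect_true(overlaps(a, b))
  expect_equal(intersection_area(a, b), 0.25, tolerance = 1e-6)
})

test_that("overlap agrees with the convex-clip area oracle on random pairs", {
  set.seed(44)
  for (k in 1:300) {
    A <- random_convex(7, shift = runif(2, -1, 1))
    B <- random_convex(7, shift = runif(2, -1, 1))
    area <- o_convex_intersection_area(A, B)
    expect_identical(overlaps(A, B), area > 1e-9)
    if (area > 1e-6)
      expect_equal(intersection_area(A, B), area, tolerance = 1e-6)
  }
})

test_that("rigid motions preserve shape and act as expected", {
  P <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)) # 2 x 1 rectangle
  # full turn is the identity
  expect_equal(apply_motion(P, rigid_motion(360)), P, tolerance = 1e-9)
  # translation shifts the centroid exactly
  Q <- apply_motion(P, rigid_motion(0, c(1, 0)))
  expect_equal(centre_point(Q) - centre_point(P), c(1, 0), tolerance = 1e-12)
  # quarter turn swaps width and length about an unchanged centroid
  R <- apply_motion(P, rigid_motion(90))
  expect_equal(centre_point(R), centre_point(P), tolerance = 1e-12)
  expect_equal(diff(range(R[, 1])), 1, tolerance = 1e-12)
  expect_equal(diff(range(R[, 2])), 2, tolerance = 1e-12)
  # area/perimeter conservation on random motions
  set.seed(45)
  for (k in 1:50) {
    P <- random_convex(8, scale = runif(1, 0.1, 10))
    M <- rigid_motion(runif(1, 0, 360), runif(2, -50, 50))
    Q <- apply_motion(P, M)
    expect_equal(polygon_area(Q), polygon_area(P),
                 tolerance = 1e-9 * abs(polygon_area(P)))
    expect_equal(polygon_perimeter(Q), polygon_perimeter(P),
                 tolerance = 1e-9 * polygon_perimeter(P))
  }
})

test_that("polygon validation rejects degenerate rings", {
  expect_error(validate_polygon(cbind(c(0, 1), c(0, 1))), "3 distinct")
  expect_error(validate_polygon(cbind(c(0, 1, 2), c(0, 0, 0))), "area")
  expect_error(validate_polygon(cbind(c(0, 1, NA), c(0, 0, 1))), "finite")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(validate_polygon(bowtie), "self-intersect")
  expect_error(centre_point(cbind(c(0, 1, 2), c(0, 0, 0))))
})
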