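test_that("point-to-triangle distance handles all closest-point regions", {
  tri <- rbind(c(-10, -10, 0), c(10, -10, 0), c(0, 15, 0))
  centroid <- colMeans(tri)
  expect_equal(point_to_triangle_distance(centroid + c(0, 0, 2), tri), 2)
  # beyond a vertex: distance equals point-to-vertex distance
  p <- c(0, 20, 3)
  expect_equal(point_to_triangle_distance(p, tri), sqrt(sum((p - tri[3, ])^2)))
  expect_error(point_to_triangle_distance(c(0, 0, 1),
                                          rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "zero-area")
})

test_that("analytic distance is bounded by and close to the sampling oracle", {
  set.seed(51)
  n_checked <- 0
  while (n_checked < 250) {
    tri <- matrix(runif(9, -1, 1), 3, 3)
    if (sqrt(sum(pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2)) / 2 < 0.05)
      next
    p <- runif(3, -1.5, 1.5)
    d <- point_to_triangle_distance(p, tri)
    if (d < 0.05) next   # keep the sampling-oracle error second order
    oracle <- sampling_tri_dist(p, tri)
    expect_lte(d, oracle + 1e-12)
    expect_lt(oracle - d, 1e-3)
    n_checked <- n_checked + 1
  }
})

test_that("surface distance maps are exact and match brute force", {
  h <- small_hand()
  self <- surface_distance_map(h$mesh, h$mesh)
  expect_equal(max(self$distances), 0)

  # parallel plane patches separated by d give a constant map
  plane <- function(z) {
    g <- expand.grid(x = seq(0, 10, 2), y = seq(0, 10, 2))
    v <- cbind(g$x, g$y, z)
    nx <- 6
    fc <- NULL
    for (j in 1:5) for (i in 1:5) {
      a <- (j - 1) * nx + i
      fc <- rbind(fc, c(a, a + 1, a + nx + 1), c(a, a + nx + 1, a + nx))
    }
    hand_mesh(v, fc)
  }
  dm <- surface_distance_map(plane(3.25), plane(0))
  expect_equal(unname(range(dm$distances)), c(3.25, 3.25))

  # accelerated equals brute force on a small random instance
  a <- random_mesh(60, seed = 2)
  b <- random_mesh(55, seed = 3)
  g <- surface_distance_map(a, b, method = "grid")
  br <- surface_distance_map(a, b, method = "brute")
  expect_lt(max(abs(g$distances - br$distances)), 1e-9)
})

test_that("distance maps are invariant under a common rigid transform", {
  a <- random_mesh(40, seed = 6)
  b <- random_mesh(35, seed = 7)
  tr <- random_rigid_transform(12)
  d0 <- surface_distance_map(a, b)$distances
  d1 <- surface_distance_map(apply_transform(tr, a), apply_transform(tr, b))$distances
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("region restriction never increases the maximum distance", {
  h <- small_hand()
  t1 <- simulate_repeat_acquisition(h, acquisition_jitter(), seed = 14)
  reg <- apply_transform(icp_register(t1$mesh, h$mesh)$transform, t1$mesh)
  full <- surface_distance_map(reg, h$mesh)
  palm <- surface_distance_map(reg, h$mesh, regions = t1$regions, region = "palm")
  expect_lte(max(palm$distances), max(full$distances))
  # with finger jitter, the palm is the more reproducible region
  expect_lt(summary(palm)$abs_mean, summary(full)$abs_mean)
  expect_error(surface_distance_map(reg, h$mesh, regions = t1$regions,
                                    region = "pinky"), "unknown region")
})

test_that("signed maps carry the inside/outside convention", {
  s_in <- uv_sphere(10)
  s_out <- uv_sphere(11)   # inflated by 1 mm along the radial normals
  dm <- signed_surface_distance_map(s_out, s_in)
  expect_true(all(dm$sign > 0))
  expect_equal(mean(dm$distances), 1, tolerance = 0.1)

  flipped <- signed_surface_distance_map(s_in, s_out)
  expect_true(mean(flipped$sign) < 0)   # swapping flips the dominant sign

  # identical surfaces: zero magnitudes
  same <- signed_surface_distance_map(s_in, s_in)
  expect_equal(max(same$distances), 0)

  # inconsistently oriented target is rejected
  bad <- s_in
  bad$faces[1, ] <- bad$faces[1, c(1, 3, 2)]
  expect_error(signed_surface_distance_map(s_out, bad), "orient")
})

test_that("summaries report the abs mean and interpolated percentiles", {
  const <- structure(list(distances = rep(1.5, 20), region = "full"),
                     class = "distance_map")
  s <- summary(const)
  expect_equal(c(s$abs_mean, s$p50, s$p90), c(1.5, 1.5, 1.5))

  eleven <- structure(list(distances = 0:10, region = "full"),
                      class = "distance_map")
  s <- summary(eleven)
  expect_equal(s$p50, 5)
  expect_equal(s$p90, 9)

  set.seed(61)
  for (i in 1:5) {
    m <- structure(list(distances = rexp(50), region = "full"),
                   class = "distance_map")
    sm <- summary(m)
    expect_lte(sm$p50, sm$p90)
    expect_gte(sm$abs_mean, 0)
  }
})
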