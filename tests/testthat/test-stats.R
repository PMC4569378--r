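test_that("paired t statistic follows its closed form", {
  # worked case: d = (1, 2, 3) has mean 2, sd 1, n 3 -> t = 2 sqrt(3), df 2
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(as.integer(r$degrees_of_freedom), 2L)
  expect_equal(r$mean_difference, 2)
  expect_true(r$significant_at_5pct == (r$p_value < 0.05))

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  expect_warning(res <- paired_t_test(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_equal(res$p_value, 0)
  expect_true(res$significant_at_5pct)

  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "unequal")
})

test_that("p-values match a quadrature oracle over a grid of cases", {
  # two-sided tail mass of the t density, by numerical integration
  quad_p <- function(t, df) {
    dens <- function(x) {
      gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
        (1 + x^2 / df)^(-(df + 1) / 2)
    }
    2 * integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
  }
  expect_equal(quad_p(2 * sqrt(3), 2),
               paired_t_test(c(2, 4, 6), c(1, 2, 3))$p_value,
               tolerance = 1e-6)
  set.seed(81)
  for (n in c(3, 5, 9, 17)) {
    a <- rnorm(n, 1, 1)
    b <- rnorm(n, 0.5, 1)
    r <- paired_t_test(a, b)
    expect_equal(r$p_value, quad_p(r$t_statistic, n - 1), tolerance = 1e-6)
    # and the statistic agrees with its definition
    d <- a - b
    expect_equal(r$t_statistic, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-10)
  }
})

make_model <- function(lm_pts, surface) {
  sets <- list(landmark_set(lm_pts, schema_id = "hand24"),
               landmark_set(lm_pts, schema_id = "hand24"))
  m <- compute_average(sets)
  m$average_surface <- surface
  m
}

test_that("sex comparison recovers a pure size difference", {
  h <- small_hand()
  fem <- make_model(h$landmarks$points, h$mesh)
  ctr <- colMeans(h$landmarks$points[c("palm_base_radial", "palm_base_ulnar",
                                       "palm_top_radial", "palm_top_ulnar"), ])
  scale_about <- function(x, s) sweep(sweep(x, 2, ctr) * s, 2, -ctr)
  male_pts <- scale_about(h$landmarks$points, 1.1)
  rownames(male_pts) <- rownames(h$landmarks$points)
  male_mesh <- hand_mesh(scale_about(h$mesh$vertices, 1.1), h$mesh$faces)
  mal <- make_model(male_pts, male_mesh)

  gc <- compare_sex_averages(mal, fem, refine_icp = FALSE)
  expect_gt(gc$mean_signed_distance, 0)
  # a small minority of samples sit where the enlarged palm edge penetrates
  # the reference's finger capsules; away from those junctions the scaled
  # surface is outside everywhere
  expect_gt(gc$fraction_male_outside, 0.85)
  # fingertip deltas point away from the palm centroid
  for (tip in paste0(c("thumb", "index", "middle", "ring", "little"), "_tip")) {
    outward <- male_pts[tip, ] - ctr
    expect_gt(sum(gc$landmark_deltas[tip, ] * outward), 0)
  }

  # identical models: zero contrast
  same <- compare_sex_averages(fem, fem, refine_icp = FALSE)
  expect_equal(same$mean_signed_distance, 0, tolerance = 1e-9)
  expect_lt(max(abs(same$landmark_deltas)), 1e-9)
})

test_that("sex comparison is antisymmetric under group swap", {
  cohort <- generate_cohort(3, male_scale = 1.08, seed = 31,
                            base_params = hand_params(resolution = 9))
  fit <- function(subs) average_hand(as_specimens(subs), method = "subregion",
                                     seed = 1)
  fem <- fit(Filter(function(s) s$sex == "female", cohort))
  mal <- fit(Filter(function(s) s$sex == "male", cohort))
  fwd <- compare_sex_averages(mal, fem)
  rev <- compare_sex_averages(fem, mal)
  expect_gt(fwd$mean_signed_distance, 0)
  expect_lt(rev$mean_signed_distance, 0)
  # magnitudes need not match exactly: the longer fingertips are far outside
  # the smaller hand, while the smaller tips sit just inside the wider
  # capsules, so sampling from either side weighs the gap differently
  ratio <- fwd$mean_signed_distance / -rev$mean_signed_distance
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})
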