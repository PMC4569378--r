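test_that("hand generation is deterministic and structurally complete", {
  h1 <- generate_hand()
  h2 <- generate_hand()
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  expect_identical(h1$mesh$faces, h2$mesh$faces)
  expect_identical(h1$landmarks$points, h2$landmarks$points)

  expect_equal(nrow(h1$landmarks$points), 24L)
  expect_identical(rownames(h1$landmarks$points), landmark_schema("hand24")$labels)
  expect_identical(length(h1$regions), nrow(h1$mesh$vertices))
  expect_true(all(table(h1$regions) > 0))   # all six regions populated
})

test_that("sex_scale scales the hand similarly about the palm origin", {
  h1 <- generate_hand(hand_params(sex_scale = 1))
  hs <- generate_hand(hand_params(sex_scale = 1.1))
  # landmark distances from every fingertip to the palm base landmarks
  tips <- paste0(c("thumb", "index", "middle", "ring", "little"), "_tip")
  for (tip in tips) {
    d1 <- sqrt(sum((h1$landmarks$points[tip, ] -
                    h1$landmarks$points["palm_base_ulnar", ])^2))
    ds <- sqrt(sum((hs$landmarks$points[tip, ] -
                    hs$landmarks$points["palm_base_ulnar", ])^2))
    expect_equal(ds, 1.1 * d1, tolerance = 1e-9)
  }
  # full equivariance: the scaled hand is the scaled vertex array
  expect_equal(hs$mesh$vertices, 1.1 * h1$mesh$vertices, tolerance = 1e-9)
  expect_identical(hs$mesh$faces, h1$mesh$faces)
})

test_that("left and right hands are exact mirror images across x = 0", {
  r <- generate_hand(hand_params(side = "right"))
  l <- generate_hand(hand_params(side = "left"))
  refl <- l$mesh$vertices
  refl[, 1] <- -refl[, 1]
  expect_lt(max(abs(refl - r$mesh$vertices)), 1e-9)
  lref <- l$landmarks$points
  lref[, 1] <- -lref[, 1]
  expect_lt(max(abs(lref - r$landmarks$points)), 1e-9)
})

test_that("parameter validation rejects non-positive dimensions", {
  expect_error(hand_params(palm_width = -1), "positive")
  expect_error(hand_params(sex_scale = 0), "sex_scale")
  expect_error(hand_params(finger_lengths = c(1, 2, 3)), "five")
  expect_error(acquisition_jitter(sensor_noise_sd = -1), ">= 0")
})

test_that("zero jitter is a no-op and articulation moves only fingers", {
  h <- small_hand()
  still <- simulate_repeat_acquisition(h, acquisition_jitter(0, 0, 0, 0), seed = 5)
  expect_equal(still$mesh$vertices, h$mesh$vertices, tolerance = 1e-12)
  expect_equal(still$landmarks$points, h$landmarks$points, tolerance = 1e-12)

  art <- simulate_repeat_acquisition(
    h, acquisition_jitter(0, 0, finger_articulation_sd = 5, 0), seed = 5)
  palm_idx <- as.character(h$regions) == "palm"
  expect_equal(art$mesh$vertices[palm_idx, ], h$mesh$vertices[palm_idx, ],
               tolerance = 1e-12)
  finger_disp <- abs(art$mesh$vertices[!palm_idx, ] - h$mesh$vertices[!palm_idx, ])
  expect_gt(max(finger_disp), 0.5)
})

test_that("a pure global pose change is recovered by ICP", {
  h <- small_hand()
  t1 <- simulate_repeat_acquisition(
    h, acquisition_jitter(global_rotation_sd = 5, global_translation_sd = 10,
                          finger_articulation_sd = 0, sensor_noise_sd = 0),
    seed = 11)
  res <- icp_register(t1$mesh, h$mesh, tol = 1e-9, max_iter = 200)
  # recovered transform composed with the applied one must be the identity
  comp <- compose_transform(res$transform, t1$applied_global)
  expect_lt(rotation_angle(comp$rotation), 1e-3)
  expect_lt(max(abs(comp$translation)), 1e-3)
})

test_that("region consistency: digit vertices move rigidly with their digit", {
  h <- small_hand()
  t1 <- simulate_repeat_acquisition(
    h, acquisition_jitter(0, 0, finger_articulation_sd = 6, 0), seed = 3)
  # for each digit, the rigid map fitted on its landmarks must carry its
  # vertices (outside the blend zone) onto their jittered positions
  for (d in c("thumb", "index", "middle", "ring", "little")) {
    labs <- paste0(d, c("_tip", "_distal", "_proximal", "_base"))
    tr <- kabsch(h$landmarks$points[labs, ], t1$landmarks$points[labs, ])
    sel <- as.character(h$regions) == d
    base <- h$landmarks$points[paste0(d, "_base"), ]
    tip <- h$landmarks$points[paste0(d, "_tip"), ]
    u <- (tip - base) / sqrt(sum((tip - base)^2))
    along <- as.numeric(sweep(h$mesh$vertices[sel, ], 2, base) %*% u)
    beyond <- along > 3   # outside the knuckle blend zone
    moved <- apply_transform(tr, h$mesh$vertices[sel, , drop = FALSE])
    expect_lt(max(abs(moved[beyond, ] - t1$mesh$vertices[sel, ][beyond, ])), 1e-6)
  }
})

test_that("cohorts are deterministic and encode the sex size contrast", {
  c1 <- generate_cohort(3, seed = 9)
  c2 <- generate_cohort(3, seed = 9)
  expect_identical(lapply(c1, function(s) s$landmarks$points),
                   lapply(c2, function(s) s$landmarks$points))

  degenerate <- generate_cohort(3, male_scale = 1, between_subject_sd = 0,
                                seed = 2)
  pts <- lapply(degenerate, function(s) s$landmarks$points)
  for (p in pts[-1]) expect_equal(p, pts[[1]], tolerance = 1e-12)

  big <- generate_cohort(30, male_scale = 1.1, between_subject_sd = 0.04,
                         seed = 4)
  midlen <- vapply(big, function(s) {
    sqrt(sum((s$landmarks$points["middle_tip", ] -
              s$landmarks$points["middle_base", ])^2))
  }, numeric(1))
  sex <- vapply(big, function(s) s$sex, character(1))
  ratio <- mean(midlen[sex == "male"]) / mean(midlen[sex == "female"])
  expect_equal(ratio, 1.1, tolerance = 0.03)
})
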