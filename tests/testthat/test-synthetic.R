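test_that("plant generation is deterministic given a seed", {
  a <- make_plant(plant_spec(seed = 42, height = 1.6, points_per_plant = 4000))
  b <- make_plant(plant_spec(seed = 42, height = 1.6, points_per_plant = 4000))
  expect_identical(a$cloud$positions, b$cloud$positions)
  expect_identical(a$cloud$colors, b$cloud$colors)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$traits, b$truth$traits)
})

test_that("labels partition the cloud", {
  pl <- make_plant(plant_spec(seed = 3, height = 1.4, points_per_plant = 4000,
                              pot = TRUE, outlier_fraction = 0.01))
  expect_equal(length(pl$labels), pl$cloud$n)
  expect_setequal(unique(sub("_[0-9]+$", "", pl$labels)),
                  c("stem", "leaf", "pot", "outlier"))
})

test_that("noiseless points lie exactly on their surfaces", {
  sp <- plant_spec(seed = 9, height = 1.5, noise_sigma = 0,
                   points_per_plant = 4000, pot = FALSE,
                   outlier_fraction = 0, tilt_deg = 0)
  pl <- make_plant(sp)
  stem_pts <- pl$cloud$positions[pl$labels == "stem", ]
  lat <- sqrt(stem_pts[, 1]^2 + stem_pts[, 2]^2)
  expect_lt(max(abs(lat - sp$stem_radius)), 1e-9)
  # leaf points stay within the (tapering) ribbon half-width of their vein
  i <- 3
  pts <- pl$cloud$positions[pl$labels == paste0("leaf_", i), ]
  vein <- pl$truth$leaves[[i]]
  best <- rep(Inf, nrow(pts))
  for (s in seq(1, nrow(vein) - 2, by = 2))
    best <- pmin(best,
                 maizeskel:::dist_point_segment(pts, vein[s, ], vein[s + 2, ]))
  expect_lt(max(best), 0.5 * sp$width_max[i] + 1e-3)
})

test_that("ground-truth traits are self-consistent under the traits module", {
  pl <- make_plant(plant_spec(seed = 77, height = 1.9,
                              points_per_plant = 1000))
  measured <- skeleton_traits(pl$truth$skeleton)
  analytic <- pl$truth$traits
  for (cn in c("leaf_length_m", "top_length_m", "growth_height_m",
               "plant_height_m")) {
    rel <- abs(measured[[cn]] - analytic[[cn]]) /
      pmax(abs(analytic[[cn]]), 0.05)
    expect_lt(max(rel), 0.005)
  }
  expect_lt(max(abs(measured$inclination_deg - analytic$inclination_deg)),
            0.005 * mean(analytic$inclination_deg))
  d_az <- abs(measured$azimuth_deg - analytic$azimuth_deg)
  expect_lt(max(pmin(d_az, 360 - d_az)), 1)
})

test_that("study generation respects difficulty settings and leaf totals", {
  st <- make_study(6, seed = 10, difficulty = "easy", points_per_plant = 500)
  total <- sum(vapply(st, function(p) p$truth$spec$n_leaves, 0))
  expect_gte(total, 30)
  expect_lte(total, 90)
  expect_true(all(vapply(st, function(p)
    p$truth$spec$noise_sigma == 0.001 && !p$truth$spec$pot, TRUE)))
  st2 <- make_study(2, seed = 10, difficulty = "realistic",
                    points_per_plant = 500)
  expect_true(all(vapply(st2, function(p)
    p$truth$spec$noise_sigma == 0.004 && p$truth$spec$pot &&
      p$truth$spec$outlier_fraction == 0.01, TRUE)))
  # same seed, same study
  st3 <- make_study(2, seed = 10, difficulty = "realistic",
                    points_per_plant = 500)
  expect_identical(st2[[1]]$cloud$positions, st3[[1]]$cloud$positions)
})

test_that("spec invariants are enforced", {
  expect_error(plant_spec(height = 0.1), "height")
  sp <- plant_spec(seed = 1)
  expect_true(all(diff(sp$insertion_frac) > 0))
  expect_true(all(sp$vein_length > 0))
})
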