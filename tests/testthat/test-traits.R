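test_that("leaf length sums segment distances and converges to arc length", {
  expect_equal(leaf_length(rbind(c(0, 0, 0), c(0, 0.5, 0))), 0.5)
  th <- seq(0, pi / 2, length.out = 100)
  quarter <- cbind(cos(th), sin(th), 0)
  expect_equal(leaf_length(quarter), pi / 2, tolerance = 1e-3)
})

test_that("inclination matches hand geometry", {
  up <- rbind(c(0, 0, 0), c(0, 0, 0.2), c(0, 0, 0.4))
  expect_equal(inclination_angle(up, c(0, 0, 1)), 0, tolerance = 1e-10)
  flat <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(0.4, 0, 0))
  expect_equal(inclination_angle(flat, c(0, 0, 1)), 90, tolerance = 1e-10)
  diag45 <- rbind(c(0, 0, 0), c(0.1, 0, 0.1), c(0.2, 0, 0.2))
  expect_equal(inclination_angle(diag45, c(0, 0, 1)), 45, tolerance = 1e-8)
})

test_that("top length stops at the highest point and is bounded by length", {
  rising <- cbind(seq(0, 1, length.out = 6), 0, seq(0, 0.5, length.out = 6))
  expect_equal(top_length(rising), leaf_length(rising), tolerance = 1e-9)
  # symmetric arch: apex exactly at the middle node
  x <- seq(0, 1, length.out = 15)
  arch <- cbind(x, 0, -(x - 0.5)^2)
  s_apex <- maizeskel:::polyline_length(arch[1:8, ])
  expect_equal(top_length(arch), s_apex, tolerance = 1e-6)
  flat <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_equal(top_length(flat), 0)  # ties: first maximal node
  withr::with_seed(44, {
    for (i in 1:20) {
      L <- cbind(cumsum(runif(8)), rnorm(8), rnorm(8))
      expect_lte(top_length(L), leaf_length(L) + 1e-9)
    }
  })
})

test_that("azimuths measure counter-clockwise from the lowest leaf", {
  mk <- function(dir) rbind(c(0, 0, 0.2), c(dir * 0.5, 0.25))
  leaves <- list(mk(c(1, 0)), mk(c(-1, 0)), mk(c(0, 1)))
  az <- azimuth_angle(leaves, c(0, 0, 1))
  expect_equal(az, c(0, 180, 90))
})

test_that("plant height is vertical and rigid-motion invariant", {
  stem <- cbind(0.02 * seq(0, 1, length.out = 10), 0,
                seq(0, 2, length.out = 10))  # leaning stem
  leaf <- rbind(stem[7, ], c(0.3, 0.1, 2.1), c(0.5, 0.2, 1.9))
  sk <- structure(list(stem = stem, leaves = list(leaf),
                       growth_points = 7L, stem_nodes = 1:10,
                       leaf_nodes = list(integer(0)), graph = NULL),
                  class = "plant_skeleton")
  expect_equal(plant_height(sk), 2.1)
  expect_equal(growth_height(leaf, sk), stem[7, 3])
  # rotate about z and translate horizontally: heights unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mv <- function(P) sweep(P %*% t(R), 2, c(3, -2, 0), "+")
  sk2 <- sk
  sk2$stem <- mv(sk$stem)
  sk2$leaves <- list(mv(leaf))
  expect_equal(plant_height(sk2), plant_height(sk), tolerance = 1e-12)
})

test_that("trait evaluation reproduces closed forms", {
  truth <- data.frame(leaf_length_m = c(0.5, 0.6, 0.7),
                      inclination_deg = c(30, 40, 50),
                      top_length_m = c(0.3, 0.35, 0.4),
                      azimuth_deg = c(0, 180, 350),
                      growth_height_m = c(0.2, 0.5, 0.8),
                      plant_height_m = c(2, 2, 2))
  ev0 <- evaluate_traits(truth, truth)
  expect_true(all(ev0$nrmse_pct == 0))
  expect_true(all(abs(ev0$r_squared - 1) < 1e-9, na.rm = TRUE))
  pred <- truth
  for (cn in names(truth)) pred[[cn]] <- truth[[cn]] + 0.1 * mean(truth[[cn]])
  ev10 <- evaluate_traits(pred, truth)
  expect_equal(ev10$nrmse_pct[ev10$trait != "azimuth_deg"],
               rep(10, 5), tolerance = 1e-9)
})

test_that("azimuth residuals wrap across the 0/360 seam", {
  truth <- data.frame(azimuth_deg = c(0, 1, 180))
  pred <- data.frame(azimuth_deg = c(0, 359, 182))
  ev <- evaluate_traits(pred, truth)
  # errors are 0, -2, +2 after wrapping
  expect_equal(ev$nrmse_pct, 100 * sqrt(mean(c(0, 2, 2)^2)) /
                 mean(truth$azimuth_deg))
})

test_that("study evaluation matches an independent recomputation", {
  res <- run_study(2, seed = 5, difficulty = "easy", points_per_plant = 5000)
  ev <- res$eval
  for (tr in c("leaf_length_m", "growth_height_m")) {
    p <- res$pred[[tr]]
    y <- res$truth[[tr]]
    expect_equal(ev$nrmse_pct[ev$trait == tr],
                 100 * sqrt(mean((p - y)^2)) / mean(y), tolerance = 1e-12)
    expect_equal(ev$r_squared[ev$trait == tr], cor(p, y)^2,
                 tolerance = 1e-12)
  }
  ph <- ev[ev$trait == "plant_height_m", ]
  expect_equal(ph$n, 2)  # one height per plant
})
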