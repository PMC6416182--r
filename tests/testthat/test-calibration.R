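# a hand-built skeleton list suffices for the stem calibration unit tests
stem_skeleton <- function(stem, gp = integer(0), leaves = list()) {
  structure(list(stem = stem, leaves = leaves,
                 growth_points = gp,
                 stem_nodes = seq_len(nrow(stem)),
                 leaf_nodes = lapply(leaves, function(x) integer(0)),
                 graph = NULL),
            class = "plant_skeleton")
}

test_that("a perfectly straight stem is a fixed point of calibration", {
  stem <- cbind(0, 0, seq(0, 1, length.out = 12))
  sk <- stem_skeleton(stem, gp = c(4L, 8L))
  out <- calibrate_stem(sk)
  expect_equal(out$stem, stem, tolerance = 1e-12)
})

test_that("bent interior nodes are projected to exact collinearity", {
  z <- seq(0, 1, length.out = 13)
  stem <- cbind(0, 0, z)
  gp <- c(5L, 9L)
  # bend the nodes adjacent to the growth points sideways (the Laplacian
  # artifact): the growth points themselves are excluded from the fits
  stem[c(4, 6, 8, 10), 1] <- 0.02
  sk <- stem_skeleton(stem, gp = gp)
  out <- calibrate_stem(sk)
  # each section's owned nodes lie on one exact line
  bounds <- unique(c(1L, gp, 13L))
  for (b in seq_len(length(bounds) - 1)) {
    own <- seq(bounds[b], if (b == length(bounds) - 1) bounds[b + 1]
               else bounds[b + 1] - 1)
    if (length(own) < 3) next
    seg <- out$stem[own, , drop = FALSE]
    line <- maizeskel:::tls_line(seg)
    res <- max(sqrt(rowSums((seg -
      maizeskel:::project_on_line(seg, line))^2)))
    expect_lt(res, 1e-10 * maizeskel:::polyline_length(seg))
  }
})

test_that("the base extension walks down to the bottom of the stem points", {
  stem <- cbind(0, 0, seq(0.12, 1, length.out = 10))
  sk <- stem_skeleton(stem, gp = c(4L, 7L))
  withr::with_seed(31, {
    cloud <- cbind(rnorm(4000, 0, 0.005), rnorm(4000, 0, 0.005),
                   runif(4000, 0, 1))
  })
  out <- calibrate_stem(sk, stem_cloud = cloud)
  expect_lt(out$stem[1, 3], 0.02)   # reached the cloud bottom
  expect_gt(out$stem[1, 3], -0.03)
  # and never moves the base upward
  out2 <- calibrate_stem(stem_skeleton(cbind(0, 0, seq(0, 1, length.out = 10)),
                                       gp = c(4L, 7L)),
                         stem_cloud = cloud + rep(c(0, 0, 0.3), each = 4000))
  expect_lte(out2$stem[1, 3], 0 + 1e-9)
})

# ribbon sampled around a known quadratic Bezier vein
ribbon_fixture <- function(n = 2500, width = 0.06, noise = 0, seed = 33) {
  P0 <- c(0, 0, 1); P1 <- c(0.25, 0, 1.25); P2 <- c(0.55, 0, 1.15)
  tfine <- seq(0, 1, length.out = 400)
  vein <- maizeskel:::bezier_point(tfine, P0, P1, P2)
  withr::with_seed(seed, {
    tt <- runif(n)
    B <- maizeskel:::bezier_point(tt, P0, P1, P2)
    lat <- runif(n, -1, 1) * 0.5 * width * sin(pi * tt)^0.6
    pts <- B + outer(lat, c(0, 1, 0))
    if (noise > 0) pts <- pts + matrix(rnorm(3 * n, 0, noise), ncol = 3)
  })
  list(cloud = pts, vein = vein)
}

dist_to_polyline <- function(P, L) {
  best <- rep(Inf, nrow(P))
  for (s in seq(1, nrow(L) - 5, by = 5))
    best <- pmin(best, maizeskel:::dist_point_segment(P, L[s, ], L[s + 5, ]))
  best
}

test_that("laterally displaced leaf nodes snap back onto the vein", {
  fx <- ribbon_fixture()
  idx <- round(seq(1, 400, length.out = 10))
  nodes <- fx$vein[idx, ]
  nodes[-1, 2] <- nodes[-1, 2] + 0.01    # lateral displacement
  cal <- calibrate_leaf(nodes, fx$cloud)
  d <- dist_to_polyline(cal[-1, , drop = FALSE], fx$vein)
  expect_lt(max(d), 0.003)
})

test_that("a polyline already on the vein hardly moves", {
  fx <- ribbon_fixture()
  idx <- round(seq(1, 400, length.out = 10))
  nodes <- fx$vein[idx, ]
  spacing <- maizeskel:::polyline_length(nodes) / (nrow(nodes) - 1)
  cal <- calibrate_leaf(nodes, fx$cloud)
  # interior nodes stay put; the terminal node is a half-slab boundary
  # effect and is re-extended by the tip step instead
  moved <- sqrt(rowSums((cal[2:9, ] - nodes[2:9, ])^2))
  expect_lt(max(moved), 0.5 * spacing / 10 + 0.002)
  d_tip <- sqrt(sum((cal[nrow(cal), ] - fx$vein[400, ])^2))
  expect_lt(d_tip, 0.5 * spacing)
})

test_that("tip extension recovers a leaf cut several nodes short", {
  fx <- ribbon_fixture()
  idx <- round(seq(1, 260, length.out = 8))   # stops ~1/3 short of the tip
  nodes <- fx$vein[idx, ]
  spacing <- maizeskel:::polyline_length(nodes) / (nrow(nodes) - 1)
  cal <- calibrate_leaf(nodes, fx$cloud)
  tip_true <- fx$vein[400, ]
  d_tip <- sqrt(sum((cal[nrow(cal), ] - tip_true)^2))
  expect_lt(d_tip, spacing)
})

test_that("an empty leaf cloud leaves the polyline unchanged with a warning", {
  nodes <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_warning(out <- calibrate_leaf(nodes, matrix(0, 0, 3)), "uncalibrated")
  expect_equal(out, nodes)
})

test_that("recentered nodes stay inside the cloud's bounding box", {
  fx <- ribbon_fixture(noise = 0.003)
  idx <- round(seq(1, 400, length.out = 9))
  nodes <- fx$vein[idx, ] + 0.005
  cal <- calibrate_leaf(nodes, fx$cloud)
  lo <- apply(fx$cloud, 2, min) - 1e-9
  hi <- apply(fx$cloud, 2, max) + 1e-9
  inside <- sweep(cal[-1, , drop = FALSE], 2, lo, ">=") &
    sweep(cal[-1, , drop = FALSE], 2, hi, "<=")
  expect_true(all(inside))
})

test_that("full-skeleton calibration preserves leaf count and assignment", {
  pl <- small_plant(seed = 10, points = 6000, noise = 0.004)
  skel <- extract_skeleton(pl$cloud, skel_control(target_points = 6000))
  expect_true(skel$calibrated)
  expect_equal(length(skel$leaves), length(skel$leaf_nodes))
  expect_equal(length(skel$leaves), length(skel$growth_points))
})
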