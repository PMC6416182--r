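test_that("PLY, PCD and xyzrgb files round-trip positions and colors", {
  withr::with_seed(11, {
    pos <- matrix(runif(30, -1, 2), 10)
    col <- matrix(sample(0:255, 30, replace = TRUE), 10)
  })
  pc <- point_cloud(pos, col)
  for (fmt in c("ply", "pcd", "xyzrgb")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_point_cloud(pc, f, format = fmt)
    back <- read_point_cloud(f, format = fmt)
    expect_equal(back$n, 10)
    # positions are stored in text at better than float32 precision
    expect_equal(back$positions, pc$positions, tolerance = 1e-6)
    expect_identical(back$colors, pc$colors)  # colors bit-exact
  }
  # binary little-endian PLY stores float32 coordinates
  fb <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(pc, fb, format = "ply", binary = TRUE)
  back <- read_point_cloud(fb)
  expect_equal(back$positions, pc$positions, tolerance = 1e-6)
  expect_identical(back$colors, pc$colors)
})

test_that("a tiny ASCII PLY reads with colors exactly as written", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header",
               "0 0 0 10 20 30", "1 0 0 40 50 60", "0 1 0 70 80 90"), f)
  pc <- read_point_cloud(f)
  expect_equal(pc$n, 3)
  expect_identical(pc$colors, matrix(c(10, 40, 70, 20, 50, 80, 30, 60, 90), 3))
})

test_that("colorless files are rejected unless a default color is given", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 1 1"), f)
  expect_error(read_point_cloud(f), "no color")
  pc <- read_point_cloud(f, default_color = c(1, 2, 3))
  expect_identical(pc$colors[2, ], c(1, 2, 3))
  fp <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0"), fp)
  expect_error(read_point_cloud(fp), "no color")
})

test_that("malformed files raise parse errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 5",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header", "0 0 0 1 2 3"), f)
  expect_error(read_point_cloud(f), "malformed|records")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0", "1 1"), f2)
  expect_error(read_point_cloud(f2), "malformed")
})

test_that("axis remapping permutes coordinates at load time", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("1 2 3 0 0 0", f)
  pc <- read_point_cloud(f, axis_order = c("z", "x", "y"))
  expect_equal(as.numeric(pc$positions), c(3, 1, 2))
})

test_that("bounding-box diagonal matches closed forms and brute force", {
  cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)), const_color(8))
  expect_equal(bbox_diagonal(cube), sqrt(3))
  expect_equal(bbox_diagonal(point_cloud(matrix(c(1, 2, 3), 1),
                                         const_color(1))), 0)
  withr::with_seed(3, {
    P <- cbind(runif(100, 0, 2), runif(100), runif(100))
  })
  brute <- sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
  expect_equal(bbox_diagonal(point_cloud(P, const_color(100))), brute)
})

test_that("uniform simplification hits the target band and keeps points", {
  pl <- make_plant(plant_spec(seed = 2, height = 2.0,
                              points_per_plant = 130000, pot = TRUE))
  expect_gt(pl$cloud$n, 120000)
  out <- uniform_simplify(pl$cloud, 10000)
  expect_gte(out$n, 9000)
  expect_lte(out$n, 11000)
  # retained points are a subset of the input (no interpolation)
  key_in <- paste(pl$cloud$positions[, 1], pl$cloud$positions[, 2])
  key_out <- paste(out$positions[, 1], out$positions[, 2])
  expect_true(all(key_out %in% key_in))
})

test_that("simplification is a no-op below the target", {
  withr::with_seed(5, P <- matrix(runif(1500), 500))
  pc <- point_cloud(P, const_color(500))
  expect_identical(uniform_simplify(pc, 10000), pc)
})

test_that("voxel downsampling is idempotent at a fixed voxel size", {
  withr::with_seed(6, P <- matrix(runif(3000), 1000))
  pc <- point_cloud(P, const_color(1000))
  once <- voxel_downsample(pc, 0.07)
  twice <- voxel_downsample(once, 0.07)
  expect_identical(once$positions, twice$positions)
})

test_that("grid simplification spreads points better than random subsets", {
  pc <- grid_cloud(4)  # 64 points
  out <- uniform_simplify(pc, 8)
  expect_gte(out$n, 8 * 0.9)
  expect_lte(out$n, ceiling(8 * 1.1))
  min_pair <- function(P) min(dist(P))
  ours <- min_pair(out$positions)
  wins <- withr::with_seed(9, {
    vapply(1:1000, function(i) {
      sub <- pc$positions[sample(64, out$n), ]
      ours >= min_pair(sub)
    }, TRUE)
  })
  expect_gte(mean(wins), 0.95)
})
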