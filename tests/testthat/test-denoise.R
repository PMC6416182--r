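# scalar reference implementation of the color difference, kept independent
# of the vectorized package code
ref_color_diff <- function(p, q) {
  ep <- mean(p); eq <- mean(q)
  cp <- p - ep; cq <- q - eq
  np <- sqrt(sum(cp^2)); nq <- sqrt(sum(cq^2))
  th <- if (np < 1e-9 || nq < 1e-9) 0 else
    acos(max(-1, min(1, sum(cp * cq) / (np * nq)))) * 255 / (pi / 2)
  2 * abs(max(ep, eq) / min(ep, eq) - 1) * th
}

test_that("color difference vanishes exactly where the definition says", {
  expect_equal(color_difference(c(120, 80, 40), c(120, 80, 40)), 0)
  # two grays: zero chroma vectors, theta := 0, so brightness is invisible
  expect_equal(color_difference(c(100, 100, 100), c(200, 200, 200)), 0)
  # equal-brightness hue flip: the ratio term vanishes despite theta > 0
  expect_equal(color_difference(c(255, 0, 0), c(0, 255, 0)), 0)
})

test_that("vectorized color difference matches the scalar reference", {
  withr::with_seed(21, {
    P <- matrix(sample(5:255, 60, replace = TRUE), ncol = 3)
    Q <- matrix(sample(5:255, 60, replace = TRUE), ncol = 3)
  })
  ref <- vapply(1:20, function(i) ref_color_diff(P[i, ], Q[i, ]), 0)
  expect_equal(as.numeric(color_difference(P, Q)), ref)
})

test_that("pot removal is an exact partition of the cloud", {
  pl <- small_plant(seed = 8, pot = TRUE, noise = 0.004)
  res <- remove_pot(pl$cloud, pl$truth$pot_samples)
  expect_equal(res$plant$n + res$pot$n, pl$cloud$n)
  # all points matching a sample color exactly go to the pot side
  same <- point_cloud(matrix(0.5, 5, 3),
                      matrix(rep(pl$truth$pot_samples[1, ], each = 5), 5))
  res2 <- remove_pot(same, pl$truth$pot_samples)
  expect_equal(res2$pot$n, 5)
  # and a cloud far from every sample stays intact
  far <- point_cloud(matrix(0.5, 5, 3), const_color(5, c(40, 150, 40)))
  res3 <- remove_pot(far, pl$truth$pot_samples)
  expect_equal(res3$plant$n, 5)
})

test_that("the pot filter separates pot from plant on a labeled scene", {
  pl <- make_plant(plant_spec(seed = 13, height = 1.6, noise_sigma = 0.004,
                              points_per_plant = 8000, pot = TRUE,
                              outlier_fraction = 0))
  res <- remove_pot(pl$cloud, pl$truth$pot_samples)
  # recover labels by matching positions
  key <- paste(round(pl$cloud$positions[, 1], 9),
               round(pl$cloud$positions[, 3], 9))
  pot_key <- paste(round(res$pot$positions[, 1], 9),
                   round(res$pot$positions[, 3], 9))
  removed <- key %in% pot_key
  is_pot <- pl$labels == "pot"
  is_leaf <- startsWith(pl$labels, "leaf")
  expect_gte(mean(removed[is_pot]), 0.99)
  expect_lte(mean(removed[is_leaf]), 0.01)
})

test_that("near-propagation clustering equals connected components", {
  blob1 <- matrix(rnorm(60, 0, 0.01), ncol = 3)
  blob2 <- sweep(matrix(rnorm(60, 0, 0.01), ncol = 3), 2, c(1, 0, 0), "+")
  two <- point_cloud(rbind(blob1, blob2), const_color(40))
  cl <- near_propagation_cluster(two, 0.1)
  expect_equal(length(cl$clusters), 2)
  expect_equal(sort(cl$sizes), c(20, 20))
  expect_equal(length(near_propagation_cluster(two, 2)$clusters), 1)
})

test_that("clustering matches a brute-force union-find on random points", {
  withr::with_seed(31, P <- matrix(runif(600), ncol = 3))
  r <- 0.05
  cl <- near_propagation_cluster(point_cloud(P, const_color(200)), r)
  # O(n^2) union-find oracle
  parent <- seq_len(200)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  D <- as.matrix(dist(P))
  for (i in 1:199) for (j in (i + 1):200) {
    if (D[i, j] <= r) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(1:200, find, 0L)
  oracle <- as.integer(factor(roots))
  # same partition up to label names
  expect_equal(length(unique(oracle)), length(cl$clusters))
  tab <- table(oracle, cl$labels)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("small clusters fall below the density threshold and are dropped", {
  withr::with_seed(41, {
    main <- matrix(runif(15000, 0, 0.2), ncol = 3)            # 5000 points
    flecks <- do.call(rbind, lapply(1:12, function(i)
      matrix(rnorm(9, 0, 0.002), ncol = 3) + 2 + i))          # 3 points each
  })
  pc <- point_cloud(rbind(main, flecks), const_color(5036))
  r <- 0.03
  cl <- near_propagation_cluster(pc, r)
  out <- drop_small_clusters(cl, pc, r, num = 10, seed = 0)
  expect_equal(out$n, 5000)
  # the threshold equals half the mean probe-neighborhood count
  probes <- withr::with_seed(0, sample.int(pc$n, 10))
  dens <- vapply(probes, function(p)
    sum(sqrt(colSums((t(pc$positions) - pc$positions[p, ])^2)) <= r), 0L)
  expect_equal(attr(out, "threshold"), 0.5 * mean(dens))
  # probing every point gives the same keep/remove decision here
  out_all <- drop_small_clusters(cl, pc, r, num = pc$n, seed = 0)
  expect_equal(out_all$n, out$n)
})

test_that("a single cluster always survives; an empty result errors", {
  withr::with_seed(42, P <- matrix(rnorm(300, 0, 0.05), ncol = 3))
  pc <- point_cloud(P, const_color(100))
  cl <- near_propagation_cluster(pc, 0.05)
  out <- drop_small_clusters(cl, pc, 0.05)
  expect_gte(out$n, 1)
  # with a huge radius and an artificial tiny-cluster-only partition,
  # everything falls below the threshold
  fake <- structure(list(clusters = as.list(seq_len(100)),
                         sizes = rep(1L, 100),
                         labels = seq_len(100)), class = "cluster_set")
  expect_error(drop_small_clusters(fake, pc, 0.05), "no plant remains")
})

test_that("the denoising pipeline is deterministic given a seed", {
  pl <- small_plant(seed = 4, pot = TRUE, outliers = 0.01, noise = 0.004)
  a <- denoise_cloud(pl$cloud, pl$truth$pot_samples, seed = 1)
  b <- denoise_cloud(pl$cloud, pl$truth$pot_samples, seed = 1)
  expect_identical(a$positions, b$positions)
})
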