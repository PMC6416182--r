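test_that("two points connect with a single edge", {
  g <- connect_knn(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(nrow(g$edges), 1)
})

test_that("square corners connect by brute-force edge admission", {
  # every corner proposes its two sides (length 1) and the diagonal
  # (length sqrt(2)); ascending-length admission accepts the four sides
  # first and the diagonals still fit under the degree-3 cap, so the
  # enumerated result is six edges; loop breaking then thins it to a tree
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  g <- connect_knn(sq)
  sides <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))
  expect_equal(nrow(g$edges), 6)
  expect_true(all(apply(sides, 1, function(e)
    any(g$edges[, 1] == min(e) & g$edges[, 2] == max(e)))))
  expect_lte(max(maizeskel:::node_degree(g)), 3)
  expect_true(maizeskel:::graph_is_tree(break_loops(g)))
})

test_that("an even chain reduces to exactly the path after loop breaking", {
  chain <- cbind(seq_len(10), 0, 0)
  tree <- break_loops(connect_knn(chain))
  expect_true(maizeskel:::graph_is_tree(tree))
  expect_equal(nrow(tree$edges), 9)
  expect_true(all(tree$edges[, 2] - tree$edges[, 1] == 1))
})

test_that("degree never exceeds three", {
  withr::with_seed(17, P <- matrix(runif(300), ncol = 3))
  g <- connect_knn(P)
  expect_lte(max(maizeskel:::node_degree(g)), 3)
})

test_that("plane fitting is exact on coplanar and symmetric inputs", {
  cop <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  pf <- plane_fit(cop)
  expect_lt(pf$residual, 1e-20)
  expect_equal(abs(pf$coef[3]), 1, tolerance = 1e-12)
  # symmetric tetrahedron about z = 0
  tet <- rbind(c(1, 0, 0.3), c(-1, 0, 0.3), c(0, 1, -0.3), c(0, -1, -0.3))
  pf2 <- plane_fit(tet)
  expect_equal(abs(pf2$coef[3]), 1, tolerance = 1e-12)
  expect_equal(pf2$coef[4], 0, tolerance = 1e-12)
})

test_that("plane fitting recovers a noisy plane normal within 2 degrees", {
  withr::with_seed(19, {
    xy <- matrix(runif(40, -1, 1), ncol = 2)
    z <- 1 - xy[, 1] - xy[, 2] + rnorm(20, 0, 0.02)
  })
  pf <- plane_fit(cbind(xy, z))
  target <- c(1, 1, 1) / sqrt(3)
  ang <- acos(min(1, abs(sum(pf$coef[1:3] * target)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("collinear input is a degenerate plane", {
  expect_error(plane_fit(cbind(1:5, 1:5, 1:5)), "degenerate")
})

test_that("breaking a lifted triangle removes the hand-computed edge", {
  # A--B on the ground, C lifted; all three nodes are exactly coplanar so
  # the coplanarity weights vanish and the turning angles decide. The
  # interior angle at C is smallest, so its two edges carry the largest
  # turning-angle sums; of those, A-C wins (interior angle at A < at B).
  A <- c(0, 0, 0); B <- c(1, 0, 0); C <- c(0.6, 0, 2)
  g <- skeleton_graph(rbind(A, B, C), rbind(c(1, 2), c(2, 3), c(1, 3)))
  tree <- break_loops(g)
  expect_true(maizeskel:::graph_is_tree(tree))
  has_edge <- function(tr, a, b)
    any(tr$edges[, 1] == min(a, b) & tr$edges[, 2] == max(a, b))
  expect_false(has_edge(tree, 1, 3))
  expect_true(has_edge(tree, 1, 2))
  expect_true(has_edge(tree, 2, 3))
})

test_that("a tree passes through loop breaking unchanged", {
  chain <- cbind(seq_len(6), 0, 0)
  g <- skeleton_graph(chain, cbind(1:5, 2:6))
  expect_equal(break_loops(g)$edges, g$edges)
})

test_that("loop breaking always returns a spanning tree, never disconnects", {
  withr::with_seed(23, {
    for (trial in 1:100) {
      P <- matrix(runif(3 * sample(8:40, 1)), ncol = 3)
      g <- connect_components(connect_knn(P))
      tree <- break_loops(g)
      expect_equal(nrow(tree$edges), nrow(P) - 1)
      expect_true(maizeskel:::graph_is_tree(tree))
    }
  })
})

test_that("a bare vertical chain segments into a stem with no leaves", {
  chain <- cbind(0, 0, seq(0, 1, length.out = 8))
  tree <- skeleton_graph(chain, cbind(1:7, 2:8))
  sk <- segment_stem_leaves(tree)
  expect_equal(nrow(sk$stem), 8)
  expect_equal(length(sk$leaves), 0)
})

test_that("a single side branch becomes the leaf, the stem stays vertical", {
  stem <- cbind(0, 0, seq(0, 1, length.out = 9))
  leaf <- cbind(seq(0.1, 0.4, length.out = 4), 0,
                0.5 + seq(0.05, 0.25, length.out = 4))
  nodes <- rbind(stem, leaf)
  edges <- rbind(cbind(1:8, 2:9), c(5, 10), cbind(10:12, 11:13))
  sk <- segment_stem_leaves(skeleton_graph(nodes, edges))
  expect_equal(length(sk$leaves), 1)
  expect_equal(nrow(sk$stem), 9)
  expect_equal(sk$growth_points, 5)
  expect_equal(sk$leaves[[1]][1, ], nodes[5, ])     # starts at growth point
  expect_equal(max(sk$stem[, 3]), 1)                # stem went straight up
  # every node belongs to exactly one organ (growth point shared)
  covered <- sort(unique(c(sk$stem_nodes, unlist(sk$leaf_nodes))))
  expect_equal(covered, 1:13)
})

test_that("tangent-coherent edge filtering drops bridges between curves", {
  # two parallel lines 0.05 apart; proposals across them are perpendicular
  # to both tangents and must be rejected
  l1 <- cbind(seq(0, 1, length.out = 40), 0, 0)
  l2 <- cbind(seq(0, 1, length.out = 40), 0.1, 0)
  P <- rbind(l1, l2)
  tang <- rbind(matrix(rep(c(1, 0, 0), each = 40), 40),
                matrix(rep(c(1, 0, 0), each = 40), 40))
  g <- connect_knn(P, tangents = tang, joint = rep(FALSE, 80))
  cross <- (g$edges[, 1] <= 40) != (g$edges[, 2] <= 40)
  expect_false(any(cross))
})
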