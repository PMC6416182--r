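#' Skeleton graph construction and loop breaking
#'
#' `connect_knn()` links skeleton key points into an undirected graph in
#' which every node has at most three incident edges, matching the single
#' stem / unbranched leaves architecture of maize: each node proposes edges
#' to its three nearest neighbors and proposals are admitted in ascending
#' length order as long as both endpoints stay within degree three. The
#' result may contain closed loops, removed by [break_loops()].
#'
#' @param points a `skeleton_points` object or an `m x 3` matrix of key
#'   points (m >= 2).
#' @param k proposals per node (default 3).
#' @param tangents optional `m x 3` matrix of local curve tangents (rows may
#'   be `NA`): a proposal misaligned with the tangents of *both* endpoints
#'   by more than `max_angle` degrees is rejected before admission. Edges
#'   bridging two near-parallel organs run perpendicular to both curves,
#'   while genuine skeleton edges follow at least one; junction nodes
#'   (`joint = TRUE`) are exempt because their tangent is undefined.
#' @param joint optional logical vector flagging junction key points.
#' @param max_angle coherence threshold in degrees (default 60).
#' @return object of class `skeleton_graph`: list with `nodes` (`m x 3`
#'   positions) and `edges` (2-column index matrix, `i < j`).
#' @export
connect_knn <- function(points, k = 3, tangents = NULL, joint = NULL,
                        max_angle = 60) {
  X <- if (inherits(points, "skeleton_points")) points$positions
       else as_xyz_matrix(points)
  m <- nrow(X)
  if (m < 2) stop("need at least two key points")
  kk <- min(k, m - 1)
  nn <- cpp_knn(X, kk)
  cand <- unique(t(apply(cbind(rep(seq_len(m), kk), as.vector(nn)), 1, sort)))
  if (!is.null(tangents) && m > 2) {
    ed <- X[cand[, 2], , drop = FALSE] - X[cand[, 1], , drop = FALSE]
    ed <- ed / sqrt(rowSums(ed^2))
    align <- function(side) {
      tg <- tangents[cand[, side], , drop = FALSE]
      a <- abs(rowSums(ed * tg))
      ok <- a >= cos(rad(max_angle))
      ok[!is.finite(a)] <- TRUE  # no tangent: cannot judge, keep
      if (!is.null(joint)) ok[joint[cand[, side]]] <- TRUE
      ok
    }
    cand <- cand[align(1) | align(2), , drop = FALSE]
    if (nrow(cand) == 0) stop("edge coherence filter removed all proposals")
  }
  len <- sqrt(rowSums((X[cand[, 1], , drop = FALSE] -
                       X[cand[, 2], , drop = FALSE])^2))
  ord <- order(len, cand[, 1], cand[, 2])
  deg <- integer(m)
  keep <- logical(nrow(cand))
  for (e in ord) {
    a <- cand[e, 1]; b <- cand[e, 2]
    if (deg[a] < 3 && deg[b] < 3) {
      keep[e] <- TRUE
      deg[a] <- deg[a] + 1
      deg[b] <- deg[b] + 1
    }
  }
  skeleton_graph(X, cand[keep, , drop = FALSE])
}

skeleton_graph <- function(nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0)
    edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  structure(list(nodes = nodes, edges = edges), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  g <- as_igraph(x)
  cat(sprintf("skeleton_graph: %d nodes, %d edges, %d component(s)%s\n",
              nrow(x$nodes), nrow(x$edges),
              igraph::count_components(g),
              if (graph_is_tree(x)) ", tree" else ""))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$edges, directed = FALSE) |>
    igraph::add_vertices(max(0, nrow(graph$nodes) -
                               max(c(0, graph$edges))))
}

node_degree <- function(graph) {
  tabulate(graph$edges, nbins = nrow(graph$nodes))
}

graph_is_tree <- function(graph) {
  g <- as_igraph(graph)
  igraph::is_connected(g) &&
    nrow(graph$edges) == nrow(graph$nodes) - 1
}

#' Total-least-squares plane fit
#'
#' Fits the plane `ax + by + cz + d = 0` minimizing the sum of squared
#' orthogonal distances (the normal is the smallest principal direction of
#' the centered points).
#'
#' @param P matrix of at least three non-collinear points.
#' @return list with `coef` (unit-normal coefficients `a, b, c, d`),
#'   `residual` (minimized sum of squared distances) and `distances`
#'   (per-point orthogonal distance).
#' @export
plane_fit <- function(P) {
  P <- as_xyz_matrix(P)
  if (nrow(P) < 3) stop("need at least three points")
  ctr <- colMeans(P)
  C <- sweep(P, 2, ctr)
  sv <- svd(C, nu = 0, nv = 3)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate plane: points are collinear")
  normal <- sv$v[, 3]
  d <- -sum(normal * ctr)
  dist <- abs(as.numeric(C %*% normal))
  list(coef = c(normal, d), residual = sum(dist^2), distances = dist)
}

# distances of arbitrary points to a fitted plane
plane_distances <- function(P, coef) {
  abs(as.numeric(P %*% coef[1:3]) + coef[4])
}

#' Break closed loops in a skeleton graph
#'
#' While the graph contains a cycle, the shortest cycle is located, a
#' total-least-squares plane is fitted to its nodes, and every cycle edge is
#' scored by
#' \deqn{W = W_s / \max_i W_{s,i} + W_c / \max_i W_{c,i},}
#' where the coplanarity weight \eqn{W_s = d_i + d_{i+1}} sums the two
#' endpoints' distances to the plane and the growth weight
#' \eqn{W_c = \alpha_i + \alpha_{i+1}} sums the edge's turning angles
#' (radians) against its two neighbors in the cycle's cyclic order. The
#' maximum-weight edge — the one most out of plane and most misaligned with
#' the local growth direction — is deleted. Only cycle edges are ever
#' removed, so connectivity is preserved and the result is a spanning tree.
#'
#' @param graph a connected `skeleton_graph`.
#' @return a `skeleton_graph` that is a tree.
#' @export
break_loops <- function(graph) {
  g <- as_igraph(graph)
  if (!igraph::is_connected(g))
    stop("break_loops requires a connected graph")
  edges <- graph$edges
  X <- graph$nodes
  repeat {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gir <- igraph::girth(g)
    if (!is.finite(gir$girth)) break
    cyc <- as.integer(gir$circle)
    w <- cycle_edge_weights(X, cyc)
    # cycle edge k joins cyc[k] and cyc[k+1] (cyclically)
    kmax <- which.max(w)
    a <- cyc[kmax]
    b <- cyc[if (kmax == length(cyc)) 1 else kmax + 1]
    drop <- which((edges[, 1] == min(a, b)) & (edges[, 2] == max(a, b)))
    edges <- edges[-drop[1], , drop = FALSE]
  }
  skeleton_graph(X, edges)
}

# combined coplanarity + growth weights for the edges of one cycle
# (cyc: node indices in cyclic order)
cycle_edge_weights <- function(X, cyc) {
  m <- length(cyc)
  nxt <- c(2:m, 1)
  prv <- c(m, 1:(m - 1))
  pf <- tryCatch(plane_fit(X[cyc, , drop = FALSE]), error = function(e) NULL)
  d <- if (is.null(pf)) rep(0, m) else pf$distances  # collinear: coplanar term void
  ws <- d + d[nxt]  # edge k = (cyc[k], cyc[k+1])
  # turning angles: edge k against edges k-1 and k+1 in traversal order
  ev <- X[cyc[nxt], , drop = FALSE] - X[cyc, , drop = FALSE]
  turn <- vapply(seq_len(m), function(k)
    angle_between(ev[prv[k], ], ev[k, ]), 0)
  wc <- turn + turn[nxt]
  norm_or_zero <- function(v) if (max(v) > 1e-300) v / max(v) else rep(0, length(v))
  norm_or_zero(ws) + norm_or_zero(wc)
}

#' Segment a skeleton tree into stem and leaves
#'
#' The base is the lowest degree-one node. The stem is the tree path from
#' the base that maximizes the cumulative vertical rise penalized by
#' horizontal wander, \eqn{\sum_e (\Delta z_e - \lVert\Delta xy_e\rVert)}:
#' maize stems are near-vertical everywhere, while any detour into a leaf
#' trades little rise for a large horizontal excursion, so the criterion
#' recovers the stem even when individual junction nodes are displaced
#' sideways by sampling. Every branch leaving the stem becomes a leaf
#' polyline whose first node — the growth point — is the stem node it
#' leaves from.
#'
#' @param tree a `skeleton_graph` that is a tree (see [break_loops()]).
#' @param min_branch arc length (meters) above which a side branch inside a
#'   leaf subtree is treated as a leaf of its own rather than a sampling
#'   spur: two leaves attached just above the last clean stem node can land
#'   in one subtree, and this splits them apart again. `0` keeps one leaf
#'   per subtree.
#' @return object of class `plant_skeleton`: list with `stem` (ordered
#'   `s x 3` polyline from the base upward), `leaves` (list of ordered
#'   polylines, each starting at its growth point), `growth_points`
#'   (per-leaf stem-node index into `stem`), `stem_nodes` / `leaf_nodes`
#'   (indices into the graph nodes) and `graph`.
#' @export
segment_stem_leaves <- function(tree, min_branch = 0) {
  if (!graph_is_tree(tree)) stop("segment_stem_leaves expects a tree")
  X <- tree$nodes
  m <- nrow(X)
  if (m < 2) stop("need at least two nodes")
  adj <- vector("list", m)
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges[e, 1]; b <- tree$edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  leaves1 <- which(deg == 1)
  base <- leaves1[which.min(X[leaves1, 3])]
  # verticality score of every tree path from the base (iterative DFS)
  score <- rep(-Inf, m)
  parent <- integer(m)
  score[base] <- 0
  parent[base] <- 0L
  stack <- base
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (nb in adj[[cur]]) {
      if (nb == parent[cur] || is.finite(score[nb])) next
      d <- X[nb, ] - X[cur, ]
      score[nb] <- score[cur] + d[3] - sqrt(d[1]^2 + d[2]^2)
      parent[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  tip <- which.max(score)
  stem_idx <- tip
  while (stem_idx[1] != base) stem_idx <- c(parent[stem_idx[1]], stem_idx)
  # trim the stem top where it bends into an erect uppermost leaf: above the
  # last branching node the stem must stay on the local stem line; the first
  # node deviating laterally by more than ~half a node spacing starts the
  # top leaf, which then branches off like any other leaf
  on_raw <- logical(m)
  on_raw[stem_idx] <- TRUE
  # subtree sizes in the DFS tree rooted at the base
  depth <- integer(m)
  for (v in seq_len(m)) {
    u <- v
    while (u != base && u != 0L) { depth[v] <- depth[v] + 1L; u <- parent[u] }
  }
  subtree <- rep(1L, m)
  for (v in order(depth, decreasing = TRUE))
    if (parent[v] != 0L) subtree[parent[v]] <- subtree[parent[v]] + subtree[v]
  # branching nodes that carry a real organ (>= 3 nodes), not a short stub
  # such as the true stem tip left beside an erect uppermost leaf
  branching <- which(vapply(seq_along(stem_idx), function(k) {
    nbs <- adj[[stem_idx[k]]]
    off <- nbs[!on_raw[nbs] & parent[nbs] == stem_idx[k]]
    any(subtree[off] >= 3L)
  }, TRUE))
  if (length(branching) > 0 && max(branching) < length(stem_idx) - 1) {
    j_top <- max(branching)
    lo <- stem_idx[max(1, j_top - 3):j_top]
    if (length(lo) >= 2) {
      ref <- tls_line(X[lo, , drop = FALSE])
      spacing <- median(sqrt(rowSums(diff(X[stem_idx, , drop = FALSE])^2)))
      tol <- 0.6 * spacing
      lat <- vapply(seq(j_top + 1, length(stem_idx)), function(k) {
        w <- X[stem_idx[k], ] - ref$point
        vec_norm(w - sum(w * ref$dir) * ref$dir)
      }, 0)
      bad <- which(lat > tol)
      if (length(bad) > 0)
        stem_idx <- stem_idx[seq_len(j_top + bad[1] - 1)]
    }
  }
  on_stem <- logical(m)
  on_stem[stem_idx] <- TRUE
  # each off-stem subtree is one leaf: maize leaves do not branch, so any
  # sub-branching inside a subtree is a sampling artifact. The polyline is
  # the longest (arc-length) path from the stem node into the subtree;
  # every subtree node still belongs to the leaf for point attribution.
  leaves <- list()
  leaf_nodes <- list()
  gp <- integer(0)
  for (si in seq_along(stem_idx)) {
    s <- stem_idx[si]
    for (nb in adj[[s]]) {
      if (on_stem[nb]) next
      # collect the subtree hanging off s through nb, with distances
      sub <- nb
      dist <- stats::setNames(vec_norm(X[nb, ] - X[s, ]), nb)
      par_sub <- stats::setNames(s, nb)
      frontier <- nb
      while (length(frontier) > 0) {
        nxt <- integer(0)
        for (v in frontier) {
          for (w in adj[[v]]) {
            if (on_stem[w] || !is.na(par_sub[as.character(w)])) next
            if (w == par_sub[[as.character(v)]]) next
            par_sub[as.character(w)] <- v
            dist[as.character(w)] <- dist[[as.character(v)]] +
              vec_norm(X[w, ] - X[v, ])
            sub <- c(sub, w)
            nxt <- c(nxt, w)
          }
        }
        frontier <- nxt
      }
      # children of each subtree node, for descending into side branches
      kids <- split(sub, vapply(sub, function(v)
        par_sub[[as.character(v)]], 0L))
      desc_set <- function(root) {
        out <- root
        frontier <- root
        while (length(frontier) > 0) {
          nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
          out <- c(out, nxt)
          frontier <- nxt
        }
        out
      }
      queue <- list(list(root = s, nodes = sub))
      while (length(queue) > 0) {
        br <- queue[[1]]
        queue <- queue[-1]
        far <- br$nodes[which.max(dist[as.character(br$nodes)])]
        path <- far
        while (path[1] != br$root)
          path <- c(par_sub[[as.character(path[1])]], path)
        own <- path
        for (v in path) {
          side <- intersect(setdiff(kids[[as.character(v)]], path), br$nodes)
          for (c2 in side) {
            ds <- desc_set(c2)
            reach <- max(dist[as.character(ds)]) - dist[[as.character(v)]]
            if (reach >= min_branch && min_branch > 0) {
              queue <- c(queue, list(list(root = v, nodes = ds)))
            } else {
              own <- c(own, ds)
            }
          }
        }
        leaves <- c(leaves, list(X[path, , drop = FALSE]))
        leaf_nodes <- c(leaf_nodes, list(unique(c(s, own))))
        gp <- c(gp, si)
      }
    }
  }
  # order leaves bottom-up by growth point height
  if (length(leaves) > 0) {
    ord <- order(X[stem_idx[gp], 3])
    leaves <- leaves[ord]
    gp <- gp[ord]
    leaf_nodes <- leaf_nodes[ord]
  }
  structure(list(stem = X[stem_idx, , drop = FALSE],
                 leaves = leaves,
                 growth_points = gp,
                 stem_nodes = stem_idx,
                 leaf_nodes = leaf_nodes,
                 graph = tree),
            class = "plant_skeleton")
}
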