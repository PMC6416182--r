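#' Illumination-robust color difference between two RGB colors
#'
#' The difference combines a brightness ratio with the angle between the
#' mean-centered chroma vectors:
#' \deqn{D = 2\,\left|\frac{\max(\eta_i,\eta_j)}{\min(\eta_i,\eta_j)} - 1\right|\,\theta,
#'   \qquad \theta = \arccos\!\frac{\tilde p_i \cdot \tilde p_j}
#'   {\lVert \tilde p_i\rVert\,\lVert \tilde p_j\rVert}\cdot\frac{255}{\pi/2},}
#' where \eqn{\eta = (r+g+b)/3} and \eqn{\tilde p = (r-\eta, g-\eta, b-\eta)}.
#' A color that is a pure brightness scaling of another has a parallel chroma
#' vector, so \eqn{\theta = 0} and \eqn{D = 0}: the measure is insensitive to
#' illumination. Two caveats follow from the definition and are deliberate:
#' equal-brightness colors always give \eqn{D = 0} (the ratio term vanishes),
#' and a gray color (zero chroma vector) has \eqn{\theta} undefined, taken
#' here as 0, so grays match everything. Pot color samples should therefore
#' be chromatic.
#'
#' @param p,q RGB triples in `[0, 255]` (or matrices with one color per row;
#'   both are recycled row-wise).
#' @return non-negative color difference(s).
#' @export
color_difference <- function(p, q) {
  p <- matrix(as.numeric(p), ncol = 3)
  q <- matrix(as.numeric(q), ncol = 3)
  n <- max(nrow(p), nrow(q))
  if (nrow(p) == 1) p <- p[rep(1, n), , drop = FALSE]
  if (nrow(q) == 1) q <- q[rep(1, n), , drop = FALSE]
  ep <- rowMeans(p)
  eq <- rowMeans(q)
  if (any(pmin(ep, eq) <= 0))
    stop("pure black colors have undefined brightness ratio")
  cp <- p - ep
  cq <- q - eq
  np <- sqrt(rowSums(cp^2))
  nq <- sqrt(rowSums(cq^2))
  cosang <- rowSums(cp * cq) / pmax(np * nq, .Machine$double.eps)
  theta <- acos(pmax(-1, pmin(1, cosang))) * 255 / (pi / 2)
  theta[np < 1e-9 | nq < 1e-9] <- 0  # gray convention
  ratio <- pmax(ep, eq) / pmin(ep, eq)
  2 * abs(ratio - 1) * theta
}

#' Remove pot points by color difference
#'
#' Each point is compared with every color of a sampled pot ("noise") color
#' list; a point whose minimum color difference falls below `threshold` is
#' assigned to the pot cloud, everything else to the plant cloud.
#'
#' @param cloud a [point_cloud].
#' @param noise_colors matrix (or list of triples) of sampled pot RGB colors.
#' @param threshold color-difference cut, default 0.1.
#' @return list with elements `plant` and `pot`, both [point_cloud]s (either
#'   may be empty); their sizes always sum to `cloud$n`.
#' @export
remove_pot <- function(cloud, noise_colors, threshold = 0.1) {
  if (is.list(noise_colors) && !is.data.frame(noise_colors))
    noise_colors <- do.call(rbind, noise_colors)
  noise_colors <- matrix(as.numeric(as.matrix(noise_colors)), ncol = 3)
  if (nrow(noise_colors) < 1) stop("noise color list is empty")
  if (any(noise_colors < 0 | noise_colors > 255))
    stop("noise colors must lie in [0, 255]")
  if (threshold <= 0) stop("threshold must be positive")
  dmin <- rep(Inf, cloud$n)
  for (s in seq_len(nrow(noise_colors))) {
    d <- color_difference(cloud$colors, noise_colors[s, ])
    dmin <- pmin(dmin, d)
  }
  is_pot <- dmin < threshold
  list(plant = cloud_subset(cloud, which(!is_pot)),
       pot = cloud_subset(cloud, which(is_pot)))
}

#' Cluster a cloud by radius propagation
#'
#' Partitions the points into the connected components of the graph that
#' links every pair of points at distance `<= r` (breadth-first propagation
#' from unvisited seeds). The partition is a property of the proximity graph,
#' so it does not depend on seed choice or traversal order.
#'
#' @param cloud a [point_cloud] or `n x 3` matrix.
#' @param r linking radius (meters). The pipeline default is
#'   `0.012 * bbox_diagonal(cloud)`.
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   index vectors), `sizes`, and `labels` (per-point cluster id).
#' @export
near_propagation_cluster <- function(cloud, r) {
  stopifnot(r > 0)
  P <- as_xyz_matrix(cloud)
  labels <- cpp_radius_components(P, r)
  clusters <- split(seq_len(nrow(P)), labels)
  names(clusters) <- NULL
  structure(list(clusters = clusters,
                 sizes = lengths(clusters),
                 labels = as.integer(labels)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d points (sizes %s%s)\n",
              length(x$clusters), length(x$labels),
              paste(head(sort(x$sizes, decreasing = TRUE), 5), collapse = ", "),
              if (length(x$sizes) > 5) ", ..." else ""))
  invisible(x)
}

#' Drop small clusters as scanning noise
#'
#' Clusters smaller than a density-derived threshold are considered scanning
#' noise and removed. The threshold is half the mean neighborhood count
#' (points within radius `r`, the point itself included) over `num` randomly
#' chosen probe points.
#'
#' @param clusters a `cluster_set` from [near_propagation_cluster()].
#' @param cloud the clustered [point_cloud].
#' @param r the clustering radius used.
#' @param num number of random probe points for the density estimate
#'   (default 10).
#' @param seed seed for the probe draw (default 0), making the estimate
#'   reproducible.
#' @return the merged [point_cloud] of all surviving clusters, with attribute
#'   `threshold` (the computed size cut) and `kept` (surviving cluster ids).
#' @export
drop_small_clusters <- function(clusters, cloud, r, num = 10, seed = 0) {
  stopifnot(inherits(clusters, "cluster_set"), num >= 1)
  n <- cloud$n
  if (length(clusters$labels) != n)
    stop("cluster set does not match the cloud")
  probes <- if (num >= n) seq_len(n) else
    withr_seed(seed, sample.int(n, num))
  dens <- cpp_radius_count(cloud$positions,
                           cloud$positions[probes, , drop = FALSE], r)
  threshold <- 0.5 * mean(dens)
  keep_cl <- which(clusters$sizes >= threshold)
  if (length(keep_cl) == 0)
    stop("no plant remains: every cluster fell below the density threshold ",
         "(check the clustering radius or the input cloud)")
  idx <- sort(unlist(clusters$clusters[keep_cl], use.names = FALSE))
  out <- cloud_subset(cloud, idx)
  attr(out, "threshold") <- threshold
  attr(out, "kept") <- keep_cl
  attr(out, "kept_index") <- idx
  out
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  seed <- abs(seed) %% 2147483647  # derived seeds must stay a valid integer
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Denoise a plant scan
#'
#' Convenience wrapper chaining pot removal (when pot colors are given) and
#' near-propagation cluster filtering.
#'
#' @param cloud a [point_cloud].
#' @param pot_colors optional matrix of sampled pot RGB colors.
#' @param pot_threshold color-difference cut for pot removal.
#' @param cluster_radius_factor clustering radius as a fraction of the
#'   bounding-box diagonal.
#' @param density_num probe count for the small-cluster threshold.
#' @param seed probe-draw seed.
#' @return the denoised plant [point_cloud].
#' @export
denoise_cloud <- function(cloud, pot_colors = NULL, pot_threshold = 0.1,
                          cluster_radius_factor = 0.012, density_num = 10,
                          seed = 0) {
  if (!is.null(pot_colors))
    cloud <- remove_pot(cloud, pot_colors, pot_threshold)$plant
  if (cloud$n == 0) stop("no plant remains after pot removal")
  r <- cluster_radius_factor * bbox_diagonal(cloud)
  cl <- near_propagation_cluster(cloud, r)
  drop_small_clusters(cl, cloud, r, num = density_num, seed = seed)
}
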