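#' Directionality degree of points in a cloud
#'
#' For each point, the covariance of its `k`-neighborhood about the
#' neighborhood centroid is eigen-decomposed (\eqn{\lambda_0 \le \lambda_1
#' \le \lambda_2}) and the directionality degree is
#' \eqn{l(v) = \lambda_2 / (\lambda_0 + \lambda_1 + \lambda_2)}. It is 1 when
#' the neighbors are perfectly collinear and approaches 1/3 in the isotropic
#' limit, so it drops wherever several branch directions mix, i.e. at
#' stem--leaf junctions.
#'
#' @param P `n x 3` matrix (or [point_cloud]) of positions.
#' @param k neighborhood size (default 10).
#' @return numeric vector of directionality values in `[1/3, 1]`; a point
#'   with a fully degenerate (coincident) neighborhood yields 1/3 with a
#'   warning.
#' @export
directionality <- function(P, k = 10) {
  P <- as_xyz_matrix(P)
  n <- nrow(P)
  if (n < k + 1) stop("need more than k points")
  nn <- cpp_knn(P, as.integer(k))
  out <- numeric(n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    V <- P[nn[i, ], , drop = FALSE]
    C <- sweep(V, 2, colMeans(V))
    ev <- eigen(crossprod(C), symmetric = TRUE, only.values = TRUE)$values
    tot <- sum(ev)
    if (tot <= 1e-24) {
      out[i] <- 1 / 3
      degenerate <- TRUE
    } else {
      out[i] <- max(ev) / tot
    }
  }
  if (degenerate)
    warning("coincident neighborhoods: directionality set to 1/3")
  out
}

#' Adaptive sphere sampling of a contracted cloud
#'
#' Reduces the contracted points to sparse skeleton key points by greedy
#' sphere absorption: the unabsorbed point with the most unabsorbed
#' neighbors seeds the next key point and absorbs everything unabsorbed
#' within its sampling radius; the absorbed set's centroid is emitted. Points
#' whose directionality degree falls below `joint_threshold` sit where
#' branch directions mix (stem--leaf junctions) and use the finer radius
#' `r_joint`, preserving geometry at branchings; elsewhere the coarser
#' `r_branch` applies. Note that a low directionality marks a junction: at a
#' branching the neighborhood spreads over two or more directions, so the
#' leading eigenvalue's share drops.
#'
#' @param state a `contraction_state` from [contract_cloud()], or a bare
#'   `n x 3` matrix of contracted positions.
#' @param r_branch sampling sphere radius along branches (meters).
#' @param r_joint finer radius at junctions; must satisfy
#'   `0 < r_joint < r_branch`.
#' @param joint_threshold directionality below which a point is treated as a
#'   junction (default 0.9).
#' @param k_cov neighborhood size for the directionality degree.
#' @return object of class `skeleton_points`: list with `positions` (key
#'   points, one per absorption sphere), `source_indices` (list of absorbed
#'   contracted-point indices per key point), `seed` (the seeding contracted
#'   point of each key point) and `directionality` (the seed's `l(v)`).
#' @export
adaptive_sample <- function(state, r_branch, r_joint, joint_threshold = 0.9,
                            k_cov = 10) {
  P <- if (inherits(state, "contraction_state")) state$P else as_xyz_matrix(state)
  n <- nrow(P)
  if (!(r_joint > 0 && r_joint < r_branch))
    stop("need 0 < r_joint < r_branch")
  if (n == 1) {
    return(structure(list(positions = P, source_indices = list(1L),
                          seed = 1L, directionality = 1),
                     class = "skeleton_points"))
  }
  lv <- if (n > k_cov) directionality(P, k_cov) else rep(1, n)
  res <- cpp_adaptive_sample(P, lv < joint_threshold, r_branch, r_joint)
  assign <- res$assign
  groups <- split(seq_len(n), assign)
  pos <- do.call(rbind, lapply(groups, function(ix)
    colMeans(P[ix, , drop = FALSE])))
  dimnames(pos) <- NULL
  # local curve tangent at each key point: leading principal direction of
  # the absorbed contracted points (NA when degenerate)
  tangent <- do.call(rbind, lapply(groups, function(ix) {
    if (length(ix) < 3) return(c(NA_real_, NA_real_, NA_real_))
    C <- sweep(P[ix, , drop = FALSE], 2, colMeans(P[ix, , drop = FALSE]))
    sv <- svd(C, nu = 0, nv = 3)
    if (sv$d[1] < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
    sv$v[, 1]
  }))
  dimnames(tangent) <- NULL
  structure(list(positions = pos,
                 source_indices = unname(groups),
                 seed = res$seeds,
                 directionality = lv[res$seeds],
                 tangent = tangent),
            class = "skeleton_points")
}

#' @export
print.skeleton_points <- function(x, ...) {
  cat(sprintf("skeleton_points: %d key points (%d joint-classified)\n",
              nrow(x$positions), sum(x$directionality < 0.9)))
  invisible(x)
}
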