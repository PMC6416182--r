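#' Calibrate the stem skeleton by per-section line fits
#'
#' Laplacian contraction bends the stem wherever a leaf attaches, because
#' the leaf points pull on their neighborhood; between attachments the stem
#' is straight. The growth points therefore split the stem into sections,
#' and each section's interior nodes (the growth points at its ends
#' excluded, as those are the bent ones) define a 3D total-least-squares
#' line onto which every node owned by the section is orthogonally
#' projected. Optionally the lowest section is extended downward along its
#' fitted line to the bottom of the original stem points, recovering the
#' base that contraction and sphere sampling pull up.
#'
#' @param skeleton a `plant_skeleton` from [segment_stem_leaves()].
#' @param stem_cloud optional `n x 3` matrix of original-cloud points (the
#'   full denoised cloud is fine: only points within 3.5 cm of the first
#'   section's line and near the base are used); when given, the base node
#'   is moved down the fitted line to their lower end (0.2% quantile along
#'   the line, robust to stray points), and never upward.
#' @return the `plant_skeleton` with straightened stem and updated leaf
#'   growth points; sections whose interior has fewer than two nodes are
#'   left untouched.
#' @export
calibrate_stem <- function(skeleton, stem_cloud = NULL) {
  stem <- skeleton$stem
  s <- nrow(stem)
  if (s < 3 && length(skeleton$growth_points) < 2) return(skeleton)
  # section boundaries: base, each growth point, tip
  gp <- sort(unique(skeleton$growth_points))
  bounds <- unique(c(1L, gp, s))
  new_stem <- stem
  first_line <- NULL
  for (b in seq_len(length(bounds) - 1)) {
    lo <- bounds[b]
    hi <- bounds[b + 1]
    interior <- setdiff(seq(lo, hi), gp)
    if (length(interior) < 2) next
    line <- tls_line(stem[interior, , drop = FALSE])
    if (line$dir[3] < 0) line$dir <- -line$dir  # orient upward
    if (is.null(first_line)) first_line <- line
    # a section owns its lower boundary; the last owns its top too
    own <- seq(lo, if (b == length(bounds) - 1) hi else hi - 1)
    new_stem[own, ] <- project_on_line(stem[own, , drop = FALSE], line)
  }
  if (!is.null(stem_cloud) && !is.null(first_line) && nrow(stem_cloud) > 0) {
    rel <- sweep(stem_cloud, 2, first_line$point)
    t_cloud <- as.numeric(rel %*% first_line$dir)
    lat <- sqrt(pmax(rowSums(rel^2) - t_cloud^2, 0))
    t_cur <- sum((new_stem[1, ] - first_line$point) * first_line$dir)
    near <- lat < 0.035 & t_cloud > t_cur - 0.4 & t_cloud < t_cur + 0.2
    if (sum(near) >= 20) {
      t_base <- quantile(t_cloud[near], 0.002, names = FALSE)
      # extension only reaches downward: a partial point set must never
      # raise the base
      t_base <- min(t_base, t_cur)
      new_stem[1, ] <- first_line$point + t_base * first_line$dir
    }
  }
  skeleton$stem <- new_stem
  # keep leaf polylines anchored at the (moved) growth points
  for (i in seq_along(skeleton$leaves))
    skeleton$leaves[[i]][1, ] <- new_stem[skeleton$growth_points[i], ]
  skeleton
}

#' Calibrate one leaf polyline against its original points
#'
#' Walking from the leaf base toward the tip, each node is replaced by the
#' centroid of the original leaf points inside the slab of half-thickness
#' `h` around the cutting plane through the node, perpendicular to the
#' tangent from its predecessor. Past the last node the cutting plane keeps
#' stepping forward by `s` along the running tangent, appending slab
#' centroids as new nodes, until a slab holds fewer than `min_slice_points`
#' points — this recovers the leaf tip that Laplacian contraction pulls
#' inward. Slab membership is limited to points within `3 h` of the plane
#' anchor laterally, so a plane does not pick up a distant part of a
#' strongly arched leaf.
#'
#' @param leaf ordered `m x 3` polyline, first node = growth point.
#' @param leaf_cloud matrix of original-cloud points attributed to this leaf.
#' @param h slab half-thickness; default half the mean inter-node spacing.
#' @param s forward step for tip extension; default the mean inter-node
#'   spacing.
#' @param min_slice_points minimum slab occupancy (default 3).
#' @return the calibrated polyline (possibly with more nodes than the
#'   input). With an empty `leaf_cloud` the input is returned with a
#'   warning.
#' @export
calibrate_leaf <- function(leaf, leaf_cloud, h = NULL, s = NULL,
                           min_slice_points = 3) {
  if (nrow(leaf) < 2) return(leaf)
  if (is.null(leaf_cloud) || nrow(leaf_cloud) == 0) {
    warning("empty leaf cloud: leaf left uncalibrated")
    return(leaf)
  }
  # a sampling spur can fold the polyline tail back onto itself; truncate at
  # the first strong direction reversal so the walk below runs tipward only
  if (nrow(leaf) >= 3) {
    segs <- diff(leaf)
    lens <- sqrt(rowSums(segs^2))
    for (i in 2:nrow(segs)) {
      if (lens[i] < 1e-12 || lens[i - 1] < 1e-12) next
      if (sum(segs[i, ] * segs[i - 1, ]) / (lens[i] * lens[i - 1]) < -0.3) {
        leaf <- leaf[seq_len(i), , drop = FALSE]
        break
      }
    }
  }
  spacing <- polyline_length(leaf) / (nrow(leaf) - 1)
  if (is.null(h)) h <- 0.5 * spacing
  if (is.null(s)) s <- spacing
  slab_centroid <- function(anchor, tangent) {
    t_along <- as.numeric(sweep(leaf_cloud, 2, anchor) %*% tangent)
    lat2 <- rowSums(sweep(leaf_cloud, 2, anchor)^2) - t_along^2
    inside <- abs(t_along) <= h & lat2 <= (3 * h)^2
    if (sum(inside) < min_slice_points) return(NULL)
    colMeans(leaf_cloud[inside, , drop = FALSE])
  }
  out <- leaf
  for (i in 2:nrow(out)) {
    # the first off-base node uses its outward neighbor for the tangent:
    # the segment from the (graph) growth node can point far off the vein
    tangent <- if (i == 2 && nrow(out) >= 3) out[3, ] - out[2, ]
               else out[i, ] - out[i - 1, ]
    if (vec_norm(tangent) < .Machine$double.eps) next
    ctr <- slab_centroid(out[i, ], unit(tangent))
    if (!is.null(ctr)) out[i, ] <- ctr
  }
  # tip extension
  repeat {
    m <- nrow(out)
    tangent <- out[m, ] - out[m - 1, ]
    if (vec_norm(tangent) < .Machine$double.eps) break
    tangent <- unit(tangent)
    anchor <- out[m, ] + s * tangent
    ctr <- slab_centroid(anchor, tangent)
    if (is.null(ctr)) break
    step_len <- vec_norm(ctr - out[m, ])
    if (step_len < 0.25 * s) break  # no forward progress left
    # never march back over territory the polyline already covers
    if (m > 2 &&
        min(sqrt(rowSums((out[seq_len(m - 2), , drop = FALSE] -
                          rep(ctr, each = m - 2))^2))) < 0.75 * s) break
    out <- rbind(out, ctr)
    if (nrow(out) > 10 * nrow(leaf) + 100) break  # safety stop
  }
  # close the residual gap to the farthest leaf point in the tangent
  # corridor, so a sparse slab near the narrowing tip cannot strand the
  # polyline short of the blade end
  m <- nrow(out)
  tangent <- out[m, ] - out[m - 1, ]
  if (vec_norm(tangent) > .Machine$double.eps) {
    tangent <- unit(tangent)
    rel <- sweep(leaf_cloud, 2, out[m, ])
    t_along <- as.numeric(rel %*% tangent)
    lat2 <- rowSums(rel^2) - t_along^2
    ahead <- t_along > h & lat2 <= (3 * h)^2
    if (any(ahead)) {
      t_max <- max(t_along[ahead])
      last <- ahead & t_along >= t_max - 2 * h
      if (sum(last) >= 1)
        out <- rbind(out, colMeans(leaf_cloud[last, , drop = FALSE]))
    }
  }
  out
}

#' Calibrate a whole plant skeleton against the original cloud
#'
#' Applies [calibrate_stem()] and then [calibrate_leaf()] to every leaf,
#' attributing original points to organs through the sampling
#' back-propagation: an original point belongs to the organ of the key point
#' that absorbed its contracted image.
#'
#' @param skeleton a `plant_skeleton`.
#' @param cloud the denoised original [point_cloud] (pre-contraction), whose
#'   row order matches the contracted positions.
#' @param samples the `skeleton_points` used to build the graph (for
#'   `source_indices`).
#' @param h,s,min_slice_points see [calibrate_leaf()]; `NULL` uses per-leaf
#'   defaults from the node spacing.
#' @param extend_base move the stem base down to the bottom of the stem
#'   points (default `TRUE`).
#' @return the calibrated `plant_skeleton`.
#' @export
calibrate_skeleton <- function(skeleton, cloud, samples, h = NULL, s = NULL,
                               min_slice_points = 3, extend_base = TRUE) {
  P0 <- as_xyz_matrix(cloud)
  # original points per graph node
  node_points <- samples$source_indices
  skeleton <- calibrate_stem(
    skeleton,
    stem_cloud = if (extend_base) P0 else NULL)
  for (i in seq_along(skeleton$leaves)) {
    own <- setdiff(skeleton$leaf_nodes[[i]], skeleton$stem_nodes)
    idx <- unlist(node_points[own], use.names = FALSE)
    skeleton$leaves[[i]] <- calibrate_leaf(
      skeleton$leaves[[i]], P0[idx, , drop = FALSE],
      h = h, s = s, min_slice_points = min_slice_points)
  }
  skeleton <- refine_growth_points(skeleton)
  skeleton$calibrated <- TRUE
  skeleton
}

# The growth point is the intersection of the leaf with the adjacent stem.
# Contraction merges the leaf sheath into the stem, so the tree's branching
# node sits well above the true attachment. The calibrated off-stem nodes
# lie on the vein (slab centroids of a near-symmetric ribbon), and a smooth
# vein is locally quadratic in arc length, so a least-squares quadratic
# through the first few off-stem nodes, extended backward to its closest
# approach to the stem line, recovers the attachment; the leaf base is then
# rebuilt from that curve so the first polyline segments follow the true
# base tangent.
refine_growth_points <- function(skeleton, max_shift = 0.35) {
  stem <- skeleton$stem
  for (i in seq_along(skeleton$leaves)) {
    L <- skeleton$leaves[[i]]
    m <- nrow(L)
    if (m < 4) next
    gi <- skeleton$growth_points[i]
    line <- stem_line_at(skeleton, gi)
    axis_d <- line$dir
    q <- line$point  # robust anchor: a junction stem node may be displaced
    # quadratic fit through the first K off-stem nodes, arc parameterized;
    # a short span keeps arc length a faithful quadratic parameter, so the
    # backward extrapolation stays unbiased. One junction-contaminated node
    # can wreck the extrapolated tangent, so nodes whose residual stands
    # far above the rest are dropped and the curve refitted.
    fit_q <- function(N) {
      s <- c(0, cumsum(sqrt(rowSums(diff(N)^2))))
      B <- cbind(1, s, s^2)
      cf <- tryCatch(qr.solve(B, N), error = function(e) NULL)
      if (is.null(cf)) return(NULL)
      resid <- sqrt(rowSums((B %*% cf - N)^2))
      list(cf = cf, resid = resid, s = s)
    }
    # the node adjacent to the junction is often an absorbed-blob remnant:
    # vet it against the curve through the nodes beyond it, and use it only
    # if it lies on that curve (it then shortens the extrapolation)
    first <- 2L
    K <- min(6, m - first)
    N <- L[first:(first + K - 1), , drop = FALSE]
    if (nrow(N) >= 4) {
      ft_out <- fit_q(N[-1, , drop = FALSE])
      if (!is.null(ft_out)) {
        d2 <- stats::optimize(function(uv)
          sqrt(sum((drop(c(1, uv, uv^2) %*% ft_out$cf) - N[1, ])^2)),
          c(-0.25, 0.1))$objective
        if (d2 > 0.015) {
          first <- 3L
          K <- min(5, m - first)
          N <- L[first:(first + K - 1), , drop = FALSE]
        }
      }
    }
    ft <- fit_q(N)
    if (is.null(ft)) next
    s <- ft$s
    if (nrow(N) >= 5) {
      worst <- which.max(ft$resid)
      if (ft$resid[worst] > 0.008 &&
          ft$resid[worst] > 2.5 * median(ft$resid)) {
        ft2 <- fit_q(N[-worst, , drop = FALSE])
        if (!is.null(ft2)) ft <- ft2
      }
    }
    cf <- ft$cf
    s <- ft$s
    curve_at <- function(sv) drop(c(1, sv, sv^2) %*% cf)
    dist_to_stem <- function(sv) {
      p <- curve_at(sv)
      w <- p - q
      vec_norm(w - sum(w * axis_d) * axis_d)
    }
    span <- max(s)
    opt <- stats::optimize(dist_to_stem, c(-1.5 * span, 0))
    # attachment estimate: where the backward curve first comes within
    # r_attach of the stem line (robust for erect leaves whose distance
    # minimum is shallow), continued to the stem along the local tangent.
    # The extrapolation counts only if the curve actually approaches the
    # stem; otherwise the raw attachment is kept (and bounded below).
    r_attach <- 0.03
    gp_new <- NULL
    s_star <- opt$minimum
    if (opt$objective <= 0.06 + 0.5 * vec_norm(L[2, ] - L[1, ])) {
      if (opt$objective < r_attach && dist_to_stem(0) > r_attach) {
        s_star <- stats::uniroot(function(sv) dist_to_stem(sv) - r_attach,
                                 c(opt$minimum, 0))$root
      }
      p_star <- curve_at(s_star)
      tang <- cf[2, ] + 2 * s_star * cf[3, ]
      if (vec_norm(tang) > 1e-9) {
        u <- unit(tang)
        b <- sum(axis_d * u)
        if (1 - b^2 > 0.01) {  # lines not near-parallel
          w0 <- q - p_star
          t_int <- (b * sum(u * w0) - sum(axis_d * w0)) / (1 - b^2)
          gp_new <- q + t_int * axis_d
        }
      }
      if (is.null(gp_new)) {
        w <- p_star - q
        gp_new <- q + sum(w * axis_d) * axis_d
      }
    }
    extrapolated <- !is.null(gp_new)
    if (extrapolated && gp_new[3] < L[1, 3] - 0.2) {
      # an attachment far below the branching node is implausible (the
      # merged sheath region is never that long): discard the extrapolation
      gp_new <- NULL
      extrapolated <- FALSE
    }
    if (!extrapolated) {
      # raw graph attachment, cleaned onto the stem line
      w <- L[1, ] - q
      gp_new <- q + sum(w * axis_d) * axis_d
      p_star <- N[1, ]
      s_star <- 0
    }
    # a vein bends only away from the stem axis, so the secant from the
    # attachment to the first measured node is steeper than the vein
    # tangent there: that bounds how high the attachment can sit. Any
    # estimate violating the bound clearly (an under-rotated extrapolation
    # or an un-refined graph attachment) is clamped to it, with the secant
    # as its tangent estimate.
    t0_clamp <- NULL
    w1 <- N[1, ] - q
    lat1 <- vec_norm(w1 - sum(w1 * axis_d) * axis_d)
    th_fit <- angle_between(cf[2, ], axis_d)
    th_fit <- min(th_fit, pi - th_fit)
    th_seg <- angle_between(N[2, ] - N[1, ], axis_d)
    th_seg <- min(th_seg, pi - th_seg)
    th1 <- max(th_fit, th_seg)  # conservative: keeps the bound valid
    if (th1 > 0.06 && lat1 > 0.01) {
      drop1 <- min(lat1 / tan(th1), 0.6)
      z_bound <- max(N[1, 3] - drop1, L[1, 3] - 0.2)
      if (gp_new[3] > z_bound + 0.015) {
        gp_new <- gp_new + ((z_bound - gp_new[3]) / axis_d[3]) * axis_d
        t0_clamp <- N[1, ] - gp_new
      }
    }
    if (!extrapolated && is.null(t0_clamp)) {
      # nothing better than the raw attachment: keep the polyline
      skeleton$leaves[[i]][1, ] <- gp_new
      skeleton$growth_points[i] <-
        which.min(colSums((t(stem) - gp_new)^2))
      next
    }
    gp_new[3] <- max(min(gp_new[3], max(stem[, 3])), min(stem[, 3]))
    if (vec_norm(gp_new - L[1, ]) > max_shift) next
    # base interpolation restarts from the attachment-side end of the curve
    s_star <- min(s_star, 0)
    # rebuild the leaf base: growth point plus two nodes along the vein
    # tangent *at the attachment* (the parabola derivative continued back to
    # the growth point), so the polyline's first segments measure the true
    # insertion angle rather than the already-curved blade a few cm out
    # the fitted quadratic treats curvature as constant in arc length while
    # a real vein straightens toward the sheath, so the derivative taken all
    # the way back at the attachment over-rotates; halfway between the
    # attachment and the closest measured approach balances the two
    s0 <- s_star - 0.25 * vec_norm(gp_new - p_star)
    t0 <- if (is.null(t0_clamp)) cf[2, ] + 2 * s0 * cf[3, ] else t0_clamp
    if (vec_norm(t0) < 1e-9) next
    t0 <- unit(t0)
    ds <- max(0.015, min(0.03, (vec_norm(p_star - gp_new) - s_star) / 3))
    base_nodes <- rbind(gp_new, gp_new + ds * t0, gp_new + 2 * ds * t0)
    new_leaf <- rbind(base_nodes, L[first:m, , drop = FALSE])
    # drop near-duplicate consecutive nodes (clamped interpolants)
    seg <- sqrt(rowSums(diff(new_leaf)^2))
    new_leaf <- new_leaf[c(TRUE, seg > 1e-4), , drop = FALSE]
    if (nrow(new_leaf) < 2) next
    skeleton$leaves[[i]] <- new_leaf
    skeleton$growth_points[i] <-
      which.min(colSums((t(stem) - gp_new)^2))
  }
  ord <- order(vapply(skeleton$leaves, function(L) L[1, 3], 0))
  skeleton$leaves <- skeleton$leaves[ord]
  skeleton$growth_points <- skeleton$growth_points[ord]
  skeleton$leaf_nodes <- skeleton$leaf_nodes[ord]
  skeleton
}
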