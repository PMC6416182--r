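#' Pipeline control parameters
#'
#' Collects every tunable of the skeleton-extraction pipeline with its
#' default. Radii are expressed as fractions of the bounding-box diagonal of
#' the denoised plant cloud, so the same settings serve plants of any size.
#'
#' @param target_points uniform-simplification target before processing.
#' @param pot_threshold color-difference cut for pot removal.
#' @param cluster_radius_factor radius of the noise-clustering proximity
#'   graph, as a fraction of the bounding-box diagonal.
#' @param density_num probe count for the small-cluster density threshold.
#' @param seed seed for the (few) random choices: density probes.
#' @param k_neighbors Laplacian neighborhood size.
#' @param s_l,w_l_init,w_l_cap,max_iters,converge_ratio,cot_clamp see
#'   [contract_control()].
#' @param sample_r_branch_factor,sample_r_joint_factor adaptive-sampling
#'   sphere radii (fractions of the bounding-box diagonal).
#' @param joint_threshold directionality below which a point samples with
#'   the finer joint radius.
#' @param k_cov neighborhood for the directionality degree.
#' @param base_k leaf-base segments used for the inclination tangent.
#' @param min_slice_points minimum cutting-plane slab occupancy during
#'   calibration.
#' @param slab_h,slab_s slab half-thickness and tip step; `NULL` derives
#'   them per leaf from the node spacing.
#' @param extend_base extend the stem base down to the stem points.
#' @return a named list of class `skel_control`.
#' @export
skel_control <- function(target_points = 10000,
                         pot_threshold = 0.1,
                         cluster_radius_factor = 0.012,
                         density_num = 10,
                         seed = 0,
                         k_neighbors = 10,
                         s_l = 3,
                         w_l_init = NULL,
                         w_l_cap = 2048,
                         max_iters = 20,
                         converge_ratio = 0.01,
                         cot_clamp = 1e4,
                         sample_r_branch_factor = 0.016,
                         sample_r_joint_factor = 0.0077,
                         joint_threshold = 0.9,
                         k_cov = 10,
                         base_k = 2,
                         min_slice_points = 3,
                         slab_h = NULL,
                         slab_s = NULL,
                         extend_base = TRUE) {
  structure(as.list(environment()), class = "skel_control")
}

#' Connect the components of a skeleton graph
#'
#' A 3-nearest-neighbor graph over the key points is occasionally split into
#' a few components (a leaf tip whose nearest neighbors are all taken, for
#' example). This helper repeatedly adds the shortest edge between the two
#' closest components until the graph is connected, so that loop breaking
#' can proceed.
#'
#' @param graph a `skeleton_graph`.
#' @return a connected `skeleton_graph`.
#' @export
connect_components <- function(graph) {
  repeat {
    g <- as_igraph(graph)
    comp <- igraph::components(g)$membership
    if (max(comp) == 1) return(graph)
    X <- graph$nodes
    best <- c(Inf, NA, NA)
    for (ca in seq_len(max(comp) - 1)) {
      ia <- which(comp == ca)
      ib <- which(comp > ca)
      D <- as.matrix(stats::dist(X))[ia, ib, drop = FALSE]
      k <- arrayInd(which.min(D), dim(D))
      if (D[k] < best[1]) best <- c(D[k], ia[k[1]], ib[k[2]])
    }
    graph <- skeleton_graph(X, rbind(graph$edges, best[2:3]))
  }
}

# An erect upper leaf whose base merged into the stem during contraction can
# surface as two polylines attached at nearby stem nodes on the same side.
# Fragments pointing the same way (azimuth within az_tol degrees) with
# attachments within `gap` meters vertically are one leaf: keep the
# lower-attached polyline and pool the node sets, so calibration rebuilds
# the full blade from the union cloud. `gap` must stay well below the
# vertical spacing of consecutive same-side leaves (two phyllotaxy steps),
# or neighbors would merge.
merge_leaf_fragments <- function(skel, gap = 0.08, az_tol = 25) {
  nl <- length(skel$leaves)
  if (nl < 2) return(skel)
  az <- vapply(skel$leaves, function(L) {
    v <- colMeans(L[-1, , drop = FALSE]) - L[1, ]
    atan2(v[2], v[1]) * 180 / pi
  }, 0)
  gz <- vapply(seq_len(nl), function(i)
    skel$stem[skel$growth_points[i], 3], 0)
  drop <- logical(nl)
  for (i in seq_len(nl - 1)) {
    if (drop[i]) next
    for (j in seq(i + 1, nl)) {
      if (drop[j]) next
      daz <- abs(((az[i] - az[j] + 180) %% 360) - 180)
      if (daz <= az_tol && abs(gz[i] - gz[j]) <= gap) {
        lo <- if (gz[i] <= gz[j]) i else j
        hi <- if (lo == i) j else i
        skel$leaf_nodes[[lo]] <- union(skel$leaf_nodes[[lo]],
                                       skel$leaf_nodes[[hi]])
        drop[hi] <- TRUE
      }
    }
  }
  skel$leaves <- skel$leaves[!drop]
  skel$growth_points <- skel$growth_points[!drop]
  skel$leaf_nodes <- skel$leaf_nodes[!drop]
  skel
}

# Degree-capped 3-NN admission occasionally leaves a vertical gap in the
# stem chain (a stem node's budget fills with shorter redundant links), so
# the only route upward runs out through a leaf and the traced stem stops
# at a fraction of the plant. Detect that (stem reach far below the node
# cloud top), bridge the stem tip to the nearest node above it in a narrow
# vertical corridor, and let loop breaking remove the detour instead.
repair_stem_gaps <- function(tree, diagl, max_attempts = 3) {
  reach <- function(tr) {
    sk <- segment_stem_leaves(tr)
    max(sk$stem[, 3])
  }
  for (a in seq_len(max_attempts)) {
    X <- tree$nodes
    z0 <- min(X[, 3])
    z_top <- max(X[, 3])
    r <- reach(tree)
    if (r - z0 > 0.7 * (z_top - z0)) break
    sk <- segment_stem_leaves(tree)
    tip_idx <- sk$stem_nodes[which.max(sk$stem[, 3])]
    tip <- X[tip_idx, ]
    horiz <- sqrt((X[, 1] - tip[1])^2 + (X[, 2] - tip[2])^2)
    cand <- which(X[, 3] > tip[3] + 0.01 & horiz < 0.08 * diagl)
    if (length(cand) == 0) break
    v <- cand[which.min(sqrt(rowSums((X[cand, , drop = FALSE] -
                                        rep(tip, each = length(cand)))^2)))]
    tree2 <- break_loops(skeleton_graph(X, rbind(tree$edges, c(tip_idx, v))))
    if (reach(tree2) > r + 0.05) tree <- tree2 else break
  }
  tree
}

#' Extract a maize plant skeleton from a point cloud
#'
#' Runs the full five-stage pipeline: uniform simplification, denoising (pot
#' removal by color difference where pot colors are supplied, then
#' near-propagation cluster filtering), Laplacian contraction, adaptive
#' sampling into key points, topological connection (3-nearest-neighbor
#' graph, loop breaking, stem/leaf segmentation) and calibration against the
#' denoised cloud. The result behaves like a fitted model: [print()],
#' [summary()], [plot()], [coef()][coef.plant_skeleton] (the trait table)
#' and [residuals()][residuals.plant_skeleton] (per-point distance from the
#' denoised cloud to the skeleton) methods are provided.
#'
#' @param cloud a [point_cloud] of one plant (with pot and clutter allowed).
#' @param control a [skel_control()] list.
#' @param pot_colors optional matrix of sampled pot RGB colors; `NULL` skips
#'   pot removal.
#' @return a `plant_skeleton` with, in addition to the skeleton fields of
#'   [segment_stem_leaves()]: `cloud` (the denoised cloud), `samples`,
#'   `contraction` (iteration diagnostics), `traits`, `control` and
#'   `stages` (per-stage point/node counts).
#' @examples
#' \donttest{
#' plant <- make_plant(plant_spec(seed = 1, height = 1.6,
#'                                points_per_plant = 6000))
#' skel <- extract_skeleton(plant$cloud,
#'                          pot_colors = plant$truth$pot_samples)
#' skel
#' coef(skel)
#' }
#' @export
extract_skeleton <- function(cloud, control = skel_control(),
                             pot_colors = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  stages <- list(input = cloud$n)
  cloud <- uniform_simplify(cloud, control$target_points)
  stages$simplified <- cloud$n
  denoised <- denoise_cloud(
    cloud, pot_colors = pot_colors,
    pot_threshold = control$pot_threshold,
    cluster_radius_factor = control$cluster_radius_factor,
    density_num = control$density_num, seed = control$seed)
  stages$denoised <- denoised$n
  cc <- contract_control(
    k_neighbors = control$k_neighbors, s_l = control$s_l,
    w_l_init = control$w_l_init, w_l_cap = control$w_l_cap,
    max_iters = control$max_iters, converge_ratio = control$converge_ratio,
    cot_clamp = control$cot_clamp)
  state <- contract_cloud(denoised, cc)
  diagl <- bbox_diagonal(denoised)
  samples <- adaptive_sample(
    state,
    r_branch = control$sample_r_branch_factor * diagl,
    r_joint = control$sample_r_joint_factor * diagl,
    joint_threshold = control$joint_threshold,
    k_cov = control$k_cov)
  stages$key_points <- nrow(samples$positions)
  graph <- connect_components(connect_knn(
    samples,
    tangents = samples$tangent,
    joint = samples$directionality < control$joint_threshold))
  tree <- break_loops(graph)
  tree <- repair_stem_gaps(tree, diagl)
  min_leaf <- 3 * control$sample_r_branch_factor * diagl
  skel <- segment_stem_leaves(tree, min_branch = min_leaf)
  # prune stub "leaves" (topology artifacts far shorter than any real leaf)
  keep <- vapply(skel$leaves, polyline_length, 0) >= min_leaf
  skel$leaves <- skel$leaves[keep]
  skel$growth_points <- skel$growth_points[keep]
  skel$leaf_nodes <- skel$leaf_nodes[keep]
  skel <- merge_leaf_fragments(skel)
  stages$leaves <- length(skel$leaves)
  skel <- calibrate_skeleton(
    skel, denoised, samples,
    h = control$slab_h, s = control$slab_s,
    min_slice_points = control$min_slice_points,
    extend_base = control$extend_base)
  # calibration can collapse a leaf that was only a junction artifact
  # (reversal truncation shrinks it below any real blade): prune again
  keep <- vapply(skel$leaves, polyline_length, 0) >= min_leaf
  if (!all(keep)) {
    skel$leaves <- skel$leaves[keep]
    skel$growth_points <- skel$growth_points[keep]
    skel$leaf_nodes <- skel$leaf_nodes[keep]
    stages$leaves <- length(skel$leaves)
  }
  skel$cloud <- denoised
  skel$samples <- samples
  skel$contraction <- list(iterations = state$iterations,
                           ring_history = state$ring_history)
  skel$traits <- skeleton_traits(skel, base_k = control$base_k)
  skel$control <- control
  skel$stages <- stages
  skel
}

#' @export
print.plant_skeleton <- function(x, ...) {
  cat(sprintf("plant_skeleton: stem of %d nodes, %d leaves%s\n",
              nrow(x$stem), length(x$leaves),
              if (isTRUE(x$calibrated)) ", calibrated" else ""))
  if (!is.null(x$traits))
    cat(sprintf("  plant height %.3f m; leaf lengths %.2f-%.2f m\n",
                attr(x$traits, "plant_height"),
                min(x$traits$leaf_length_m), max(x$traits$leaf_length_m)))
  invisible(x)
}

#' @export
summary.plant_skeleton <- function(object, ...) {
  print(object)
  if (!is.null(object$stages)) {
    cat("  stages:",
        paste(names(object$stages), unlist(object$stages), sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(object$contraction))
    cat(sprintf("  contraction: %d iterations, one-ring length ratio %.3f\n",
                object$contraction$iterations,
                tail(object$contraction$ring_history, 1) /
                  object$contraction$ring_history[1]))
  if (!is.null(object$traits)) {
    cat("  traits:\n")
    print(object$traits, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Trait table of a fitted skeleton
#'
#' @param object a `plant_skeleton` from [extract_skeleton()].
#' @param ... unused.
#' @return the trait `data.frame` (see [skeleton_traits()]).
#' @export
coef.plant_skeleton <- function(object, ...) {
  if (is.null(object$traits)) skeleton_traits(object) else object$traits
}

#' Distances from the cloud to the fitted skeleton
#'
#' For every point of the denoised cloud, the distance to the nearest
#' skeleton segment — a goodness-of-fit measure of the skeleton to the
#' cloud (large residuals flag organs the skeleton missed).
#'
#' @param object a `plant_skeleton` carrying its `cloud`.
#' @param ... unused.
#' @return numeric vector of distances (meters).
#' @export
residuals.plant_skeleton <- function(object, ...) {
  if (is.null(object$cloud)) stop("skeleton carries no cloud")
  P <- object$cloud$positions
  polys <- c(list(object$stem), object$leaves)
  best <- rep(Inf, nrow(P))
  for (L in polys) {
    if (nrow(L) < 2) next
    for (s in seq_len(nrow(L) - 1))
      best <- pmin(best, dist_point_segment(P, L[s, ], L[s + 1, ]))
  }
  best
}

# distance from each row of P to segment [a, b]
dist_point_segment <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < .Machine$double.eps) return(sqrt(rowSums(sweep(P, 2, a)^2)))
  t <- pmin(1, pmax(0, as.numeric(sweep(P, 2, a) %*% ab) / len2))
  sqrt(rowSums((P - (outer(t, ab) + rep(a, each = nrow(P))))^2))
}

#' Plot a plant skeleton over its cloud
#'
#' Two-dimensional orthographic projection (xz by default) of the denoised
#' cloud with the stem and leaf polylines drawn on top.
#'
#' @param x a `plant_skeleton`.
#' @param which projection plane: `"xz"`, `"yz"` or `"xy"`.
#' @param ... passed to [plot.point_cloud()].
#' @export
plot.plant_skeleton <- function(x, which = c("xz", "yz", "xy"), ...) {
  which <- match.arg(which)
  idx <- match(strsplit(which, "")[[1]], c("x", "y", "z"))
  if (!is.null(x$cloud)) {
    plot(x$cloud, which = which, ...)
  } else {
    allp <- do.call(rbind, c(list(x$stem), x$leaves))
    plot(allp[, idx[1]], allp[, idx[2]], type = "n", asp = 1,
         xlab = substr(which, 1, 1), ylab = substr(which, 2, 2))
  }
  graphics::lines(x$stem[, idx[1]], x$stem[, idx[2]], col = "black", lwd = 2)
  for (L in x$leaves)
    graphics::lines(L[, idx[1]], L[, idx[2]], col = "red3", lwd = 1.5)
  invisible(x)
}

# ---------------------------------------------------------------------------
# skeleton export

#' Write a skeleton to OBJ or JSON
#'
#' `write_skeleton_obj()` writes `v`/`l` records (one polyline per organ);
#' `write_skeleton_json()` writes `{nodes, edges, labels}` with stem and
#' leaf node index lists.
#'
#' @param skeleton a `plant_skeleton`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skeleton_obj <- function(skeleton, path) {
  polys <- c(list(skeleton$stem), skeleton$leaves)
  lines <- character(0)
  offset <- 0
  for (L in polys) {
    lines <- c(lines,
               sprintf("v %.9g %.9g %.9g", L[, 1], L[, 2], L[, 3]),
               paste("l", paste(offset + seq_len(nrow(L)), collapse = " ")))
    offset <- offset + nrow(L)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_skeleton_obj
#' @export
write_skeleton_json <- function(skeleton, path) {
  polys <- c(list(skeleton$stem), skeleton$leaves)
  nodes <- do.call(rbind, polys)
  sizes <- vapply(polys, nrow, 0L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  edges <- do.call(rbind, lapply(seq_along(polys), function(i) {
    if (sizes[i] < 2) return(NULL)
    cbind(starts[i]:(ends[i] - 1), (starts[i] + 1):ends[i])
  }))
  obj <- list(nodes = unname(apply(nodes, 1, as.numeric, simplify = FALSE)),
              edges = unname(apply(edges, 1, as.integer, simplify = FALSE)),
              labels = list(
                stem = as.integer(starts[1]:ends[1]),
                leaves = lapply(seq_along(skeleton$leaves), function(i)
                  as.integer(starts[i + 1]:ends[i + 1]))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Run the study protocol: pipeline on synthetic plants, traits vs truth
#'
#' Generates a multi-plant synthetic study, runs [extract_skeleton()] on
#' every cloud, rank-matches predicted and ground-truth leaves, and
#' evaluates per-trait NRMSE and R-squared across all plants (plant height
#' counted once per plant).
#'
#' @param n_plants,seed,difficulty,points_per_plant see [make_study()].
#' @param control a [skel_control()].
#' @return list with `eval` (a `trait_eval` table), `pred` / `truth`
#'   (stacked leaf-level tables with a `plant` column), `pred_plants` /
#'   `truth_plants` (plant-level height tables) and `skeletons`.
#' @export
run_study <- function(n_plants = 6, seed = 1, difficulty = "realistic",
                      points_per_plant = 10000, control = skel_control()) {
  study <- make_study(n_plants, seed, difficulty, points_per_plant)
  pred <- truth <- list()
  skels <- list()
  for (i in seq_along(study)) {
    pl <- study[[i]]
    skel <- extract_skeleton(pl$cloud, control,
                             pot_colors = if (pl$truth$spec$pot)
                               pl$truth$pot_samples else NULL)
    pt <- coef(skel)
    tt <- pl$truth$traits
    pt$plant <- i
    tt$plant <- i
    pred[[i]] <- pt
    truth[[i]] <- tt
    skels[[i]] <- skel
  }
  # leaves are matched to ground truth in growth-height order by monotone
  # sequence alignment: pairing cost combines attachment-height difference
  # with azimuth disagreement, and either side may skip a row (a missed or
  # spurious leaf then costs its own row instead of shifting every rank
  # above it, which is what matching by physical identity would do). A
  # near-tie rank inversion resolves through the azimuth term.
  match_rank <- function(p, t) {
    np <- nrow(p); nt <- nrow(t)
    daz <- function(a, b) min(abs(a - b), 360 - abs(a - b))
    cost <- function(i, j)
      abs(p$growth_height_m[i] - t$growth_height_m[j]) +
        0.15 * daz(p$azimuth_deg[i], t$azimuth_deg[j]) / 180
    gap <- 0.12
    D <- matrix(0, np + 1, nt + 1)
    D[, 1] <- (0:np) * gap
    D[1, ] <- (0:nt) * gap
    for (i in seq_len(np)) for (j in seq_len(nt))
      D[i + 1, j + 1] <- min(D[i, j] + cost(i, j),
                             D[i, j + 1] + gap,
                             D[i + 1, j] + gap)
    ip <- np; jt <- nt
    pi_idx <- ti_idx <- integer(0)
    while (ip > 0 && jt > 0) {
      if (abs(D[ip + 1, jt + 1] - (D[ip, jt] + cost(ip, jt))) < 1e-12) {
        pi_idx <- c(ip, pi_idx); ti_idx <- c(jt, ti_idx)
        ip <- ip - 1; jt <- jt - 1
      } else if (abs(D[ip + 1, jt + 1] - (D[ip, jt + 1] + gap)) < 1e-12) {
        ip <- ip - 1
      } else {
        jt <- jt - 1
      }
    }
    list(p = p[pi_idx, ], t = t[ti_idx, ])
  }
  matched <- Map(match_rank, pred, truth)
  pred_all <- do.call(rbind, lapply(matched, `[[`, "p"))
  truth_all <- do.call(rbind, lapply(matched, `[[`, "t"))
  pred_plants <- do.call(rbind, lapply(pred, function(d) d[1, , drop = FALSE]))
  truth_plants <- do.call(rbind, lapply(truth, function(d) d[1, , drop = FALSE]))
  ev <- evaluate_traits(pred_all, truth_all, pred_plants, truth_plants)
  list(eval = ev, pred = pred_all, truth = truth_all,
       pred_plants = pred_plants, truth_plants = truth_plants,
       skeletons = skels)
}

#' Write / read pipeline control settings as YAML
#'
#' The full [skel_control()] list round-trips losslessly through a YAML
#' file, so a study's settings can be archived next to its outputs.
#'
#' @param control a [skel_control()] list.
#' @param path YAML file path.
#' @return `read_control()` returns a `skel_control`; `write_control()`
#'   returns `path` invisibly.
#' @export
write_control <- function(control, path) {
  stopifnot(inherits(control, "skel_control"))
  yaml::write_yaml(unclass(control), path)
  invisible(path)
}

#' @rdname write_control
#' @export
read_control <- function(path) {
  vals <- yaml::read_yaml(path)
  ctl <- skel_control()
  unknown <- setdiff(names(vals), names(ctl))
  if (length(unknown) > 0)
    stop("unknown control keys: ", paste(unknown, collapse = ", "))
  for (k in names(vals)) ctl[k] <- list(vals[[k]])  # keeps NULLs
  ctl
}
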