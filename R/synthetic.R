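#' Specification of one procedural maize plant
#'
#' Draws a complete, explicit parameter set for one synthetic plant:
#' insertion heights, inclinations, azimuths (alternate 180-degree
#' phyllotaxy with jitter), vein arc geometry and blade widths for every
#' leaf, plus stem, pot, noise and outlier settings. All per-leaf draws are
#' deterministic functions of `seed`. The defaults emulate a field-grown
#' plant between the jointing and silking stages: a near-vertical stem
#' 1--2.6 m tall carrying 5--15 leaves whose veins rise from the sheath,
#' arch over a highest point and droop toward the tip, the uppermost leaves
#' erect enough that a leaf apex (not the stem) is the plant's highest
#' point, as in a pre-tassel canopy.
#'
#' @param seed integer seed; every draw derives from it.
#' @param height nominal stem height in meters (1.0--2.6 covers the staged
#'   plants this emulates).
#' @param n_leaves leaf count; default scales with height
#'   (`round(6 + 3.2 * height)`), keeping junctions separated.
#' @param stem_radius stem cylinder radius (m).
#' @param tilt_deg stem lean from vertical (degrees).
#' @param noise_sigma isotropic Gaussian sensor noise (m).
#' @param points_per_plant number of plant-surface points.
#' @param pot include a pot annulus below the plant.
#' @param pot_color base RGB of the pot; scanned pot colors are this color
#'   under varying illumination (brightness scaling 0.9--1.1).
#' @param outlier_fraction fraction of `points_per_plant` added as sparse
#'   clutter clusters away from the plant.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(seed = 1, height = 2.0, n_leaves = NULL,
                       stem_radius = 0.012, tilt_deg = NULL,
                       noise_sigma = 0.004, points_per_plant = 10000,
                       pot = TRUE, pot_color = c(180, 90, 45),
                       outlier_fraction = 0.01) {
  stopifnot(height > 0.3, stem_radius > 0, noise_sigma >= 0,
            points_per_plant >= 200, outlier_fraction >= 0)
  if (is.null(n_leaves)) n_leaves <- round(6 + 3.2 * height)
  if (n_leaves < 1) stop("need at least one leaf")
  withr_seed(seed * 7919 + 13, {
    if (is.null(tilt_deg)) tilt_deg <- runif(1, 0, 1.5)
    n <- n_leaves
    # insertion height fractions: positive jittered gaps over [0.13, 0.97]
    # the uppermost collar sits well below the stem apex (the peduncle
    # region is leafless), so insertions span 13-92% of stem height
    gaps <- runif(n - 1, 0.6, 1.4)
    f <- if (n == 1) 0.6 else 0.13 + 0.79 * c(0, cumsum(gaps)) / sum(gaps)
    # lower leaves spread, upper more erect but fully unfolded: insertion
    # angles below ~25 degrees would model the still-furled uppermost
    # leaves of a pre-silking whorl, which these plants deliberately lack
    theta <- pmax(22, pmin(66, 58 - 30 * f + runif(n, -4, 4)))
    phi <- (runif(1, 0, 360) + 180 * (seq_len(n) - 1) +
              c(0, cumsum(runif(n - 1, -10, 10)))[seq_len(n)]) %% 360
    vein_length <- (0.32 + 0.30 * height) *
      (0.60 + 0.40 * sin(pi * pmin(f, 0.97)^0.9)) * runif(n, 0.95, 1.05)
    droop_deg <- pmax(12, 20 + 25 * (1 - f) + runif(n, -5, 5))
    droop_b <- runif(n, 0.75, 1.0)
    width_max <- 0.045 + 0.05 * vein_length / max(vein_length)
  })
  if (any(diff(f) <= 0)) stop("insertion heights must be strictly increasing")
  structure(list(seed = seed, height = height, n_leaves = n_leaves,
                 stem_radius = stem_radius, tilt_deg = tilt_deg,
                 noise_sigma = noise_sigma,
                 points_per_plant = points_per_plant, pot = pot,
                 pot_color = pot_color, outlier_fraction = outlier_fraction,
                 insertion_frac = f, inclination_deg = theta,
                 azimuth_deg = phi, vein_length = vein_length,
                 droop_deg = droop_deg, droop_b = droop_b,
                 width_max = width_max),
            class = "plant_spec")
}

# quadratic Bezier and helpers -----------------------------------------------

bezier_point <- function(t, P0, P1, P2) {
  outer((1 - t)^2, P0) + outer(2 * t * (1 - t), P1) + outer(t^2, P2)
}

# cumulative arc length on a dense t grid
bezier_arc_table <- function(P0, P1, P2, m = 2000) {
  t <- seq(0, 1, length.out = m + 1)
  B <- bezier_point(t, P0, P1, P2)
  seg <- sqrt(rowSums((B[-1, , drop = FALSE] - B[-(m + 1), , drop = FALSE])^2))
  list(t = t, cum = c(0, cumsum(seg)))
}

# leaf vein control points in world coordinates for leaf i of a spec
leaf_geometry <- function(spec, i, axis, e1, e2) {
  u <- spec$insertion_frac[i] * spec$height
  P0 <- u * axis
  phi <- rad(spec$azimuth_deg[i])
  uphi <- c(cos(phi), sin(phi), 0)
  w <- uphi - sum(uphi * axis) * axis
  w <- unit(w)
  theta <- rad(spec$inclination_deg[i])
  d <- cos(theta) * axis + sin(theta) * w
  a <- 0.5 * spec$vein_length[i]
  P1 <- P0 + a * d
  psi <- rad(spec$droop_deg[i])
  e <- cos(psi) * w - sin(psi) * axis
  P2 <- P1 + spec$droop_b[i] * a * e
  list(P0 = P0, P1 = P1, P2 = P2, w = w, d = d, theta = theta)
}

#' Generate a synthetic maize plant point cloud with exact ground truth
#'
#' Builds the surface point cloud of the plant described by a
#' [plant_spec()]: stem points on a cylinder around a (slightly leaning)
#' axis, leaf points on ribbons around planar quadratic Bezier vein curves
#' whose width tapers to zero at the tip, plus isotropic Gaussian sensor
#' noise, an optional brown pot frustum below the plant and sparse outlier
#' clutter. Every point carries a ground-truth label. The returned ground
#' truth holds the analytic vein curves (finely sampled), a skeleton-shaped
#' version of them, and the trait table computed from the exact geometry.
#'
#' @param spec a [plant_spec()] (or a seed, passed through to `plant_spec()`).
#' @return list with elements `cloud` (a [point_cloud]), `labels` (character
#'   vector: `"stem"`, `"leaf_<i>"`, `"pot"`, `"outlier"`), `truth` (list:
#'   `spec`, `stem` fine polyline, `leaves` fine vein polylines,
#'   `skeleton` a `plant_skeleton`-shaped list, `traits` analytic trait
#'   table, `pot_samples` five illumination-spread pot colors).
#' @export
make_plant <- function(spec = plant_spec()) {
  if (is.numeric(spec)) spec <- plant_spec(seed = spec)
  stopifnot(inherits(spec, "plant_spec"))
  tilt <- rad(spec$tilt_deg)
  withr_seed(spec$seed * 104729 + 71, {
    tdir <- runif(1, 0, 2 * pi)
    axis <- c(sin(tilt) * cos(tdir), sin(tilt) * sin(tdir), cos(tilt))
    # orthonormal frame around the axis
    e1 <- unit(cross3(axis, c(0, 0, 1) + c(1e-4, 0, 0)))
    e2 <- cross3(axis, e1)
    n <- spec$n_leaves
    geo <- lapply(seq_len(n), leaf_geometry, spec = spec, axis = axis,
                  e1 = e1, e2 = e2)
    arcs <- lapply(geo, function(g) bezier_arc_table(g$P0, g$P1, g$P2))
    arc_len <- vapply(arcs, function(a) tail(a$cum, 1), 0)
    # point budget split by surface area
    stem_area <- 2 * pi * spec$stem_radius * spec$height
    leaf_area <- arc_len * spec$width_max * 0.7
    wts <- c(stem_area * 2.5, leaf_area)  # cylinder seen from all around
    counts <- pmax(30, round(spec$points_per_plant * wts / sum(wts)))
    # stem cylinder points
    ns <- counts[1]
    us <- runif(ns, 0, spec$height)
    om <- runif(ns, 0, 2 * pi)
    stem_pts <- outer(us, axis) + spec$stem_radius *
      (outer(cos(om), e1) + outer(sin(om), e2))
    pts <- list(stem_pts)
    labs <- list(rep("stem", ns))
    cols <- list(jitter_color(c(60, 140, 50), 10, ns))
    for (i in seq_len(n)) {
      ni <- counts[i + 1]
      # uniform by arc length via the inverse cumulative table
      si <- runif(ni, 0, arc_len[i])
      ti <- approx(arcs[[i]]$cum, arcs[[i]]$t, xout = si)$y
      B <- bezier_point(ti, geo[[i]]$P0, geo[[i]]$P1, geo[[i]]$P2)
      nvec <- unit(cross3(geo[[i]]$w, axis))
      halfw <- 0.5 * spec$width_max[i] * pmax(0, sin(pi * ti))^0.6
      lat <- runif(ni, -1, 1) * halfw
      pts <- c(pts, list(B + outer(lat, nvec)))
      labs <- c(labs, list(rep(paste0("leaf_", i), ni)))
      cols <- c(cols, list(jitter_color(c(40, 150, 40), 10, ni)))
    }
    plant <- do.call(rbind, pts)
    if (spec$noise_sigma > 0)
      plant <- plant + matrix(rnorm(length(plant), 0, spec$noise_sigma),
                              ncol = 3)
    labels <- unlist(labs)
    colors <- do.call(rbind, cols)
    # pot: truncated cone wall below the plant base
    if (spec$pot) {
      np <- round(0.12 * nrow(plant))
      v <- runif(np)
      rad_p <- 0.10 + 0.04 * v
      omp <- runif(np, 0, 2 * pi)
      pot_pts <- cbind(rad_p * cos(omp), rad_p * sin(omp), -0.17 + 0.17 * v)
      if (spec$noise_sigma > 0)
        pot_pts <- pot_pts + matrix(rnorm(length(pot_pts), 0,
                                          spec$noise_sigma), ncol = 3)
      sfac <- runif(np, 0.9, 1.1)
      pot_cols <- round(outer(sfac, spec$pot_color))
      plant <- rbind(plant, pot_pts)
      labels <- c(labels, rep("pot", np))
      colors <- rbind(colors, pot_cols)
    }
    # sparse clutter: small tight clusters away from every plant point
    n_out <- round(spec$outlier_fraction * spec$points_per_plant)
    if (n_out > 0) {
      lo <- apply(plant, 2, min) - 0.15
      hi <- apply(plant, 2, max) + 0.15
      n_cl <- max(1, round(n_out / 6))
      centers <- matrix(0, 0, 3)
      tries <- 0
      while (nrow(centers) < n_cl && tries < 200 * n_cl) {
        cand <- matrix(lo + runif(3) * (hi - lo), 1)
        tries <- tries + 1
        if (cpp_radius_count(plant, cand, 0.09)[1] == 0)
          centers <- rbind(centers, cand)
      }
      if (nrow(centers) > 0) {
        sizes <- diff(round(seq(0, n_out, length.out = nrow(centers) + 1)))
        out_pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
          centers[rep(i, sizes[i]), , drop = FALSE] +
            matrix(rnorm(3 * sizes[i], 0, 0.004), ncol = 3)))
        keep <- nrow(out_pts)
        plant <- rbind(plant, out_pts)
        labels <- c(labels, rep("outlier", keep))
        colors <- rbind(colors, jitter_color(c(120, 130, 220), 15, keep))
      }
    }
    cloud <- point_cloud(plant, colors)
  })
  truth <- make_ground_truth(spec)
  list(cloud = cloud, labels = labels, truth = truth)
}

jitter_color <- function(base, amp, n) {
  m <- round(matrix(rep(base, each = n), n) +
               matrix(runif(3 * n, -amp, amp), n))
  # pmin/pmax take attributes from their first argument: keep the matrix first
  pmin(pmax(m, 0), 255)
}

# analytic ground truth: fine polylines and the exact trait table
make_ground_truth <- function(spec) {
  tilt <- rad(spec$tilt_deg)
  withr_seed(spec$seed * 104729 + 71, {
    tdir <- runif(1, 0, 2 * pi)  # same draw order as make_plant
    axis <- c(sin(tilt) * cos(tdir), sin(tilt) * sin(tdir), cos(tilt))
    e1 <- unit(cross3(axis, c(0, 0, 1) + c(1e-4, 0, 0)))
    e2 <- cross3(axis, e1)
  })
  n <- spec$n_leaves
  geo <- lapply(seq_len(n), leaf_geometry, spec = spec, axis = axis,
                e1 = e1, e2 = e2)
  stem_fine <- outer(seq(0, spec$height, length.out = 200), axis)
  leaves_fine <- lapply(geo, function(g) {
    t <- seq(0, 1, length.out = 400)
    bezier_point(t, g$P0, g$P1, g$P2)
  })
  # exact traits
  arc <- lapply(geo, function(g) bezier_arc_table(g$P0, g$P1, g$P2, 4000))
  len <- vapply(arc, function(a) tail(a$cum, 1), 0)
  top_len <- vapply(seq_len(n), function(i) {
    g <- geo[[i]]
    z0 <- g$P0[3]; z1 <- g$P1[3]; z2 <- g$P2[3]
    den <- (z1 - z0) - (z2 - z1)
    tstar <- if (abs(den) < 1e-15) 1 else (z1 - z0) / den
    tstar <- max(0, min(1, tstar))
    approx(arc[[i]]$t, arc[[i]]$cum, xout = tstar)$y
  }, 0)
  w1 <- geo[[1]]$w
  azim <- vapply(geo, function(g) {
    ang <- atan2(sum(axis * cross3(w1, g$w)), sum(w1 * g$w))
    (deg(ang) + 360) %% 360
  }, 0)
  gh <- vapply(geo, function(g) g$P0[3], 0)
  apex_z <- vapply(seq_len(n), function(i) max(leaves_fine[[i]][, 3]), 0)
  ph <- max(spec$height * axis[3], apex_z)
  traits <- data.frame(
    leaf_rank = seq_len(n),
    leaf_length_m = len,
    inclination_deg = spec$inclination_deg,
    top_length_m = top_len,
    azimuth_deg = azim,
    growth_height_m = gh,
    plant_height_m = ph)
  attr(traits, "plant_height") <- ph
  gp_idx <- vapply(spec$insertion_frac, function(f)
    which.min(abs(seq(0, 1, length.out = 200) - f)), 0L)
  skeleton <- structure(list(stem = stem_fine, leaves = leaves_fine,
                             growth_points = gp_idx,
                             stem_nodes = seq_len(200),
                             leaf_nodes = NULL, graph = NULL),
                        class = "plant_skeleton")
  pot_samples <- t(vapply(c(0.9, 0.95, 1.0, 1.05, 1.1),
                          function(s) round(spec$pot_color * s), numeric(3)))
  list(spec = spec, axis = axis, stem = stem_fine, leaves = leaves_fine,
       skeleton = skeleton, traits = traits, pot_samples = pot_samples)
}

#' Generate a multi-plant synthetic study
#'
#' Draws `n_plants` plant specifications spanning the jointing-to-silking
#' size range (stem heights 1.1--2.4 m, leaf counts scaling with height) and
#' generates each plant. `"easy"` plants are nearly noise-free
#' (`noise_sigma = 0.001`, no pot, no outliers); `"realistic"` plants carry
#' `noise_sigma = 0.004`, a pot and 1% outlier clutter, emulating an indoor
#' terrestrial-laser scan after registration.
#'
#' @param n_plants number of plants.
#' @param seed study seed; plant `i` uses a seed derived from it.
#' @param difficulty `"easy"` or `"realistic"`.
#' @param points_per_plant surface points per plant (default 10000).
#' @return list of `make_plant()` results, one per plant.
#' @export
make_study <- function(n_plants = 6, seed = 1,
                       difficulty = c("realistic", "easy"),
                       points_per_plant = 10000) {
  difficulty <- match.arg(difficulty)
  heights <- withr_seed(seed * 31 + 7,
                        seq(1.1, 2.4, length.out = n_plants) +
                          runif(n_plants, -0.08, 0.08))
  lapply(seq_len(n_plants), function(i) {
    spec <- plant_spec(
      seed = (seed * 1000 + i) %% 2147483647,
      height = heights[i],
      noise_sigma = if (difficulty == "easy") 0.001 else 0.004,
      points_per_plant = points_per_plant,
      pot = difficulty == "realistic",
      outlier_fraction = if (difficulty == "easy") 0 else 0.01)
    make_plant(spec)
  })
}
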