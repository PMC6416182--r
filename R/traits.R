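#' Leaf length along a skeleton polyline
#'
#' Sum of the Euclidean distances between consecutive skeleton nodes from
#' the leaf base (growth point) to the tip.
#'
#' @param leaf ordered `m x 3` polyline (m >= 2).
#' @return length in meters.
#' @export
leaf_length <- function(leaf) {
  if (nrow(leaf) < 2) stop("a leaf polyline needs at least two nodes")
  polyline_length(leaf)
}

#' Leaf inclination angle
#'
#' Angle between the tangent of the leaf base and the stem axis at the
#' growth point. The base tangent is the mean of the unit directions of the
#' first `base_k` polyline segments.
#'
#' @param leaf ordered `m x 3` polyline starting at the growth point.
#' @param stem_axis unit vector of the stem axis at the growth point
#'   (pointing up).
#' @param base_k number of base segments averaged (default 2).
#' @return angle in degrees, in `[0, 180]`.
#' @export
inclination_angle <- function(leaf, stem_axis, base_k = 2) {
  if (nrow(leaf) < 2) stop("a leaf polyline needs at least two nodes")
  base_k <- min(base_k, nrow(leaf) - 1)
  dirs <- vapply(seq_len(base_k), function(i)
    unit(leaf[i + 1, ] - leaf[i, ]), numeric(3))
  tangent <- rowMeans(dirs)
  deg(angle_between(tangent, unit(stem_axis)))
}

#' Leaf top length
#'
#' Polyline arc length from the leaf base to the highest point of the leaf.
#' The height profile is nearly flat around the apex of an arching leaf, so
#' the apex position is refined by fitting a quadratic to z over arc length
#' through the highest node and its neighbors (interior apexes only); with
#' ties the first maximal node wins. Never exceeds the leaf length.
#'
#' @inheritParams leaf_length
#' @return length in meters.
#' @export
top_length <- function(leaf) {
  if (nrow(leaf) < 2) stop("a leaf polyline needs at least two nodes")
  m <- nrow(leaf)
  apex <- which.max(leaf[, 3])
  if (apex == 1) return(0)
  seg <- sqrt(rowSums(diff(leaf)^2))
  s <- c(0, cumsum(seg))
  s_apex <- s[apex]
  lo <- max(1, apex - 2)
  hi <- min(m, apex + 2)
  if (apex > 1 && apex < m && hi - lo >= 2) {
    ss <- s[lo:hi]
    zz <- leaf[lo:hi, 3]
    fit <- stats::lm.fit(cbind(1, ss, ss^2), zz)
    a2 <- fit$coefficients[3]
    if (is.finite(a2) && a2 < 0) {
      s_v <- -fit$coefficients[2] / (2 * a2)
      if (s_v >= ss[1] && s_v <= ss[length(ss)]) s_apex <- s_v
    }
  }
  min(s_apex, s[m])
}

#' Leaf azimuth angles relative to the lowest leaf
#'
#' Each leaf's planar direction is the projection of its growth-point-to-tip
#' vector onto the plane perpendicular to the stem axis. The azimuth is the
#' counter-clockwise angle (viewed from above) from the lowest leaf's
#' direction, so the lowest leaf has azimuth 0 by construction.
#'
#' @param leaves list of ordered leaf polylines, sorted from lowest to
#'   highest growth point (element 1 is the reference leaf).
#' @param stem_axis upward unit vector of the stem axis.
#' @return numeric vector of azimuths in `[0, 360)` degrees, one per leaf.
#' @export
azimuth_angle <- function(leaves, stem_axis) {
  a <- unit(stem_axis)
  planar <- lapply(leaves, function(L) {
    v <- L[nrow(L), ] - L[1, ]
    v - sum(v * a) * a
  })
  ref <- planar[[1]]
  vapply(planar, function(v) {
    ang <- atan2(sum(a * cross3(ref, v)), sum(ref * v))
    (deg(ang) + 360) %% 360
  }, 0)
}

#' Leaf growth height and plant height
#'
#' `growth_height()` is the vertical (z) distance from a leaf's growth point
#' to the base of the stem. `plant_height()` is the vertical distance from
#' the highest node of any organ of the skeleton to the base point; it is
#' measured vertically, not along the stem, so a leaning plant is handled
#' correctly.
#'
#' @param leaf ordered leaf polyline whose first node is the growth point.
#' @param skeleton a `plant_skeleton`.
#' @return height in meters.
#' @export
growth_height <- function(leaf, skeleton) {
  leaf[1, 3] - skeleton$stem[1, 3]
}

#' @rdname growth_height
#' @export
plant_height <- function(skeleton) {
  zmax <- max(skeleton$stem[, 3],
              vapply(skeleton$leaves, function(L) max(L[, 3]), 0))
  zmax - skeleton$stem[1, 3]
}

# local stem line near stem node `si`: total-least-squares line over the
# calibrated stem nodes in a z window, which averages out residual
# junction-node displacement; falls back to the whole stem for short stems
stem_line_at <- function(skeleton, si, window = 0.4) {
  stem <- skeleton$stem
  z0 <- stem[si, 3]
  sel <- which(abs(stem[, 3] - z0) <= window)
  if (length(sel) < 3) sel <- seq_len(nrow(stem))
  if (length(sel) < 2)
    return(list(point = stem[si, ], dir = c(0, 0, 1)))
  line <- tls_line(stem[sel, , drop = FALSE])
  if (line$dir[3] < 0) line$dir <- -line$dir
  line
}

stem_axis_at <- function(skeleton, si, window = 0.4) {
  stem_line_at(skeleton, si, window)$dir
}

#' Phenotypic trait table of a plant skeleton
#'
#' Computes the six phenotypic parameters from a (preferably calibrated)
#' `plant_skeleton`: per leaf, ordered from the lowest growth point up ---
#' leaf length, inclination angle, top length, azimuth angle and growth
#' height --- plus the per-plant plant height (attached as an attribute and
#' repeated in the `plant_height_m` column for convenience).
#'
#' @param skeleton a `plant_skeleton`.
#' @param base_k base segments used for the inclination tangent.
#' @return `data.frame` with one row per leaf and columns `leaf_rank`,
#'   `leaf_length_m`, `inclination_deg`, `top_length_m`, `azimuth_deg`,
#'   `growth_height_m`, `plant_height_m`; attribute `plant_height`.
#' @export
skeleton_traits <- function(skeleton, base_k = 2) {
  nl <- length(skeleton$leaves)
  ph <- plant_height(skeleton)
  if (nl == 0) {
    out <- data.frame(leaf_rank = integer(0), leaf_length_m = numeric(0),
                      inclination_deg = numeric(0), top_length_m = numeric(0),
                      azimuth_deg = numeric(0), growth_height_m = numeric(0),
                      plant_height_m = numeric(0))
    attr(out, "plant_height") <- ph
    return(out)
  }
  axis_all <- unit(skeleton$stem[nrow(skeleton$stem), ] - skeleton$stem[1, ])
  az <- azimuth_angle(skeleton$leaves, axis_all)
  out <- data.frame(
    leaf_rank = seq_len(nl),
    leaf_length_m = vapply(skeleton$leaves, leaf_length, 0),
    inclination_deg = vapply(seq_len(nl), function(i)
      inclination_angle(skeleton$leaves[[i]],
                        stem_axis_at(skeleton, skeleton$growth_points[i]),
                        base_k), 0),
    top_length_m = vapply(skeleton$leaves, top_length, 0),
    azimuth_deg = az,
    growth_height_m = vapply(skeleton$leaves, growth_height, 0,
                             skeleton = skeleton),
    plant_height_m = ph)
  attr(out, "plant_height") <- ph
  out
}

#' Compare predicted and reference trait tables
#'
#' Leaves are matched by vertical rank of their growth points (both tables
#' are assumed ordered lowest to highest; with unequal counts the lowest
#' `min(n)` ranks are compared and a warning is raised). For every trait the
#' normalized root-mean-square error
#' \eqn{\mathrm{NRMSE} = 100\,\mathrm{RMSE}/\overline{y}_{\mathrm{ref}}} (%)
#' and the squared Pearson correlation \eqn{R^2} are reported. Azimuth
#' residuals are wrapped to \eqn{(-180, 180]} degrees before computing
#' either statistic, so a prediction of 359 degrees against a reference of 1
#' degree counts as a 2-degree error.
#'
#' @param pred,truth trait `data.frame`s from [skeleton_traits()] (or any
#'   frames with the same columns). Multiple plants may be stacked; rows are
#'   compared positionally after per-plant rank matching by the caller.
#' @param pred_plants,truth_plants optional frames with one `plant_height_m`
#'   row per plant; when supplied, the plant-height statistics use them
#'   instead of the (per-leaf repeated) column of `pred` / `truth`, so every
#'   plant counts once.
#' @return object of class `trait_eval`: `data.frame` with columns `trait`,
#'   `nrmse_pct`, `r_squared`, `n`.
#' @export
evaluate_traits <- function(pred, truth, pred_plants = NULL,
                            truth_plants = NULL) {
  if (!is.null(pred_plants) && !is.null(truth_plants)) {
    leaf_eval <- evaluate_traits(pred, truth)
    keep <- leaf_eval$trait != "plant_height_m"
    ph <- evaluate_traits(
      pred_plants[, "plant_height_m", drop = FALSE],
      truth_plants[, "plant_height_m", drop = FALSE])
    out <- rbind(as.data.frame(leaf_eval)[keep, ], as.data.frame(ph))
    class(out) <- c("trait_eval", "data.frame")
    return(out)
  }
  traits <- intersect(
    c("leaf_length_m", "inclination_deg", "top_length_m",
      "azimuth_deg", "growth_height_m", "plant_height_m"),
    intersect(names(pred), names(truth)))
  n <- min(nrow(pred), nrow(truth))
  if (nrow(pred) != nrow(truth))
    warning(sprintf("leaf count mismatch (%d vs %d): comparing lowest %d",
                    nrow(pred), nrow(truth), n))
  rows <- lapply(traits, function(tr) {
    p <- pred[[tr]][seq_len(n)]
    y <- truth[[tr]][seq_len(n)]
    if (tr == "azimuth_deg") {
      resid <- ((p - y + 180) %% 360) - 180
      p <- y + resid
    }
    ok <- is.finite(p) & is.finite(y)
    p <- p[ok]; y <- y[ok]
    rmse <- sqrt(mean((p - y)^2))
    r2 <- if (length(unique(y)) > 1 && sd(p) > 0) cor(p, y)^2 else NA_real_
    data.frame(trait = tr, nrmse_pct = 100 * rmse / mean(y),
               r_squared = r2, n = length(y))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trait_eval", "data.frame")
  out
}

#' @export
print.trait_eval <- function(x, ...) {
  cat("trait evaluation (rank-matched leaves):\n")
  df <- as.data.frame(x)
  df$nrmse_pct <- sprintf("%.2f", df$nrmse_pct)
  df$r_squared <- sprintf("%.3f", df$r_squared)
  print(df, row.names = FALSE)
  invisible(x)
}
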