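# small geometry helpers shared across modules

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

vec_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two 3D vectors, radians, robust to rounding
angle_between <- function(a, b) {
  na <- vec_norm(a); nb <- vec_norm(b)
  if (na < .Machine$double.eps || nb < .Machine$double.eps) return(0)
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# arc length of a polyline given as an m x 3 matrix
polyline_length <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

# total-least-squares line fit: point = centroid, direction = leading
# principal axis
tls_line <- function(P) {
  stopifnot(nrow(P) >= 2)
  ctr <- colMeans(P)
  C <- sweep(P, 2, ctr)
  sv <- svd(C, nu = 0, nv = 3)
  list(point = ctr, dir = sv$v[, 1])
}

project_on_line <- function(P, line) {
  t <- as.numeric(sweep(P, 2, line$point) %*% line$dir)
  sweep(outer(t, line$dir), 2, line$point, "+")
}

as_xyz_matrix <- function(x) {
  if (inherits(x, "point_cloud")) return(x$positions)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  storage.mode(x) <- "double"
  x
}
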