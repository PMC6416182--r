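#' Cotangent Laplacian of a point cloud from local Delaunay one-rings
#'
#' For every point, its `k` nearest neighbors are projected onto the local
#' PCA tangent plane and triangulated (2D Delaunay); the triangles incident
#' to the point define its one-ring. The off-diagonal entry for ring edge
#' \eqn{(i,j)} is \eqn{\cot\alpha_{ij} + \cot\beta_{ij}} over the two
#' triangles sharing the edge (angles measured in 3D, each cotangent clamped
#' to `[-clamp, clamp]`); the diagonal is minus the row sum, so every row
#' sums to zero exactly. Degenerate neighborhoods (collinear or coincident
#' projections) fall back to uniform unit weights over the `k` neighbors.
#'
#' @param P `n x 3` position matrix (or a [point_cloud]).
#' @param k neighbor count (>= 4, default 15).
#' @param clamp cotangent magnitude cap (default `1e4`).
#' @return list with `L` (sparse `dgCMatrix` Laplacian), `S` (per-point total
#'   one-ring edge length), and `fallbacks` (number of degenerate rows).
#' @export
build_laplacian <- function(P, k = 15, clamp = 1e4) {
  P <- as_xyz_matrix(P)
  n <- nrow(P)
  if (k < 4) stop("k must be at least 4")
  if (n < k + 1) stop("need at least k + 1 points")
  nn <- cpp_knn(P, as.integer(k))
  trip <- cpp_cotan_laplacian(P, nn, clamp)
  i <- trip$i + 1L
  j <- trip$j + 1L
  w <- trip$w
  # diagonal = -rowsum of off-diagonals
  dg <- rowsum(w, i)
  L <- Matrix::sparseMatrix(i = c(i, as.integer(rownames(dg))),
                            j = c(j, as.integer(rownames(dg))),
                            x = c(w, -dg[, 1]), dims = c(n, n))
  list(L = L, S = as.numeric(trip$S), fallbacks = trip$fallbacks)
}

#' Contraction control parameters
#'
#' @param k_neighbors neighborhood size for the Laplacian.
#' @param s_l multiplicative growth of the contraction weight per iteration.
#' @param w_l_init initial contraction weight; `NULL` selects
#'   `1 / (5 * mean one-ring edge length)`, which balances the two blocks of
#'   the stacked system.
#' @param w_l_cap upper bound on the contraction weight.
#' @param max_iters iteration cap.
#' @param converge_ratio stop once the relative drop of the total one-ring
#'   length in one iteration falls below this.
#' @param cot_clamp cotangent clamp for the Laplacian.
#' @return a named list of class `contract_control`.
#' @export
contract_control <- function(k_neighbors = 15, s_l = 3, w_l_init = NULL,
                             w_l_cap = 2048, max_iters = 20,
                             converge_ratio = 0.01, cot_clamp = 1e4) {
  structure(list(k_neighbors = k_neighbors, s_l = s_l, w_l_init = w_l_init,
                 w_l_cap = w_l_cap, max_iters = max_iters,
                 converge_ratio = converge_ratio, cot_clamp = cot_clamp),
            class = "contract_control")
}

# one constrained-Laplacian least-squares step:
# minimize |W_L L P|^2 + sum_i W_H_i^2 |P_i - P0_i|^2
# solved through the normal equations (W_L^2 L'L + diag(W_H^2)) P = W_H^2 P0.
contract_solve <- function(L, P, w_l, w_h) {
  n <- nrow(P)
  A <- (w_l^2) * Matrix::crossprod(L) + Matrix::Diagonal(n, w_h^2)
  rhs <- P * w_h^2
  as.matrix(Matrix::solve(A, rhs))
}

#' Contract a point cloud toward its curve skeleton
#'
#' Iteratively solves the constrained Laplacian system
#' \deqn{\begin{bmatrix} W_L L^t \\ W_H^t \end{bmatrix} P^{t+1} =
#'       \begin{bmatrix} 0 \\ W_H^t P^t \end{bmatrix}}
#' in the least-squares sense, then updates \eqn{W_L \leftarrow S_L W_L} and
#' \eqn{W_{H,i} \leftarrow W_{H,i}^0 S_i^0 / S_i^t} (one-ring length ratio)
#' and rebuilds the Laplacian from the new positions. Iteration stops when
#' the total one-ring length decreases by less than `converge_ratio` in one
#' step, or at `max_iters`. A maize cloud typically collapses onto a clean
#' skeleton shape within about four iterations.
#'
#' @param cloud a [point_cloud] or `n x 3` matrix (denoised single plant).
#' @param control a [contract_control()] list.
#' @return object of class `contraction_state`: list with `P` (contracted
#'   positions, same row order as the input), `P0`, `S0`, `S`, `w_l`, `w_h`,
#'   `iterations`, and `ring_history` (total one-ring length per iteration,
#'   starting with the initial value).
#' @export
contract_cloud <- function(cloud, control = contract_control()) {
  P0 <- as_xyz_matrix(cloud)
  n <- nrow(P0)
  if (n < control$k_neighbors + 1)
    stop("too few points to contract")
  lap <- build_laplacian(P0, control$k_neighbors, control$cot_clamp)
  S0 <- pmax(lap$S, .Machine$double.eps)
  w_l <- if (is.null(control$w_l_init)) {
    1 / (5 * mean(S0 / ring_degree(lap$L)))
  } else control$w_l_init
  w_h <- rep(1, n)
  P <- P0
  S <- S0
  ring_history <- sum(S0)
  iters <- 0
  for (t in seq_len(control$max_iters)) {
    P_new <- tryCatch(
      contract_solve(lap$L, P, w_l, w_h),
      error = function(e) NULL)
    if (is.null(P_new) || any(!is.finite(P_new))) {
      # singular system: lift the attraction floor once and retry
      P_new <- contract_solve(lap$L, P, w_l, pmax(w_h, 0.1))
      if (any(!is.finite(P_new))) stop("contraction solve failed")
    }
    lap <- build_laplacian(P_new, control$k_neighbors, control$cot_clamp)
    S_new <- pmax(lap$S, 1e-12)
    ratio <- (sum(S) - sum(S_new)) / sum(S)
    if (ratio < 0) break  # overstepped: keep the previous, shorter state
    iters <- t
    P <- P_new
    S <- S_new
    ring_history <- c(ring_history, sum(S_new))
    w_l <- min(control$s_l * w_l, control$w_l_cap)
    w_h <- S0 / S_new
    if (ratio < control$converge_ratio) break
  }
  structure(list(P = P, P0 = P0, S0 = S0, S = S, w_l = w_l, w_h = w_h,
                 iterations = iters, ring_history = ring_history),
            class = "contraction_state")
}

# number of off-diagonal entries per row of a sparse Laplacian
ring_degree <- function(L) {
  dl <- Matrix::diag(L)
  tab <- Matrix::rowSums(L != 0)
  pmax(tab - (dl != 0), 1)
}

#' @export
print.contraction_state <- function(x, ...) {
  cat(sprintf(
    "contraction_state: %d points, %d iterations, one-ring length %.4g -> %.4g (x%.3f)\n",
    nrow(x$P), x$iterations, x$ring_history[1],
    tail(x$ring_history, 1), tail(x$ring_history, 1) / x$ring_history[1]))
  invisible(x)
}
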