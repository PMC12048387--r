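# ---- Plane-stress linear-elastic FEM on 6-node (quadratic) triangles ----
#
# Straight-sided quadratic triangles (midside nodes at edge midpoints), 3-point
# midpoint Gauss rule (exact for the quadratic stiffness integrand), vectorized
# sparse assembly through Matrix. Displacement BCs only.

#' Plane-stress constitutive matrix
#'
#' @param E Young's modulus (MPa).
#' @param nu material Poisson's ratio.
#' @return 3x3 matrix relating (eps_x, eps_y, gamma_xy) to (sig_x, sig_y, tau_xy).
#' @keywords internal
plane_stress_D <- function(E, nu) {
  E / (1 - nu^2) * matrix(c(1, nu, 0,
                            nu, 1, 0,
                            0, 0, (1 - nu) / 2), 3, 3, byrow = TRUE)
}

.gauss3 <- list(L = matrix(c(0.5, 0.5, 0,
                             0, 0.5, 0.5,
                             0.5, 0, 0.5), 3, 3, byrow = TRUE),
                w = rep(1 / 3, 3))

# Per-element corner geometry: gradients of area coordinates and 2*area.
.tri_geom <- function(nodes, elements) {
  x <- matrix(nodes[elements[, 1:3], 1], ncol = 3)
  y <- matrix(nodes[elements[, 1:3], 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A2 <- x[, 2] * y[, 3] - x[, 3] * y[, 2] +
    x[, 3] * y[, 1] - x[, 1] * y[, 3] +
    x[, 1] * y[, 2] - x[, 2] * y[, 1]
  if (any(A2 <= 0)) stop("mesh contains non-positively oriented or degenerate elements")
  list(gbx = b / A2, gby = cc / A2, A2 = A2)
}

# Shape-function derivative arrays (m x 6) at one Gauss point.
.tri6_dN_all <- function(L, gb) {
  cbind((4 * L[1] - 1) * gb[, 1],
        (4 * L[2] - 1) * gb[, 2],
        (4 * L[3] - 1) * gb[, 3],
        4 * (L[2] * gb[, 1] + L[1] * gb[, 2]),
        4 * (L[3] * gb[, 2] + L[2] * gb[, 3]),
        4 * (L[1] * gb[, 3] + L[3] * gb[, 1]))
}

#' Solve a plane-stress linear elasticity problem
#'
#' Assembles and solves \code{K u = 0} under prescribed displacements on a
#' 6-node triangular mesh and returns the nodal displacement field together
#' with per-Gauss-point stresses.
#'
#' @param nodes numeric matrix (n x 2) of node coordinates (mm).
#' @param elements integer matrix (m x 6); columns 1:3 corner nodes
#'   (counter-clockwise), columns 4:6 midside nodes on edges 1-2, 2-3, 3-1.
#' @param E,nu,thickness material constants (MPa, -, mm).
#' @param bc data.frame with columns \code{node}, \code{dof} (1 = x, 2 = y)
#'   and \code{value}: prescribed displacements (mm).
#' @return list with \code{u} (n x 2 nodal displacements, mm), \code{stress}
#'   (m x 3 x 3 array: element, Gauss point, (sx, sy, txy), MPa), and
#'   \code{von_mises} (m x 3, MPa).
#' @export
fem_plane_stress <- function(nodes, elements, E, nu, thickness, bc) {
  n_nodes <- nrow(nodes)
  m <- nrow(elements)
  stopifnot(ncol(nodes) == 2, ncol(elements) == 6, E > 0, thickness > 0)
  if (anyDuplicated(paste(bc$node, bc$dof)))
    stop("duplicate boundary condition entries")

  D <- plane_stress_D(E, nu)
  d11 <- D[1, 1]; d12 <- D[1, 2]; d33 <- D[3, 3]
  g <- .tri_geom(nodes, elements)
  gp <- .gauss3

  # element stiffness blocks, vectorized over elements:
  # K[(i,x),(j,x)] = d11 Nx_i Nx_j + d33 Ny_i Ny_j   (etc. for x/y combos)
  Kxx <- Kxy <- Kyx <- Kyy <- array(0, dim = c(m, 6, 6))
  for (q in 1:3) {
    dNx <- .tri6_dN_all(gp$L[q, ], g$gbx)
    dNy <- .tri6_dN_all(gp$L[q, ], g$gby)
    s <- (g$A2 / 2) * gp$w[q] * thickness
    for (i in 1:6) for (j in 1:6) {
      Kxx[, i, j] <- Kxx[, i, j] + s * (d11 * dNx[, i] * dNx[, j] + d33 * dNy[, i] * dNy[, j])
      Kxy[, i, j] <- Kxy[, i, j] + s * (d12 * dNx[, i] * dNy[, j] + d33 * dNy[, i] * dNx[, j])
      Kyx[, i, j] <- Kyx[, i, j] + s * (d12 * dNy[, i] * dNx[, j] + d33 * dNx[, i] * dNy[, j])
      Kyy[, i, j] <- Kyy[, i, j] + s * (d11 * dNy[, i] * dNy[, j] + d33 * dNx[, i] * dNx[, j])
    }
  }
  dofx <- 2L * elements - 1L  # m x 6
  dofy <- 2L * elements
  ti <- c(dofx[, rep(1:6, each = 6)], dofx[, rep(1:6, each = 6)],
          dofy[, rep(1:6, each = 6)], dofy[, rep(1:6, each = 6)])
  tj <- c(dofx[, rep(1:6, times = 6)], dofy[, rep(1:6, times = 6)],
          dofx[, rep(1:6, times = 6)], dofy[, rep(1:6, times = 6)])
  tx <- c(aperm(Kxx, c(1, 3, 2)), aperm(Kxy, c(1, 3, 2)),
          aperm(Kyx, c(1, 3, 2)), aperm(Kyy, c(1, 3, 2)))
  ndof <- 2L * n_nodes
  K <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, ndof))

  cdof <- 2L * bc$node - 2L + bc$dof
  uc <- bc$value
  free <- setdiff(seq_len(ndof), cdof)
  u <- numeric(ndof)
  u[cdof] <- uc
  rhs <- -K[free, cdof, drop = FALSE] %*% uc
  uf <- tryCatch(
    as.numeric(Matrix::solve(K[free, free], rhs)),
    error = function(err) stop("singular stiffness system (disconnected mesh?): ",
                               conditionMessage(err))
  )
  u[free] <- uf
  U <- matrix(u, ncol = 2, byrow = TRUE)

  # stress at Gauss points
  ux <- matrix(U[elements, 1], ncol = 6)
  uy <- matrix(U[elements, 2], ncol = 6)
  stress <- array(0, dim = c(m, 3, 3))
  vm <- matrix(0, m, 3)
  for (q in 1:3) {
    dNx <- .tri6_dN_all(gp$L[q, ], g$gbx)
    dNy <- .tri6_dN_all(gp$L[q, ], g$gby)
    ex <- rowSums(dNx * ux)
    ey <- rowSums(dNy * uy)
    gxy <- rowSums(dNy * ux) + rowSums(dNx * uy)
    sx <- d11 * ex + d12 * ey
    sy <- d12 * ex + d11 * ey
    txy <- d33 * gxy
    stress[, q, 1] <- sx; stress[, q, 2] <- sy; stress[, q, 3] <- txy
    vm[, q] <- sqrt(sx^2 - sx * sy + sy^2 + 3 * txy^2)
  }
  list(u = U, stress = stress, von_mises = vm, n_dof = ndof, n_free = length(free))
}
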