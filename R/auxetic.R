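# ---- Rotating-square auxetic patch: geometry, FEM stretch, inverse design ----

#' Auxetic structure parameters
#'
#' Parameters of the rotating-square (rotational square) auxetic pattern:
#' square edge length \code{a}, joint (ligament) width \code{b} between
#' adjacent squares, and the initial inter-square angle \code{theta}
#' (180 degrees = fully closed sheet; smaller angles pre-open the pattern by
#' rotating alternate squares by +/-(180 - theta)/2).
#'
#' @param a square edge length (mm).
#' @param b joint width between squares (mm); must satisfy 0 < b < a.
#' @param theta initial angle between squares (degrees), in (90, 180].
#' @return object of class \code{auxetic_params}.
#' @examples
#' auxetic_params(10, 3, 175)
#' @export
auxetic_params <- function(a, b, theta) {
  if (!is.numeric(a) || !is.numeric(b) || !is.numeric(theta) ||
      length(a) != 1 || length(b) != 1 || length(theta) != 1)
    stop("a, b, theta must be numeric scalars")
  if (!(a > 0) || !(b > 0)) stop("a and b must be positive")
  if (b >= a) stop("joint width b must be smaller than square edge a")
  if (theta <= 90 || theta > 180)
    stop("theta must lie in (90, 180] degrees")
  structure(list(a = a, b = b, theta = theta), class = "auxetic_params")
}

#' @export
print.auxetic_params <- function(x, ...) {
  cat(sprintf("Rotating-square auxetic unit: a = %g mm, b = %g mm, theta = %g deg\n",
              x$a, x$b, x$theta))
  invisible(x)
}

# Slit layout of the closed (theta = 180) pattern on an R x C cell grid.
# Each internal cell edge carries a slit of length a - b leaving the ligament
# at the hinge end; hinge ends alternate so alternate squares counter-rotate.
# Returns merged maximal segments: data.frame(orient, pos, lo, hi).
.slit_layout <- function(params, grid) {
  a <- params$a; b <- params$b
  R <- grid[1]; C <- grid[2]
  segs <- list()
  add <- function(orient, pos, lo, hi) {
    segs[[length(segs) + 1L]] <<- data.frame(orient = orient, pos = pos,
                                             lo = lo, hi = hi)
  }
  # vertical internal lines x = j*a, j = 1..C-1; edge for cell row r
  for (j in seq_len(max(C - 1, 0))) {
    for (r in seq_len(R) - 1L) {
      pl <- r + (j - 1L)                   # parity of the left square
      if (pl %% 2L == 0L) add("v", j * a, r * a + b, (r + 1) * a)
      else add("v", j * a, r * a, (r + 1) * a - b)
    }
  }
  # horizontal internal lines y = i*a, i = 1..R-1; edge for cell column c
  for (i in seq_len(max(R - 1, 0))) {
    for (c in seq_len(C) - 1L) {
      pl <- (i - 1L) + c                   # parity of the lower square
      if (pl %% 2L == 0L) add("h", i * a, c * a, (c + 1) * a - b)
      else add("h", i * a, c * a + b, (c + 1) * a)
    }
  }
  segs <- do.call(rbind, segs)
  if (is.null(segs)) return(segs)
  # merge touching collinear intervals
  out <- list()
  for (key in unique(paste(segs$orient, segs$pos))) {
    s <- segs[paste(segs$orient, segs$pos) == key, ]
    s <- s[order(s$lo), ]
    cur <- s[1, ]
    for (k in seq_len(nrow(s))[-1]) {
      if (s$lo[k] <= cur$hi + 1e-9) cur$hi <- max(cur$hi, s$hi[k])
      else { out[[length(out) + 1L]] <- cur; cur <- s[k, ] }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

# 1D breakpoints within one cell [0, a]: near-uniform grid of pitch <= h_target
# with the ligament offsets b and a-b inserted exactly.
.cell_coords <- function(a, b, h_target) {
  n <- max(4L, ceiling(a / h_target))
  u <- seq(0, a, length.out = n + 1)
  h <- a / n
  for (v in c(b, a - b)) {
    if (min(abs(u - v)) > 1e-9) {
      # replace the nearest interior uniform point to avoid sliver intervals
      cand <- which(u > 1e-9 & u < a - 1e-9)
      k <- cand[which.min(abs(u[cand] - v))]
      if (abs(u[k] - v) < 0.45 * h) u[k] <- v else u <- c(u, v)
    }
  }
  sort(unique(u))
}

#' Build a rotating-square auxetic patch FEM model
#'
#' Generates the slit-cut rotating-square geometry on a regular cell grid,
#' meshes it with quadratic (6-node) triangles, and pre-opens the pattern to
#' the requested inter-square angle via the rigid rotating-square kinematic
#' map. Slits are zero-width cuts realized by node duplication; ligament
#' endpoints lie exactly on mesh nodes.
#'
#' @param params an \code{\link{auxetic_params}} object.
#' @param grid integer vector c(rows, cols) of unit cells; default 5 x 5.
#' @param material list with \code{E} (MPa), \code{nu}, \code{thickness} (mm).
#' @param h_target target element edge length (mm); default \code{b/4} so the
#'   joints are resolved by at least four quadratic elements across.
#' @return object of class \code{patch_model}: mesh (nodes, 6-node elements),
#'   clamped-edge node sets, initial bounding dimensions \code{W_i},
#'   \code{L_i} (mm), the slit layout, and the inputs.
#' @examples
#' p <- build_patch(auxetic_params(10, 3, 175), grid = c(2, 2), h_target = 1.5)
#' p$L_i
#' @export
build_patch <- function(params, grid = c(5, 5),
                        material = list(E = 0.63, nu = 0.20, thickness = 0.30),
                        h_target = params$b / 4) {
  stopifnot(inherits(params, "auxetic_params"), length(grid) == 2,
            all(grid >= 1), h_target > 0)
  a <- params$a; b <- params$b
  R <- as.integer(grid[1]); C <- as.integer(grid[2])
  degenerate <- abs(params$theta - 180) < 1e-9
  if (degenerate)
    warning("theta = 180 deg: closed pattern; slits are modelled as traction-free ",
            "cracks (self-contact ignored), behaving as a near-solid sheet only in tension")

  cell <- .cell_coords(a, b, h_target)
  xs <- sort(unique(round(as.numeric(sapply(seq_len(C) - 1L, function(j) j * a + cell)), 9)))
  ys <- sort(unique(round(as.numeric(sapply(seq_len(R) - 1L, function(i) i * a + cell)), 9)))
  Nx <- length(xs); Ny <- length(ys)
  nodes <- cbind(rep(xs, times = Ny), rep(ys, each = Nx))
  nid <- function(ix, iy) (iy - 1L) * Nx + ix

  # quads -> 2 linear triangles (counter-clockwise)
  ix <- rep(seq_len(Nx - 1L), times = Ny - 1L)
  iy <- rep(seq_len(Ny - 1L), each = Nx - 1L)
  n00 <- nid(ix, iy); n10 <- nid(ix + 1L, iy)
  n01 <- nid(ix, iy + 1L); n11 <- nid(ix + 1L, iy + 1L)
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))

  # cut slits by duplicating nodes; a slit tip on the outer boundary is cut through
  W0 <- C * a; H0 <- R * a
  slits <- .slit_layout(params, grid)
  tol <- 1e-7
  centroid <- function() (nodes[tri[, 1], ] + nodes[tri[, 2], ] + nodes[tri[, 3], ]) / 3
  if (!is.null(slits)) {
    for (s in seq_len(nrow(slits))) {
      or <- slits$orient[s]; p0 <- slits$pos[s]
      lo <- slits$lo[s]; hi <- slits$hi[s]
      along <- if (or == "v") nodes[, 2] else nodes[, 1]
      across <- if (or == "v") nodes[, 1] else nodes[, 2]
      bmax <- if (or == "v") H0 else W0
      inside <- abs(across - p0) < tol &
        ((along > lo + tol & along < hi - tol) |
           (abs(along - lo) < tol & lo < tol) |
           (abs(along - hi) < tol & hi > bmax - tol))
      cen <- centroid()
      side <- if (or == "v") cen[, 1] > p0 else cen[, 2] > p0
      for (id in which(inside)) {
        hit <- which(tri == id, arr.ind = TRUE)
        el <- unique(hit[, 1])
        pos_el <- el[side[el]]
        neg_el <- el[!side[el]]
        if (length(pos_el) == 0 || length(neg_el) == 0) next
        nodes <- rbind(nodes, nodes[id, , drop = FALSE])
        newid <- nrow(nodes)
        for (k in seq_len(nrow(hit)))
          if (side[hit[k, 1]]) tri[hit[k, 1], hit[k, 2]] <- newid
      }
    }
  }

  # clamped edges, identified in the closed configuration
  bottom <- which(nodes[, 2] < tol)
  top <- which(nodes[, 2] > H0 - tol)

  # pre-open: rigid rotating-square kinematics, alternate rotation +/- phi
  phi <- (180 - params$theta) / 2 * pi / 180
  if (phi > 0) {
    rr <- pmin(pmax(floor(nodes[, 2] / a), 0), R - 1)
    cc <- pmin(pmax(floor(nodes[, 1] / a), 0), C - 1)
    sgn <- ifelse((rr + cc) %% 2 == 0, 1, -1)
    k <- cos(phi) + sin(phi)
    cx <- (cc + 0.5) * a; cy <- (rr + 0.5) * a
    dx <- nodes[, 1] - cx; dy <- nodes[, 2] - cy
    ang <- sgn * phi
    nodes <- cbind(k * cx + cos(ang) * dx - sin(ang) * dy,
                   k * cy + sin(ang) * dx + cos(ang) * dy)
  }

  # quadratic (6-node) elements: shared midside nodes keyed on corner pairs
  n_corner <- nrow(nodes)
  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  keys <- c(edge_key(tri[, 1], tri[, 2]),
            edge_key(tri[, 2], tri[, 3]),
            edge_key(tri[, 3], tri[, 1]))
  uk <- unique(keys)
  mid_id <- n_corner + match(keys, uk)
  pair <- do.call(rbind, strsplit(uk, "_"))
  i1 <- as.integer(pair[, 1]); i2 <- as.integer(pair[, 2])
  nodes <- rbind(nodes, (nodes[i1, , drop = FALSE] + nodes[i2, , drop = FALSE]) / 2)
  m <- nrow(tri)
  elements <- cbind(tri, mid_id[1:m], mid_id[(m + 1):(2 * m)], mid_id[(2 * m + 1):(3 * m)])
  # a midside node lies on a clamped edge iff both its corners do
  mid_unique <- n_corner + seq_along(uk)
  bottom <- sort(unique(c(bottom, mid_unique[i1 %in% bottom & i2 %in% bottom])))
  top <- sort(unique(c(top, mid_unique[i1 %in% top & i2 %in% top])))

  structure(list(
    nodes = nodes, elements = elements,
    bottom = bottom, top = top,
    W_i = diff(range(nodes[, 1])), L_i = diff(range(nodes[, 2])),
    slits = slits, params = params, grid = c(R, C), material = material,
    h_target = h_target, degenerate = degenerate
  ), class = "patch_model")
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf(paste0("Auxetic patch model: %d x %d cells (a = %g, b = %g, theta = %g)\n",
                     "  mesh: %d nodes, %d quadratic triangles; W_i = %.3f mm, L_i = %.3f mm\n"),
              x$grid[1], x$grid[2], x$params$a, x$params$b, x$params$theta,
              nrow(x$nodes), nrow(x$elements), x$W_i, x$L_i))
  invisible(x)
}

#' Structural Poisson's ratio from bounding dimensions
#'
#' \eqn{\mu = -((W_t - W_i)/W_i) / ((L_t - L_i)/L_i)}: the negative ratio of
#' lateral to axial engineering strain of the patch bounding box.
#'
#' @param W_i,L_i initial width and length (mm).
#' @param W_t,L_t deformed width and length (mm).
#' @return structural Poisson's ratio (dimensionless).
#' @examples
#' structural_poisson(100, 100, 109.4, 110)  # -0.94
#' @export
structural_poisson <- function(W_i, L_i, W_t, L_t) {
  if (!(W_i > 0) || !(L_i > 0)) stop("initial dimensions must be positive")
  if (L_t == L_i) stop("axial strain is zero: Poisson's ratio undefined")
  -((W_t - W_i) / W_i) / ((L_t - L_i) / L_i)
}

#' Solve the uniaxial stretch of an auxetic patch
#'
#' Plane-stress elastic solve with incremental geometry updating: the stretch
#' is applied in steps of at most \code{step} mm, each step a linear solve on
#' the current (updated) node coordinates, which captures the finite rotations
#' of the squares that dominate the auxetic response. The bottom clamped edge
#' is fixed axially (one node additionally pinned laterally to remove
#' rigid-body translation), the top edge is displaced along the length;
#' lateral edges are free. Incremental stresses are accumulated
#' component-wise (small-strain approximation; rotation of stress axes within
#' a step is neglected).
#'
#' The structural Poisson's ratio depends on the stretch once rotations are
#' finite; \code{mu} is the Eq.-style secant value at the full displacement,
#' while \code{mu_sweep} summarizes the response as the mean secant ratio over
#' the displacement sweep from \code{sweep_from} mm to the full stretch, the
#' protocol used to characterize the optimized design.
#'
#' @param patch a \code{\link{build_patch}} model.
#' @param displacement applied axial stretch (mm), default 10.
#' @param step maximum displacement increment per geometric update (mm),
#'   default 0.5; \code{step >= displacement} gives a single linear solve.
#' @param sweep_from lower end (mm) of the displacement sweep summarized by
#'   \code{mu_sweep}, default 2.
#' @return object of class \code{mech_response}: initial/deformed bounding
#'   dimensions (mm), \code{mu}, \code{mu_sweep}, accumulated maximum von
#'   Mises stress \code{sigma_max} (MPa, at element Gauss points), the total
#'   displacement field \code{u}, and a per-step \code{trace}.
#' @export
solve_stretch <- function(patch, displacement = 10, step = 0.5, sweep_from = 2) {
  stopifnot(inherits(patch, "patch_model"), displacement >= 0, step > 0)
  if (displacement == 0) {
    warning("zero displacement: zero stress, structural Poisson's ratio undefined")
    return(structure(list(W_i = patch$W_i, L_i = patch$L_i,
                          W_t = patch$W_i, L_t = patch$L_i,
                          mu = NA_real_, mu_sweep = NA_real_, sigma_max = 0,
                          displacement = 0, u = patch$nodes * 0,
                          trace = data.frame()), class = "mech_response"))
  }
  nstep <- max(1L, ceiling(displacement / step))
  d <- displacement / nstep
  nodes <- patch$nodes
  bot <- patch$bottom; top <- patch$top
  pin <- bot[which.min(nodes[bot, 1])]
  bc <- rbind(
    data.frame(node = bot, dof = 2L, value = 0),
    data.frame(node = pin, dof = 1L, value = 0),
    data.frame(node = top, dof = 2L, value = d)
  )
  acc <- NULL
  trace <- vector("list", nstep)
  for (s in seq_len(nstep)) {
    sol <- fem_plane_stress(nodes, patch$elements,
                            E = patch$material$E, nu = patch$material$nu,
                            thickness = patch$material$thickness, bc = bc)
    nodes <- nodes + sol$u
    acc <- if (is.null(acc)) sol$stress else acc + sol$stress
    W_s <- diff(range(nodes[, 1])); L_s <- diff(range(nodes[, 2]))
    vm <- sqrt(acc[, , 1]^2 - acc[, , 1] * acc[, , 2] + acc[, , 2]^2 +
                 3 * acc[, , 3]^2)
    trace[[s]] <- data.frame(disp = s * d, W_t = W_s, L_t = L_s,
                             mu = structural_poisson(patch$W_i, patch$L_i, W_s, L_s),
                             sigma_max = max(vm))
  }
  trace <- do.call(rbind, trace)
  last <- trace[nstep, ]
  in_sweep <- trace$disp >= sweep_from - 1e-9
  structure(list(W_i = patch$W_i, L_i = patch$L_i,
                 W_t = last$W_t, L_t = last$L_t,
                 mu = last$mu,
                 mu_sweep = if (any(in_sweep)) mean(trace$mu[in_sweep]) else last$mu,
                 sigma_max = last$sigma_max,
                 displacement = displacement, u = nodes - patch$nodes,
                 trace = trace),
            class = "mech_response")
}

#' @export
print.mech_response <- function(x, ...) {
  cat(sprintf(paste0("Stretch response: %g mm axial displacement\n",
                     "  W: %.3f -> %.3f mm, L: %.3f -> %.3f mm\n",
                     "  structural Poisson's ratio: %.4f at full stretch, ",
                     "%.4f sweep mean\n  max von Mises: %.4f MPa\n"),
              x$displacement, x$W_i, x$W_t, x$L_i, x$L_t, x$mu, x$mu_sweep,
              x$sigma_max))
  invisible(x)
}

#' Inverse-design objective
#'
#' Piecewise target driving the structural Poisson's ratio towards -1 while
#' penalizing designs whose maximum von Mises stress exceeds the material
#' integrity limit: \eqn{f = \mu + 1} if \eqn{\sigma \le 0.5} MPa, else
#' \eqn{f = \mu + 11}.
#'
#' @param mu structural Poisson's ratio.
#' @param sigma_max maximum von Mises stress (MPa).
#' @param sigma_limit stress bound (MPa), default 0.5.
#' @param penalty additive penalty above the bound, default 10.
#' @return objective value.
#' @examples
#' design_objective(-0.94, 0.3)  # 0.06
#' design_objective(-0.94, 0.6)  # 10.06
#' @export
design_objective <- function(mu, sigma_max, sigma_limit = 0.5, penalty = 10) {
  stopifnot(is.finite(mu), is.finite(sigma_max))
  mu + 1 + if (sigma_max > sigma_limit) penalty else 0
}

#' Nelder-Mead simplex minimization with box bounds
#'
#' Derivative-free simplex search. The judgement (convergence) condition stops
#' the search when the spread of objective values across the simplex falls
#' below \code{delta}. Iterates are clamped to the box bounds.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point (within bounds).
#' @param lower,upper bound vectors.
#' @param delta convergence judgement condition (objective spread), default 0.01.
#' @param max_iter iteration budget, default 40.
#' @param step initial simplex step as a fraction of the box width, default 0.1.
#' @return list: \code{par}, \code{value}, \code{iterations}, \code{converged},
#'   and \code{trace} (data.frame of every evaluation).
#' @export
nelder_mead <- function(fn, x0, lower, upper, delta = 0.01, max_iter = 40,
                        step = 0.1) {
  stopifnot(delta > 0, max_iter >= 1, length(lower) == length(x0),
            length(upper) == length(x0), all(lower <= upper))
  if (any(x0 < lower | x0 > upper)) stop("x0 outside bounds")
  n <- length(x0)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  tr <- list()
  neval <- 0L
  f <- function(x) {
    v <- fn(x)
    neval <<- neval + 1L
    tr[[neval]] <<- c(x, v)
    v
  }
  # initial simplex: x0 plus one perturbed vertex per coordinate
  simplex <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) {
    d <- step * (upper[i] - lower[i])
    xi <- simplex[i + 1, i] + d
    if (xi > upper[i]) xi <- simplex[i + 1, i] - d
    simplex[i + 1, i] <- xi
  }
  fv <- apply(simplex, 1, f)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]; fv <- fv[ord]
    if (diff(range(fv)) < delta) { converged <- TRUE; break }
    xc <- colMeans(simplex[1:n, , drop = FALSE])    # centroid w/o worst
    xw <- simplex[n + 1, ]
    xr <- clamp(xc + (xc - xw)); fr <- f(xr)
    if (fr < fv[1]) {
      xe <- clamp(xc + 2 * (xc - xw)); fe <- f(xe)
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xk <- clamp(xc + 0.5 * (xw - xc)); fk <- f(xk)
      if (fk < fv[n + 1]) { simplex[n + 1, ] <- xk; fv[n + 1] <- fk }
      else { # shrink towards the best vertex
        for (i in 2:(n + 1)) {
          simplex[i, ] <- clamp(simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ]))
          fv[i] <- f(simplex[i, ])
        }
      }
    }
  }
  ord <- order(fv)
  trace <- as.data.frame(do.call(rbind, tr))
  names(trace) <- c(paste0("x", seq_len(n)), "f")
  list(par = simplex[ord[1], ], value = fv[ord[1]], iterations = iter,
       converged = converged, trace = trace)
}

#' Inverse design of the auxetic patch
#'
#' Minimizes \code{\link{design_objective}} over (a, b, theta) with
#' \code{\link{nelder_mead}}, each evaluation running the full
#' geometry-build + plane-stress stretch solve. Infeasible geometries
#' (\code{b >= a}, failed meshes) receive a large penalty value.
#'
#' @param init \code{\link{auxetic_params}} start design.
#' @param lower,upper named numeric vectors with entries a, b, theta (mm, mm, deg).
#' @param grid cell grid passed to \code{\link{build_patch}}.
#' @param material material constants passed to \code{\link{build_patch}}.
#' @param stretch applied displacement (mm), default 10.
#' @param delta Nelder-Mead judgement condition, default 0.01.
#' @param max_iter iteration budget, default 40.
#' @param h_target mesh density override (mm); default \code{b/4} per design.
#' @param step displacement increment passed to \code{\link{solve_stretch}}.
#' @return list: \code{par} (auxetic_params), \code{response}
#'   (\code{mech_response} at the optimum), \code{objective}, and the
#'   evaluation \code{trace} (a, b, theta, mu, sigma_max, f).
#' @export
optimize_design <- function(init, lower = c(a = 5, b = 1, theta = 150),
                            upper = c(a = 15, b = 5, theta = 179),
                            grid = c(5, 5),
                            material = list(E = 0.63, nu = 0.20, thickness = 0.30),
                            stretch = 10, delta = 0.01, max_iter = 40,
                            h_target = NULL, step = 0.5) {
  stopifnot(inherits(init, "auxetic_params"))
  x0 <- c(init$a, init$b, init$theta)
  rows <- list()
  evalfn <- function(x) {
    out <- tryCatch({
      p <- auxetic_params(x[1], x[2], x[3])
      ht <- if (is.null(h_target)) p$b / 4 else h_target
      resp <- solve_stretch(build_patch(p, grid = grid, material = material,
                                        h_target = ht),
                            displacement = stretch, step = step)
      c(resp$mu_sweep, resp$sigma_max,
        design_objective(resp$mu_sweep, resp$sigma_max))
    }, error = function(err) c(NA_real_, NA_real_, 1e3))
    rows[[length(rows) + 1L]] <<- c(x, out)
    out[3]
  }
  nm <- nelder_mead(evalfn, x0, lower = unname(lower[c("a", "b", "theta")]),
                    upper = unname(upper[c("a", "b", "theta")]),
                    delta = delta, max_iter = max_iter)
  if (all(!is.finite(sapply(rows, `[`, 6))) || min(nm$trace$f) >= 1e3)
    stop("all design evaluations infeasible")
  trace <- as.data.frame(do.call(rbind, rows))
  names(trace) <- c("a", "b", "theta", "mu", "sigma_max", "f")
  best <- auxetic_params(nm$par[1], nm$par[2], nm$par[3])
  ht <- if (is.null(h_target)) best$b / 4 else h_target
  resp <- solve_stretch(build_patch(best, grid = grid, material = material,
                                    h_target = ht),
                        displacement = stretch, step = step)
  list(par = best, response = resp, objective = nm$value,
       converged = nm$converged, iterations = nm$iterations, trace = trace)
}

#' Export the laser-cut slit pattern as SVG
#'
#' Writes the closed-configuration slit skeleton (one line element per merged
#' cut) with document units in millimetres.
#'
#' @param params an \code{\link{auxetic_params}} object.
#' @param grid cell grid c(rows, cols).
#' @param file output path (.svg).
#' @return invisibly, the slit table that was written.
#' @export
export_cut_path <- function(params, grid = c(5, 5), file) {
  stopifnot(inherits(params, "auxetic_params"))
  slits <- .slit_layout(params, grid)
  if (is.null(slits)) stop("no internal slits for a 1 x 1 grid")
  W <- grid[2] * params$a; H <- grid[1] * params$a
  ln <- vapply(seq_len(nrow(slits)), function(s) {
    if (slits$orient[s] == "v")
      sprintf('  <line x1="%.6f" y1="%.6f" x2="%.6f" y2="%.6f" stroke="black" stroke-width="0.05"/>',
              slits$pos[s], slits$lo[s], slits$pos[s], slits$hi[s])
    else
      sprintf('  <line x1="%.6f" y1="%.6f" x2="%.6f" y2="%.6f" stroke="black" stroke-width="0.05"/>',
              slits$lo[s], slits$pos[s], slits$hi[s], slits$pos[s])
  }, character(1))
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%gmm" height="%gmm" viewBox="0 0 %g %g">',
                   W, H, W, H),
           ln, "</svg>")
  writeLines(svg, file)
  invisible(slits)
}
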