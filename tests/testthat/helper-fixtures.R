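# Shared fixtures, built once per test run.

fix_env <- new.env()

# Small labelled dataset + trained classifier reused by model/stream tests.
small_model <- function() {
  if (is.null(fix_env$model)) {
    cond <- motion_conditions()
    ds <- build_dataset(cond, n_per_condition = 15, seed = 101)
    fz <- featurize_dataset(ds)
    fix_env$dataset <- ds
    fix_env$features <- fz
    fix_env$model <- torque_net(fz$features, fz$labels$torque,
                                hidden = c(64, 32), epochs = 60,
                                batch_size = 16, seed = 11)
  }
  fix_env$model
}

small_features <- function() { small_model(); fix_env$features }
small_dataset <- function() { small_model(); fix_env$dataset }

# Coarse auxetic patch (2x2 cells, coarse mesh) for fast FEM tests.
coarse_patch <- function(params = auxetic_params(10, 3, 175)) {
  build_patch(params, grid = c(2, 2), h_target = params$b / 2)
}

# Structured solid plate meshed with quadratic triangles (no cuts): the
# analytic plane-stress oracle geometry.
solid_plate <- function(n = 8, L = 50, material = list(E = 0.63, nu = 0.20,
                                                       thickness = 0.30)) {
  xs <- seq(0, L, length.out = n + 1)
  Nx <- length(xs)
  nodes <- cbind(rep(xs, times = Nx), rep(xs, each = Nx))
  nid <- function(ix, iy) (iy - 1L) * Nx + ix
  ix <- rep(seq_len(Nx - 1), times = Nx - 1)
  iy <- rep(seq_len(Nx - 1), each = Nx - 1)
  tri <- rbind(cbind(nid(ix, iy), nid(ix + 1, iy), nid(ix + 1, iy + 1)),
               cbind(nid(ix, iy), nid(ix + 1, iy + 1), nid(ix, iy + 1)))
  n_corner <- nrow(nodes)
  ek <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  keys <- c(ek(tri[, 1], tri[, 2]), ek(tri[, 2], tri[, 3]), ek(tri[, 3], tri[, 1]))
  uk <- unique(keys)
  mid <- n_corner + match(keys, uk)
  pr <- do.call(rbind, strsplit(uk, "_"))
  i1 <- as.integer(pr[, 1]); i2 <- as.integer(pr[, 2])
  nodes <- rbind(nodes, (nodes[i1, , drop = FALSE] + nodes[i2, , drop = FALSE]) / 2)
  m <- nrow(tri)
  el <- cbind(tri, mid[1:m], mid[(m + 1):(2 * m)], mid[(2 * m + 1):(3 * m)])
  list(nodes = nodes, elements = el,
       bottom = which(nodes[, 2] < 1e-9), top = which(nodes[, 2] > L - 1e-9),
       L = L, material = material)
}

plate_stretch <- function(plate, disp) {
  bot <- plate$bottom
  bc <- rbind(data.frame(node = bot, dof = 2L, value = 0),
              data.frame(node = bot[which.min(plate$nodes[bot, 1])],
                         dof = 1L, value = 0),
              data.frame(node = plate$top, dof = 2L, value = disp))
  fem_plane_stress(plate$nodes, plate$elements, plate$material$E,
                   plate$material$nu, plate$material$thickness, bc)
}

# Independent spectrogram oracle: explicit O(N^2) DFT per Hann-windowed frame.
dft_mean_spectrum <- function(s, fs = 1000, window = 256, overlap = 0.5) {
  hop <- round(window * (1 - overlap))
  nframe <- floor((length(s) - window) / hop) + 1
  win <- 0.5 * (1 - cos(2 * pi * seq_len(window) / window))
  nbin <- window / 2 + 1
  mags <- matrix(0, nbin, nframe)
  for (f in seq_len(nframe)) {
    x <- s[(f - 1) * hop + seq_len(window)] * win
    for (k in seq_len(nbin)) {
      n <- seq_len(window) - 1
      ang <- -2 * pi * (k - 1) * n / window
      mags[k, f] <- Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang))))
    }
  }
  rowMeans(mags)
}
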