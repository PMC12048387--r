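test_that("parameter validation enforces the geometric constraints", {
  expect_s3_class(auxetic_params(10, 3, 175), "auxetic_params")
  expect_error(auxetic_params(10, 0, 175), "positive")
  expect_error(auxetic_params(10, 12, 175), "smaller")
  expect_error(auxetic_params(10, 3, 80), "theta")
  expect_error(auxetic_params(10, 3, 181), "theta")
})

test_that("patch meshes are connected and carry the expected slit count", {
  p <- coarse_patch()
  # 2x2 cells: the two vertical edge slits merge through the shared free
  # vertex into one cut; the two horizontal slits stay separate
  expect_equal(nrow(p$slits), 3)
  r <- solve_stretch(p, 2, step = 1)  # solvable => watertight/connected
  expect_true(is.finite(r$mu))
  expect_gt(r$sigma_max, 0)
  # closed pattern: modelled as a near-solid sheet with zero-width cracks
  expect_warning(build_patch(auxetic_params(10, 3, 180), grid = c(2, 2),
                             h_target = 2), "closed pattern")
})

test_that("the patch widens under stretch (negative structural Poisson ratio)", {
  r <- solve_stretch(coarse_patch(), 5, step = 1)
  expect_lt(r$mu, -0.3)
  expect_gt(r$W_t, r$W_i)
  expect_equal(r$L_t - r$L_i, 5, tolerance = 0.05)
  # the sweep summary averages the per-step secant values
  expect_equal(r$mu_sweep, mean(r$trace$mu[r$trace$disp >= 2]))
})

test_that("thinner joints approach the ideal rotating-square response", {
  params <- list(auxetic_params(10, 4, 175), auxetic_params(10, 2.5, 175),
                 auxetic_params(10, 1.5, 175))
  mus <- vapply(params, function(pp)
    solve_stretch(build_patch(pp, grid = c(3, 3), h_target = pp$b / 3),
                  displacement = 0.5, step = 1)$mu, numeric(1))
  expect_true(all(diff(mus) < 0))   # mu decreases towards -1 as b shrinks
})

test_that("Nelder-Mead converges on a quadratic surrogate to the known minimum", {
  fn <- function(x) sum((x - c(2, -1)) ^ 2) + 0.5
  nm <- nelder_mead(fn, c(0, 0), lower = c(-5, -5), upper = c(5, 5),
                    delta = 1e-6, max_iter = 200)
  expect_true(nm$converged)
  expect_equal(nm$par, c(2, -1), tolerance = 0.01)
  expect_equal(nm$value, 0.5, tolerance = 1e-4)
  # agreement with the reference simplex implementation
  ref <- stats::optim(c(0, 0), fn, method = "Nelder-Mead")
  expect_equal(nm$value, ref$value, tolerance = 1e-3)
  # stated judgement condition: spread below delta stops the search
  nm2 <- nelder_mead(fn, c(0, 0), lower = c(-5, -5), upper = c(5, 5),
                     delta = 0.01, max_iter = 40)
  expect_true(nm2$converged)
  expect_lte(nm2$iterations, 40)
  # bounds are respected along the whole trace
  expect_true(all(nm$trace$x1 >= -5 & nm$trace$x1 <= 5))
  expect_error(nelder_mead(fn, c(9, 0), lower = c(-5, -5), upper = c(5, 5)),
               "bounds")
})

test_that("best-so-far objective is non-increasing along an optimization trace", {
  init <- auxetic_params(9, 3.5, 172)
  res <- optimize_design(init, lower = c(a = 8, b = 2, theta = 165),
                         upper = c(a = 11, b = 4.5, theta = 179),
                         grid = c(2, 2), stretch = 4, step = 2,
                         h_target = 1.6, max_iter = 6, delta = 0.01)
  best <- cummin(res$trace$f)
  expect_true(all(diff(best) <= 0))
  expect_lt(res$objective, 1)        # a feasible auxetic design was found
  expect_lt(res$response$mu_sweep, 0)
  expect_s3_class(res$par, "auxetic_params")
  expect_true(all(c("a", "b", "theta", "mu", "sigma_max", "f") %in%
                    names(res$trace)))
})

test_that("cut-path export writes one line per merged slit in mm units", {
  skip_if_not_installed("xml2")
  params <- auxetic_params(10, 3, 175)
  path <- tempfile(fileext = ".svg")
  slits <- export_cut_path(params, grid = c(3, 3), file = path)
  doc <- xml2::read_xml(path)
  expect_match(xml2::xml_attr(doc, "width"), "mm$")
  lines <- xml2::xml_find_all(doc, ".//*[local-name()='line']")
  expect_equal(length(lines), nrow(slits))
  # round trip: vertex coordinates match to 1e-6 mm
  x1 <- as.numeric(xml2::xml_attr(lines, "x1"))
  y1 <- as.numeric(xml2::xml_attr(lines, "y1"))
  v <- slits$orient == "v"
  expect_equal(x1[v], slits$pos[v], tolerance = 1e-6)
  expect_equal(y1[v], slits$lo[v], tolerance = 1e-6)
  expect_equal(x1[!v], slits$lo[!v], tolerance = 1e-6)
})

test_that("mesh refinement changes the sweep Poisson ratio only slightly", {
  pp <- auxetic_params(10, 3, 175)
  mu_c <- solve_stretch(build_patch(pp, grid = c(3, 3), h_target = 1.5),
                        displacement = 4, step = 1)$mu
  mu_f <- solve_stretch(build_patch(pp, grid = c(3, 3), h_target = 1.0),
                        displacement = 4, step = 1)$mu
  expect_lt(abs(mu_f - mu_c), 0.01)
})
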