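disc_slice <- function(n = 64, sp = 3, radius = 50, value = 1) {
  xy <- expand.grid(x = seq_len(n) - (n + 1) / 2,
                    y = seq_len(n) - (n + 1) / 2)
  matrix(as.numeric((xy$x * sp)^2 + (xy$y * sp)^2 < radius^2) * value, n, n)
}

small_geom <- function() scan_geometry(n_angles = 60L, n_radial = 64L,
                                       bin_width_mm = 3)

test_that("forward projection is linear with correct chord integrals", {
  g <- scan_geometry(180L, 128L, 2)
  n <- 128
  disc <- disc_slice(n, 2, 50)
  v <- volume(array(disc, c(n, n, 1)), c(2, 2, 2))
  s <- forward_project(v, g)

  # zero volume projects to zero
  z <- forward_project(with_data(v, array(0, dim(v$data))), g)
  expect_true(all(z$values == 0))

  # central ray through a 10-cm disc: integral = 10 cm within 1%
  central <- max(s$values[, 1, 1])
  expect_lt(abs(central - 10) / 10, 0.01)

  # linearity: projection of a sum equals sum of projections
  a <- rand_vol(c(32, 32, 1), spacing = c(4, 4, 4), seed = 3)
  b <- rand_vol(c(32, 32, 1), spacing = c(4, 4, 4), seed = 4)
  gs <- small_geom()
  pa <- forward_project(a, gs)$values
  pb <- forward_project(b, gs)$values
  pab <- forward_project(with_data(a, a$data + b$data), gs)$values
  expect_lt(max(abs(pab - (pa + pb))) / max(pab), 1e-12)
})

test_that("attenuation factors follow the Beer-Lambert closed form", {
  g <- scan_geometry(180L, 128L, 2)
  n <- 128
  mu <- volume(array(disc_slice(n, 2, 50, 0.1), c(n, n, 1)), c(2, 2, 2),
               units = "mu_cm_inv")
  a <- attenuation_factors(mu, g)
  expect_lt(abs(min(a$values[, 1, 1]) - exp(-1)) / exp(-1), 0.01)

  # zero attenuation gives unit factors; scaling mu decreases factors
  zerov <- with_data(mu, array(0, dim(mu$data)))
  expect_true(all(attenuation_factors(zerov, g)$values == 1))
  a2 <- attenuation_factors(with_data(mu, 2 * mu$data), g)
  expect_true(all(a2$values <= a$values + 1e-15))
  expect_error(attenuation_factors(with_data(mu, mu$data - 1, "intensity"),
                                   g), "negative")
})

test_that("projector and backprojector are an exact adjoint pair", {
  g <- small_geom()
  n <- 48
  set.seed(8)
  x <- matrix(runif(n * n), n, n)
  v <- volume(array(x, c(n, n, 1)), c(4, 4, 4))
  Ax <- forward_project(v, g)$values[, , 1]
  y <- matrix(runif(g$n_radial * g$n_angles), g$n_radial, g$n_angles)
  # <Ax, y> must equal <x, A^T y>
  stencils <- suteac:::cached_stencils(g, n, n, c(4, 4, 4))
  Aty <- numeric(n * n)
  for (ai in seq_len(g$n_angles))
    Aty <- Aty + suteac:::back_angle(y[, ai], stencils[[ai]], n * n)
  expect_equal(sum(Ax * y), sum(as.vector(x) * Aty), tolerance = 1e-10)
})

test_that("emission simulation has Poisson statistics and honours seeds", {
  g <- small_geom()
  n <- 64
  act <- volume(array(disc_slice(n, 3, 60), c(n, n, 1)), c(3, 3, 3),
                units = "activity")
  mu <- volume(array(disc_slice(n, 3, 60, 0.1), c(n, n, 1)), c(3, 3, 3),
               units = "mu_cm_inv")
  N <- 2e5
  mean_sino <- simulate_emission(act, mu, g, N, poisson = FALSE)
  expect_equal(sum(mean_sino$values), N, tolerance = 1e-9)
  expect_true(all(mean_sino$values >= 0))

  totals <- vapply(1:5, function(s)
    sum(simulate_emission(act, mu, g, N, seed = s)$values), numeric(1))
  expect_true(all(abs(totals - N) < 4 * sqrt(N)))
  # counts are zero where the mean is zero
  y <- simulate_emission(act, mu, g, N, seed = 1)
  expect_true(all(y$values[mean_sino$values == 0] == 0))
  # identical seeds give identical draws
  expect_identical(simulate_emission(act, mu, g, N, seed = 9)$values,
                   simulate_emission(act, mu, g, N, seed = 9)$values)
})

test_that("MLEM converges monotonically and conserves counts", {
  g <- small_geom()
  n <- 64
  truth <- disc_slice(n, 3, 45, 2)
  act <- volume(array(truth, c(n, n, 1)), c(3, 3, 3), units = "activity")
  mu <- volume(array(disc_slice(n, 3, 55, 0.096), c(n, n, 1)), c(3, 3, 3),
               units = "mu_cm_inv")
  y <- simulate_emission(act, mu, g, 1e6, poisson = FALSE)
  acf <- attenuation_factors(mu, g)

  rmse <- vapply(c(2, 5, 10, 25, 50), function(it) {
    rec <- reconstruct(y, acf, iterations = it, subsets = 1L,
                       postfilter_fwhm_mm = 0)
    scale <- sum(truth) / sum(rec$data)
    sqrt(mean((rec$data[, , 1] * scale - truth)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))

  # count conservation: forward model of the reconstruction matches data
  rec <- reconstruct(y, acf, iterations = 3, subsets = 4L,
                     postfilter_fwhm_mm = 0)
  expect_true(all(rec$data >= 0))
  fp <- forward_project(rec, g)
  expect_lt(abs(sum(fp$values * acf$values) - sum(y$values)) /
              sum(y$values), 0.01)

  # subset reduction warns when 21 does not divide the angle count
  expect_warning(reconstruct(y, acf, iterations = 1, subsets = 21L,
                             postfilter_fwhm_mm = 0), "reduced")
})
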