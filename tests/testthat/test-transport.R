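test_that("an air-only phantom yields reference kerma but no patient dose", {
  lib <- slab_library()
  vol <- label_volume(array(0L, c(8, 8, 4)), spacing = c(10, 10, 10),
                      origin = -c(40, 40, 20))
  setup <- pencil_setup(opening = 2)
  res <- simulate_dose(vol, lib, setup, 2e4, seed = 3)
  expect_gt(res$ref_point_air_kerma, 0)
  expect_lt(res$energy$deposited / res$energy$emitted, 1e-3)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  lib <- build_material_library()
  ph <- make_head_phantom(32, 6, spacing = c(4, 4, 5), seed = 0)
  setup <- beam_setup(0, spectrum = make_analytic_spectrum(90, lib = lib))
  a <- simulate_dose(ph, lib, setup, 2e4, seed = 17)
  b <- simulate_dose(ph, lib, setup, 2e4, seed = 17)
  expect_identical(a$primary_dose$values, b$primary_dose$values)
  expect_identical(a$scatter_dose$values, b$scatter_dose$values)
  expect_identical(a$ref_point_air_kerma, b$ref_point_air_kerma)
  c <- simulate_dose(ph, lib, setup, 2e4, seed = 18)
  expect_false(identical(a$primary_dose$values, c$primary_dose$values))
})

test_that("primary attenuation in a homogeneous slab is Beer-Lambert", {
  # pure photoelectric absorber with the attenuation of water at 60 keV:
  # every primary deposits its full energy at its first interaction, so the
  # fraction of histories surviving past depth d is exp(-mu d)
  mu_rho <- 0.2059  # cm^2/g
  lib <- slab_library(mu_rho = mu_rho, f = c(1, 0, 0))
  slab <- slab_volume(nx = 10, ny = 50, nz = 5, spacing = c(8, 2, 8))
  setup <- pencil_setup(delta_spectrum(60), opening = 0.2)
  n <- 1e6
  res <- simulate_dose(slab, lib, setup, n, seed = 4)
  expect_equal(res$energy$emitted, n * 60)

  mass <- prod(slab$spacing) / 1000  # g per voxel (density 1)
  e_vox <- res$primary_dose$values * mass / (1.602176634e-16) * 1e-6  # keV
  e_beyond <- rev(cumsum(rev(apply(e_vox, 2, sum))))  # by depth row
  mu_mm <- mu_rho / 10
  depths <- (seq_len(50) - 1) * slab$spacing[2]
  for (k in c(5, 15, 25, 40)) {
    p_expect <- exp(-mu_mm * depths[k])
    p_got <- (e_beyond[k] + res$energy$escaped) / res$energy$emitted
    tol <- 3 * sqrt(p_expect * (1 - p_expect) / n)
    expect_lt(abs(p_got - p_expect), tol)
  }
})

test_that("energy is conserved to floating-point accuracy", {
  lib <- build_material_library()
  ph <- make_head_phantom(32, 6, spacing = c(4, 4, 5), seed = 0)
  setup <- beam_setup(45, spectrum = make_analytic_spectrum(120, lib = lib))
  res <- simulate_dose(ph, lib, setup, 5e4, seed = 5)
  en <- res$energy
  expect_lt(abs(en$emitted - en$deposited - en$escaped) / en$emitted, 1e-6)
  # total dose decomposes exactly into primary + scatter
  expect_equal(total_dose(res)$values,
               res$primary_dose$values + res$scatter_dose$values)
})

test_that("disabling Compton and Rayleigh removes all scatter dose", {
  lib <- slab_library(f = c(1, 0, 0))
  slab <- slab_volume()
  res <- simulate_dose(slab, lib, pencil_setup(), 5e4, seed = 6)
  expect_true(all(res$scatter_dose$values == 0))
  expect_gt(sum(res$primary_dose$values), 0)

  lib2 <- slab_library(f = c(0.2, 0.6, 0.2))
  res2 <- simulate_dose(slab, lib2, pencil_setup(), 5e4, seed = 6)
  expect_gt(sum(res2$scatter_dose$values), 0)
})

test_that("primary dose vanishes outside the collimation pyramid", {
  lib <- slab_library(f = c(0.2, 0.6, 0.2))
  slab <- slab_volume(nx = 30, ny = 30, nz = 5, spacing = c(4, 4, 8))
  setup <- pencil_setup(delta_spectrum(80), opening = 2)
  res <- simulate_dose(slab, lib, setup, 1e5, seed = 7)
  # voxels whose entire footprint is outside the pyramid (all corners out)
  d <- dim(slab$values)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  out <- array(TRUE, d)
  for (r in seq_len(nrow(corners))) {
    idx <- voxel_centers(slab) +
      rep(1, prod(d)) %o% ((corners[r, ] - 0.5) * slab$spacing)
    out <- out & array(!beam_contains(setup, idx), d)
  }
  expect_true(all(res$primary_dose$values[out] == 0))
  # while scatter does reach beyond the beam
  expect_gt(sum(res$scatter_dose$values[out]), 0)
})

test_that("batch uncertainty follows the two-batch closed form and 1/sqrt(N)", {
  grid <- function(x) scalar_volume(array(x, c(1, 1, 1)))
  fake <- structure(list(
    primary_dose = grid(7), scatter_dose = grid(3),
    batch_sumsq = grid(6^2 + 4^2),  # batches a = 6, b = 4
    n_histories = 10, n_batches = 2, ref_point_air_kerma = 1,
    seed = 1, energy = list()), class = "dose_result")
  expect_equal(estimate_uncertainty(fake)$values[1, 1, 1],
               2 * abs(6 - 4) / (6 + 4))
  # identical batches: zero uncertainty; zero dose: flagged as 1
  same <- fake
  same$batch_sumsq <- grid(2 * 5^2)
  expect_equal(estimate_uncertainty(same)$values[1, 1, 1], 0)
  zero <- fake
  zero$primary_dose <- grid(0); zero$scatter_dose <- grid(0)
  zero$batch_sumsq <- grid(0)
  expect_equal(estimate_uncertainty(zero)$values[1, 1, 1], 1)
  single <- fake
  single$n_batches <- 1
  expect_error(estimate_uncertainty(single), "batches")

  lib <- build_material_library()
  ph <- make_head_phantom(32, 6, spacing = c(4, 4, 5), seed = 0)
  setup <- beam_setup(0, spectrum = make_analytic_spectrum(90, lib = lib))
  m <- sapply(c(2e5, 4e5), function(n) {
    res <- simulate_dose(ph, lib, setup, n, seed = 20 + n / 1e5)
    unc <- estimate_uncertainty(res)
    td <- total_dose(res)$values
    sel <- ph$values > 0 & td > stats::median(td[ph$values > 0])
    median(unc$values[sel])
  })
  expect_lt(abs(m[2] / m[1] - 1 / sqrt(2)), 0.2 / sqrt(2))
})

test_that("air-kerma scaling is the forced linear normalization", {
  grid <- function(x) scalar_volume(array(x, c(2, 1, 1)))
  res <- structure(list(
    primary_dose = grid(c(1, 2)), scatter_dose = grid(c(0.5, 0)),
    batch_sumsq = grid(c(1, 1)), n_histories = 10, n_batches = 2,
    ref_point_air_kerma = 2.0, seed = 1, energy = list()),
    class = "dose_result")
  scaled <- scale_to_air_kerma(res, 49.28)
  expect_equal(scaled$primary_dose$values, res$primary_dose$values * 24.64)
  expect_equal(scaled$ref_point_air_kerma, 49.28)
  # measured == simulated leaves the result unchanged
  expect_equal(scale_to_air_kerma(res, 2.0), res)
  # scaling by k then 1/k restores the original
  back <- scale_to_air_kerma(scale_to_air_kerma(res, 10), 2.0)
  expect_equal(back$primary_dose$values, res$primary_dose$values,
               tolerance = 1e-12)
  bad <- res
  bad$ref_point_air_kerma <- 0
  expect_error(scale_to_air_kerma(bad, 10), "zero")
})

test_that("an empty beam-phantom intersection warns and deposits nothing", {
  lib <- slab_library()
  slab <- slab_volume(nx = 6, ny = 6, nz = 3, spacing = c(4, 4, 4))
  setup <- beam_setup(0, isocenter = c(5000, 0, 0), opening_phi = 0.5,
                      opening_theta = 0.5, spectrum = delta_spectrum())
  expect_warning(res <- simulate_dose(slab, lib, setup, 1e3, seed = 1),
                 "intersect")
  expect_equal(sum(total_dose(res)$values), 0)
})
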