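test_that("filter radius follows the half-window-plus-one rule", {
  expect_identical(radius_from_scale(2), 2L)
  expect_identical(radius_from_scale(16), 9L)
  expect_identical(radius_from_scale(3), 3L)  # 1.5 rounds half-up to 2, +1
  expect_identical(radius_from_scale(c(1, 4, 8)), c(2L, 3L, 5L))
  expect_error(radius_from_scale(0), "s must")
})

test_that("fraction-of-mass down-sampling is the mass-weighted window mean", {
  # uniform values survive any density pattern
  set.seed(1)
  dens <- scalar_volume(array(runif(64, 0.5, 2), c(4, 4, 4)))
  vals <- scalar_volume(array(7, c(4, 4, 4)))
  out <- downsample_fom(vals, dens, 2)
  expect_equal(unique(as.vector(out$values)), 7)

  # equal-mass 2x2 window {0,0,0,4} averages to 1
  v <- scalar_volume(array(c(0, 0, 0, 4), c(2, 2, 1)))
  rho <- scalar_volume(array(1, c(2, 2, 1)))
  expect_equal(as.vector(downsample_fom(v, rho, 2)$values), 1)

  # 1x2 window with densities {3,1} and values {0,4}: (3*0 + 1*4)/4 = 1
  v2 <- scalar_volume(array(c(0, 4), c(1, 2, 1)))
  rho2 <- scalar_volume(array(c(3, 1), c(1, 2, 1)))
  expect_equal(as.vector(downsample_fom(v2, rho2, 2)$values), 1)
})

test_that("fraction-of-mass down-sampling conserves the mass-weighted total", {
  set.seed(2)
  for (s in c(2, 3, 4)) {  # 3 exercises trailing partial windows
    vals <- scalar_volume(array(runif(10 * 10 * 3), c(10, 10, 3)),
                          spacing = c(1, 1, 5))
    dens <- scalar_volume(array(runif(10 * 10 * 3, 0.1, 2), c(10, 10, 3)),
                          spacing = c(1, 1, 5))
    coarse <- downsample_fom(vals, dens, s)
    gi <- (seq_len(10) - 1) %/% s + 1
    for (k in 1:3) {
      m <- dens$values[, , k]  # voxel volume is a common factor
      window_mass <- t(rowsum(t(rowsum(m, gi)), gi))
      lhs <- sum(coarse$values[, , k] * window_mass)
      expect_equal(lhs, sum(m * vals$values[, , k]), tolerance = 1e-12)
    }
  }
})

test_that("zero-mass windows fall back to the unweighted mean with a warning", {
  v <- scalar_volume(array(c(1, 3, 5, 7), c(2, 2, 1)))
  rho <- scalar_volume(array(0, c(2, 2, 1)))
  expect_warning(out <- downsample_fom(v, rho, 2), "zero-mass")
  expect_equal(as.vector(out$values), 4)
})

test_that("mode down-sampling picks the majority label with density tie-break", {
  lib <- build_material_library()
  # uniform volume stays put
  u <- label_volume(array(1L, c(4, 4, 2)))
  expect_true(all(downsample_mode(u, 2, lib)$values == 1L))

  # strict majority: {soft, soft, bone, air} -> soft
  m <- label_volume(array(c(1L, 1L, 3L, 0L), c(2, 2, 1)))
  expect_equal(as.vector(downsample_mode(m, 2, lib)$values), 1L)

  # tie {soft, soft, bone, bone}: the denser tissue (bone) wins
  t1 <- label_volume(array(c(1L, 1L, 3L, 3L), c(2, 2, 1)))
  expect_equal(as.vector(downsample_mode(t1, 2, lib)$values), 3L)

  # equal-density tie breaks to the lowest label id
  lib2 <- material_library(
    list(flat_material("air", 0.001, 1e-4),
         flat_material("a", 1, 0.2), flat_material("b", 1, 0.2)),
    labels = c(0L, 1L, 2L))
  t2 <- label_volume(array(c(1L, 2L, 2L, 1L), c(2, 2, 1)))
  expect_equal(as.vector(downsample_mode(t2, 2, lib2)$values), 1L)
})

test_that("mode down-sampling is idempotent on window-constant volumes", {
  lib <- build_material_library()
  set.seed(3)
  coarse <- array(sample(c(0L, 1L, 3L, 4L), 3 * 3 * 2, TRUE), c(3, 3, 2))
  blown <- label_volume(coarse[rep(1:3, each = 4), rep(1:3, each = 4), ,
                               drop = FALSE])
  down <- downsample_mode(blown, 4, lib)
  expect_identical(down$values, coarse)
  # and the coarse grid carries the scaled spacing
  expect_equal(down$spacing, blown$spacing * c(4, 4, 1))
})

test_that("guided filter matches the brute-force windowed regression oracle", {
  set.seed(4)
  for (cfg in list(list(r = 2, eps = 1e-4), list(r = 3, eps = 0.01),
                   list(r = 5, eps = 1))) {
    g <- matrix(runif(256), 16, 16)
    s <- matrix(runif(256), 16, 16)
    expect_lt(max(abs(guided_filter_2d(g, s, cfg$r, cfg$eps) -
                        guided_filter_oracle(g, s, cfg$r, cfg$eps))),
              1e-10)
  }
})

test_that("guided filter limiting cases: box mean and identity", {
  set.seed(5)
  src <- matrix(runif(144), 12, 12)
  # constant guide: a -> 0, b -> window mean, so each pixel outputs the
  # average of the window means covering it (iterated box smoothing)
  out <- guided_filter_2d(matrix(1, 12, 12), src, r = 2, eps = 1e-6)
  boxmean <- guided_filter_oracle(matrix(1, 12, 12), src, 2, 1e-6)
  expect_equal(out, boxmean, tolerance = 1e-12)
  centers <- expand.grid(4:8, 4:8)
  manual <- mean(apply(centers, 1, function(c_) {
    mean(src[(c_[1] - 2):(c_[1] + 2), (c_[2] - 2):(c_[2] + 2)])
  }))
  expect_equal(out[6, 6], manual, tolerance = 1e-10)

  # src == guide with vanishing eps: perfect linear fit returns the guide
  g <- matrix(runif(144, 1, 2), 12, 12)
  expect_lt(max(abs(guided_filter_2d(g, g, 3, 1e-14) - g)), 1e-8)

  expect_error(guided_filter_2d(matrix(NA_real_, 2, 2),
                                matrix(1, 2, 2), 1, 1e-3), "finite")
})

test_that("fluence-domain reconstruction is exact for proportional inputs", {
  lib <- build_material_library()
  ph <- make_head_phantom(32, 6, spacing = c(4, 4, 5), seed = 0)
  spectrum <- make_analytic_spectrum(90, lib = lib)
  gh <- absorption_map(ph, lib, spectrum)
  for (s in c(2, 4)) {
    gl <- absorption_map(downsample_mode(ph, s, lib), lib, spectrum)
    coarse <- scalar_volume(3.7 * gl$values, gl$spacing, gl$origin)
    rec <- upsample_dose(coarse, gh, gl, downsample_spec(s))
    expect_equal(rec$values, 3.7 * gh$values, tolerance = 1e-8)
  }
})

test_that("uniform guidance reduces reconstruction to guided smoothing", {
  g0 <- 0.03
  gh <- scalar_volume(array(g0, c(8, 8, 2)))
  gl <- scalar_volume(array(g0, c(4, 4, 2)), spacing = c(2, 2, 1))
  set.seed(6)
  coarse <- scalar_volume(array(runif(32), c(4, 4, 2)),
                          spacing = c(2, 2, 1))
  spec <- downsample_spec(2, eps = 1e-6)
  rec <- upsample_dose(coarse, gh, gl, spec)
  wi <- rep(1:4, each = 2)
  for (k in 1:2) {
    manual <- guided_filter_2d(gh$values[, , k],
                               coarse$values[wi, wi, k] / g0,
                               spec$radius, 1e-6) * g0
    expect_equal(rec$values[, , k], pmax(manual, 0), tolerance = 1e-12)
  }
})

test_that("reconstruction output is non-negative for non-negative inputs", {
  lib <- build_material_library()
  ph <- make_head_phantom(32, 6, spacing = c(4, 4, 5), seed = 1)
  spectrum <- make_analytic_spectrum(120, lib = lib)
  gh <- absorption_map(ph, lib, spectrum)
  set.seed(7)
  for (s in c(2, 4, 8)) {
    labs_lr <- downsample_mode(ph, s, lib)
    gl <- absorption_map(labs_lr, lib, spectrum)
    coarse <- scalar_volume(array(rexp(length(gl$values)), dim(gl$values)),
                            gl$spacing, gl$origin)
    rec <- upsample_dose(coarse, gh, gl, downsample_spec(s))
    expect_true(all(rec$values >= 0))
  }
})

test_that("end-to-end coarse reconstruction composes the pipeline correctly", {
  lib <- build_material_library()
  ph <- make_head_phantom(32, 6, spacing = c(4, 4, 5), seed = 0)
  setup <- beam_setup(0, spectrum = make_analytic_spectrum(90, lib = lib))

  # s = 2 simulates on a grid with half the in-plane extent
  r2 <- reconstruct_from_simulation(ph, lib, setup, downsample_spec(2),
                                    2e4, seed = 8)
  expect_identical(dim(r2$coarse$primary_dose$values), c(16L, 16L, 6L))
  expect_identical(dim(r2$dose$values), dim(ph$values))

  # fixed seed reproduces the whole chain
  r2b <- reconstruct_from_simulation(ph, lib, setup, downsample_spec(2),
                                     2e4, seed = 8)
  expect_identical(r2$dose$values, r2b$dose$values)

  # s = 1: no down-sampling, result is guided smoothing of the native run
  r1 <- reconstruct_from_simulation(ph, lib, setup, downsample_spec(1),
                                    2e4, seed = 9)
  native <- simulate_dose(ph, lib, setup, 2e4, seed = 9)
  gh <- absorption_map(ph, lib, setup$spectrum)
  manual <- upsample_dose(total_dose(native), gh, gh, downsample_spec(1))
  expect_equal(r1$dose$values, manual$values, tolerance = 1e-12)
})
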