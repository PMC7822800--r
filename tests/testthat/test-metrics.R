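vol_of <- function(x, d = c(4, 4, 3)) scalar_volume(array(x, d))

test_that("mape matches the explicit per-voxel loop and is scale invariant", {
  expect_equal(mape(vol_of(2), vol_of(2)), 0)
  expect_equal(mape(vol_of(1.8), vol_of(2)), 10)

  set.seed(1)
  est <- vol_of(runif(48, 0.1, 2))
  ref <- vol_of(runif(48, 0.1, 2))
  loop <- mean(sapply(seq_len(48), function(v) {
    abs(est$values[[v]] - ref$values[[v]]) / ref$values[[v]] * 100
  }))
  expect_equal(mape(est, ref), loop, tolerance = 1e-12)

  # scale invariance
  est5 <- vol_of(5 * est$values)
  ref5 <- vol_of(5 * ref$values)
  expect_equal(mape(est5, ref5), mape(est, ref), tolerance = 1e-12)

  mask <- array(FALSE, c(4, 4, 3))
  expect_error(mape(est, ref, mask), "empty")
  expect_error(mape(est, vol_of(0)), "positive")
})

test_that("error map is consistent with mape and flags reference zeros", {
  est <- vol_of(2)
  expect_true(all(error_map(est, est)$values == 0))

  ref <- vol_of(1)
  e2 <- vol_of(1)
  e2$values[2, 3, 1] <- 2
  em <- error_map(e2, ref)
  expect_equal(em$values[2, 3, 1], 100)
  expect_equal(sum(em$values), 100)

  set.seed(2)
  est <- vol_of(runif(48, 0.1, 2))
  refr <- vol_of(runif(48, 0.1, 2))
  mask <- array(runif(48) > 0.4, c(4, 4, 3))
  expect_equal(mean(error_map(est, refr)$values[mask]),
               mape(est, refr, mask), tolerance = 1e-12)

  z <- vol_of(1)
  z$values[1, 1, 1] <- 0
  expect_true(is.na(error_map(est, z)$values[1, 1, 1]))
})

test_that("slice organ dose averages the organ voxels per axial slice", {
  labs <- label_volume(array(0L, c(4, 4, 3)))
  labs$values[2:3, 2:3, 1] <- 4L
  labs$values[2, 2, 3] <- 4L
  dose <- vol_of(0.5)
  out <- slice_organ_dose(dose, labs, 4L)
  expect_equal(out$slice, c(1L, 3L))
  expect_equal(out$dose_mGy, c(0.5, 0.5))

  set.seed(3)
  rnd <- vol_of(runif(48))
  out2 <- slice_organ_dose(rnd, labs, 4L)
  expect_equal(out2$dose_mGy[1], mean(rnd$values[2:3, 2:3, 1]))
  expect_equal(out2$dose_mGy[2], rnd$values[2, 2, 3])
  expect_equal(out2$n_voxels, c(4L, 1L))

  expect_warning(none <- slice_organ_dose(dose, labs, 7L), "not present")
  expect_equal(nrow(none), 0L)
})

test_that("trilinear point sampling interpolates between voxel centers", {
  v <- scalar_volume(array(seq_len(48), c(4, 4, 3)), spacing = c(2, 2, 5),
                     origin = c(0, 0, 0))
  ctr <- function(i, j, k) c((i - 0.5) * 2, (j - 0.5) * 2, (k - 0.5) * 5)
  pts <- measurement_set(
    c("center", "midpoint", "edge"),
    rbind(ctr(2, 3, 1),
          (ctr(2, 3, 1) + ctr(3, 3, 1)) / 2,
          ctr(1, 1, 1)),
    dose_mGy = c(1, 1, 1), sigma_mGy = c(0, 0, 0))
  got <- sample_dose_at_points(v, pts)
  expect_equal(unname(got["center"]), v$values[2, 3, 1])
  expect_equal(unname(got["midpoint"]),
               (v$values[2, 3, 1] + v$values[3, 3, 1]) / 2)
  expect_equal(unname(got["edge"]), v$values[1, 1, 1])

  const <- vol_of(4.2)
  pc <- measurement_set("p", rbind(c(3.3, 2.1, 1.7)), 1, 0)
  expect_equal(unname(sample_dose_at_points(const, pc)), 4.2)

  outside <- measurement_set("far", rbind(c(99, 0, 0)), 1, 0)
  expect_error(sample_dose_at_points(v, outside), "far")
})

test_that("measurement comparison applies the 2-sigma criterion", {
  meas <- measurement_set(c("a", "b", "c"),
                          rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                          dose_mGy = c(10, 10, 10),
                          sigma_mGy = c(1, 1, 1), n_repeats = 5)
  sim <- c(a = 10, b = 11.5, c = 13)
  cmp <- compare_measurements(sim, meas)
  expect_equal(cmp$points$within_2sigma, c(TRUE, TRUE, FALSE))
  expect_equal(cmp$points$pct_error, c(0, 15, 30))
  expect_equal(cmp$mape, 15)

  # exact agreement: all inside, zero error
  perfect <- compare_measurements(c(a = 10, b = 10, c = 10), meas)
  expect_true(all(perfect$points$within_2sigma))
  expect_equal(perfect$mape, 0)

  # unit change mGy -> Gy leaves percentages and flags unchanged
  meas_gy <- measurement_set(meas$id,
                             as.matrix(meas[, c("x_mm", "y_mm", "z_mm")]),
                             meas$dose_mGy / 1000, meas$sigma_mGy / 1000,
                             meas$n_repeats)
  cmp_gy <- compare_measurements(sim / 1000, meas_gy)
  expect_equal(cmp_gy$points$pct_error, cmp$points$pct_error)
  expect_identical(cmp_gy$points$within_2sigma, cmp$points$within_2sigma)

  expect_error(compare_measurements(c(x = 1, y = 2, z = 3), meas),
               "ids")
})

test_that("measurement tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  ms <- measurement_set(paste0("p", 1:3),
                        matrix(rnorm(9), 3), c(1, 2, 3), c(0.1, 0.2, 0.3),
                        n_repeats = 5)
  p <- file.path(dir, "points.csv")
  write_measurements(ms, p)
  rt <- read_measurements(p)
  expect_equal(as.data.frame(rt), as.data.frame(ms), tolerance = 1e-12)
  expect_error(measurement_set(c("a", "a"), matrix(0, 2, 3), c(1, 1),
                               c(0, 0)),
               "unique")
})

test_that("brain probe layout lands every probe inside the organ", {
  ph <- make_head_phantom(48, 8, seed = 0)
  pos <- brain_probe_grid(ph, n = 13)
  expect_equal(nrow(pos), 13L)
  idx <- floor(sweep(sweep(pos, 2, ph$origin, `-`), 2, ph$spacing, `/`)) + 1
  for (r in seq_len(13)) {
    expect_identical(ph$values[idx[r, 1], idx[r, 2], idx[r, 3]], 4L)
  }
})
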