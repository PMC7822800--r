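KEV_TO_J <- 1.602176634e-16
REF_CELL_CM3 <- 1.0  # free-air scoring cell volume at the reference point

#' Monte Carlo dose simulation on a voxel phantom
#'
#' Transports `n_histories` photon histories through the labelled phantom
#' using Woodcock delta-tracking against the volume's majorant attenuation
#' and scores absorbed dose per voxel under the kerma approximation
#' (secondary-electron energy deposited at the interaction site, adequate at
#' diagnostic X-ray energies).  Each history samples its energy from the
#' beam spectrum and its direction uniformly over the rectangular
#' collimation field; interactions are photoelectric, Compton
#' (Klein-Nishina) or Rayleigh (Thomson shape) according to the material's
#' interaction fractions, and photons are terminated below 5 keV.  Primary
#' dose (deposits up to and including a photon's first Compton event) and
#' scatter dose are scored separately, along with the free-in-air collision
#' kerma of primary photons in a 1 cm^3 cell at the interventional reference
#' point, which [scale_to_air_kerma()] uses to normalize the result to the
#' air kerma reported by the X-ray system.
#'
#' The random stream is a counter-based generator indexed by history, so
#' results are bit-reproducible for a fixed `seed` and independent of the
#' batch decomposition; R's RNG state is not touched.
#'
#' @param labels A [label_volume()] registered to world coordinates.
#' @param lib A [material_library()] resolving every label.
#' @param setup A [beam_setup()].
#' @param n_histories Number of primary photon histories.
#' @param seed Integer seed.
#' @param n_batches Number of batches for the uncertainty estimate
#'   (>= 2 for [estimate_uncertainty()]).
#' @param e_cutoff Photon energy cutoff, keV; photons below it are absorbed
#'   locally.
#' @return A `dose_result`: list with `primary_dose`, `scatter_dose`
#'   (`scalar_volume`s, mGy), `batch_sumsq` (per-voxel sum of squared batch
#'   doses, mGy^2), `n_histories`, `n_batches`, `ref_point_air_kerma` (mGy),
#'   `seed`, and an `energy` accounting (emitted / deposited / escaped, keV).
#' @examples
#' \donttest{
#' lib <- build_material_library()
#' ph <- make_head_phantom(32, 6, spacing = c(4, 4, 5))
#' setup <- beam_setup(0, spectrum = make_analytic_spectrum(90, lib = lib))
#' res <- simulate_dose(ph, lib, setup, 2e4, seed = 1)
#' res$ref_point_air_kerma
#' }
#' @export
simulate_dose <- function(labels, lib, setup, n_histories, seed = 1,
                          n_batches = 10, e_cutoff = 5) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(lib, "material_library"),
            inherits(setup, "beam_setup"))
  n_histories <- as.numeric(n_histories)
  if (n_histories < n_batches) {
    stop("n_histories must be at least n_batches", call. = FALSE)
  }
  spec <- setup$spectrum
  if (min(spec$energies) < e_cutoff) {
    stop("spectrum contains energies below the transport cutoff",
         call. = FALSE)
  }

  lut <- label_lookup(labels, lib)
  mats <- lib$materials[lut$name_of]
  e_max <- min(vapply(mats, function(m) max(m$energy_keV), 0),
               max(lib_material(lib, "air")$energy_keV))
  e_min <- max(vapply(mats, function(m) min(m$energy_keV), 0),
               min(lib_material(lib, "air")$energy_keV))
  if (max(spec$energies) > e_max || min(spec$energies) < e_min) {
    stop("spectrum exceeds the tabulated material energy range",
         call. = FALSE)
  }
  egrid <- seq(max(e_min, e_cutoff), e_max, by = 1)
  tab <- function(f) vapply(mats, f, numeric(length(egrid)))
  mu_lin <- tab(function(m) {
    material_coefficient(m, egrid, "attenuation") * m$density / 10  # 1/mm
  })
  f_photo <- tab(function(m) material_coefficient(m, egrid, "f_photo"))
  f_compton <- tab(function(m) material_coefficient(m, egrid, "f_compton"))
  muen_air <- material_coefficient(lib_material(lib, "air"), egrid,
                                   "absorption")

  ax <- beam_axes(setup)
  src <- setup$isocenter - setup$sod * ax$e_c
  ref <- reference_point(setup)
  ref_radius <- (3 * REF_CELL_CM3 / (4 * pi))^(1 / 3) * 10  # mm

  if (!beam_hits_volume(labels, setup)) {
    warning("the collimated beam does not intersect the phantom; ",
            "patient dose will be zero")
  }

  kr <- .mc_transport(
    labels = array(lut$index - 1L, dim(labels$values)),
    dims = dim(labels$values), spacing = labels$spacing,
    origin = labels$origin,
    mu_lin = mu_lin, f_photo = f_photo, f_compton = f_compton,
    muen_air = muen_air, egrid_start = egrid[1], egrid_step = 1,
    src = src, e_u = ax$e_u, e_v = ax$e_v, e_c = ax$e_c,
    tan_phi = tan(setup$opening_phi * pi / 180),
    tan_theta = tan(setup$opening_theta * pi / 180),
    spec_energy = spec$energies, spec_cdf = cumsum(spec$weights),
    ref_point = ref, ref_radius = ref_radius,
    n_histories = n_histories, n_batches = as.integer(n_batches),
    seed = as.numeric(seed %% 2^48), e_cutoff = e_cutoff)

  # keV per voxel -> mGy: E[J] / m[kg] * 1000
  dens <- vapply(mats, function(m) m$density, 0)
  mass_g <- array(dens[lut$index], dim(labels$values)) *
    prod(labels$spacing) / 1000  # mm^3 -> cm^3
  to_mgy <- KEV_TO_J / (mass_g * 1e-3) * 1e3
  d <- dim(labels$values)
  vol <- function(x) scalar_volume(array(x, d), labels$spacing,
                                   labels$origin)
  ref_kerma <- kr$ref_raw * KEV_TO_J * 0.1 / REF_CELL_CM3 * 1e6  # mGy

  structure(list(
    primary_dose = vol(kr$primary * to_mgy),
    scatter_dose = vol(kr$scatter * to_mgy),
    batch_sumsq = vol(kr$batch_sumsq * to_mgy^2),
    n_histories = n_histories, n_batches = as.integer(n_batches),
    ref_point_air_kerma = ref_kerma, seed = seed,
    energy = list(emitted = kr$emitted, deposited = kr$deposited,
                  escaped = kr$escaped)),
    class = "dose_result")
}

beam_hits_volume <- function(labels, setup) {
  # the central ray hitting the grid box is sufficient (covers pencil beams
  # thinner than the sampling stride below)
  ax <- beam_axes(setup)
  src <- setup$isocenter - setup$sod * ax$e_c
  lo <- labels$origin
  hi <- labels$origin + dim(labels$values) * labels$spacing
  t0 <- 0; t1 <- Inf
  for (a in 1:3) {
    if (abs(ax$e_c[a]) < 1e-15) {
      if (src[a] <= lo[a] || src[a] >= hi[a]) t1 <- -Inf
    } else {
      tt <- sort(c((lo[a] - src[a]) / ax$e_c[a],
                   (hi[a] - src[a]) / ax$e_c[a]))
      t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
    }
  }
  if (t0 < t1) return(TRUE)
  d <- dim(labels$values)
  stride <- pmax(1L, d %/% 8L)
  i <- seq(1, d[1], by = stride[1])
  j <- seq(1, d[2], by = stride[2])
  k <- seq(1, d[3], by = stride[3])
  pts <- as.matrix(expand.grid(
    (i - 0.5) * labels$spacing[1] + labels$origin[1],
    (j - 0.5) * labels$spacing[2] + labels$origin[2],
    (k - 0.5) * labels$spacing[3] + labels$origin[3]))
  any(beam_contains(setup, pts))
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf(
    "<dose_result> %.3g histories (%d batches, seed %s)\n",
    x$n_histories, x$n_batches, format(x$seed)))
  cat(sprintf("  reference-point air kerma: %.4g mGy\n",
              x$ref_point_air_kerma))
  cat(sprintf("  max total dose: %.4g mGy\n",
              max(x$primary_dose$values + x$scatter_dose$values)))
  invisible(x)
}

#' Total (primary + scatter) dose of a simulation result
#' @param result A `dose_result`.
#' @return A `scalar_volume`, mGy.
#' @export
total_dose <- function(result) {
  scalar_volume(result$primary_dose$values + result$scatter_dose$values,
                result$primary_dose$spacing, result$primary_dose$origin)
}

#' Voxel-wise relative statistical uncertainty
#'
#' Estimates the relative 2-sigma uncertainty of the mean dose from the
#' batch-to-batch variance: for batch doses `d_b`, the standard error of the
#' mean is `sd(d_b) / sqrt(B)`.  Returned as a fraction (multiply by 100 for
#' percent); voxels with zero dose are flagged as 1 (i.e. 100 %).
#'
#' @param result A `dose_result` simulated with at least two batches.
#' @return A `scalar_volume` of relative 2-sigma values (dimensionless
#'   fractions).
#' @export
estimate_uncertainty <- function(result) {
  b <- result$n_batches
  if (b < 2) stop("need at least two batches", call. = FALSE)
  total <- result$primary_dose$values + result$scatter_dose$values
  sumsq <- result$batch_sumsq$values
  var_b <- pmax(sumsq - total^2 / b, 0) / (b - 1)
  rel <- array(1, dim(total))
  nz <- total > 0
  rel[nz] <- 2 * sqrt(var_b[nz] / b) / (total[nz] / b)
  scalar_volume(rel, result$primary_dose$spacing,
                result$primary_dose$origin)
}

#' Normalize a simulation to a measured air kerma
#'
#' Scales all dose grids by the ratio between the air kerma reported by the
#' X-ray system and the simulated primary collision kerma at the
#' interventional reference point, tying the per-history Monte Carlo output
#' to the machine's absolute output.
#'
#' @param result A `dose_result` with positive simulated reference kerma.
#' @param measured_kair Measured air kerma, mGy.
#' @return A `dose_result` with rescaled dose grids and
#'   `ref_point_air_kerma = measured_kair`.
#' @export
scale_to_air_kerma <- function(result, measured_kair) {
  if (!is.numeric(measured_kair) || measured_kair <= 0) {
    stop("measured air kerma must be positive", call. = FALSE)
  }
  if (result$ref_point_air_kerma <= 0) {
    stop("simulated reference-point air kerma is zero; cannot scale",
         call. = FALSE)
  }
  k <- measured_kair / result$ref_point_air_kerma
  result$primary_dose$values <- result$primary_dose$values * k
  result$scatter_dose$values <- result$scatter_dose$values * k
  result$batch_sumsq$values <- result$batch_sumsq$values * k^2
  result$ref_point_air_kerma <- measured_kair
  result
}

#' In-beam, in-body evaluation mask
#'
#' Logical mask of voxels whose centers lie inside the collimation pyramid
#' and carry a non-air label; the region over which reconstruction errors
#' are evaluated.
#'
#' @param labels A [label_volume()].
#' @param setup A [beam_setup()].
#' @param air_label Label id treated as air (default 0).
#' @return Logical 3-D array.
#' @export
beam_mask <- function(labels, setup, air_label = 0L) {
  inside <- array(beam_contains(setup, voxel_centers(labels)),
                  dim(labels$values))
  inside & labels$values != air_label
}
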