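#' Reconstruction-accuracy benchmark on the synthetic head phantom
#'
#' Runs the package's headline computational experiment: a high-statistics
#' full-resolution reference simulation of a collimated 120 kVp cone beam
#' on the synthetic head phantom, followed, for each down-sampling factor
#' `s`, by (a) the accelerated path — statistical-mode down-sampling of the
#' phantom, a coarse simulation with half the reference statistics, and
#' guided-filter fluence-domain reconstruction — and (b) the
#' fraction-of-mass comparison arm, where the coarse dose is obtained by
#' directly mass-weighted down-sampling of the reference dose and then
#' reconstructed with the same guided filter.  Optionally the accelerated
#' path is repeated with `lowstat_factor`-fold fewer histories.  All dose
#' volumes are scaled to a common reference-point air kerma, and the mean
#' absolute percentage error is evaluated over in-beam, in-body voxels
#' against the reference.
#'
#' Default problem sizes are chosen so that the per-voxel statistical
#' uncertainty of the reference matches the regime of a full-scale
#' reference simulation while the whole benchmark stays desk-scale (several
#' minutes on one CPU); see the methods vignette.
#'
#' @param seed Integer master seed; all simulations derive their seeds from
#'   it.
#' @param scales Down-sampling factors to evaluate.
#' @param n_xy,n_z,spacing,phantom_seed Synthetic head phantom parameters
#'   (see [make_head_phantom()]).
#' @param n_ref Reference histories; coarse simulations use `n_ref / 2`.
#' @param lowstat_factor History reduction factor for the low-statistics
#'   repeat; `NULL` skips it.
#' @param include_fom Also run the fraction-of-mass comparison arm?
#' @param air_kerma_mGy Air kerma all results are normalized to, mGy.
#' @param opening_deg Collimation half-opening angles, degrees.
#' @return A list with elements `scales`, `mape_mode`, `mape_fom`,
#'   `mape_lowstat` (named numeric vectors, %), `ref_median_2sigma`
#'   (median in-beam relative 2-sigma of the reference, fraction) and
#'   `n_ref`.
#' @seealso [reconstruct_from_simulation()], [mape()]
#' @export
benchmark_reconstruction <- function(seed = 1, scales = c(2, 4, 8, 16),
                                     n_xy = 128, n_z = 8,
                                     spacing = c(1.2, 1.2, 10),
                                     phantom_seed = 0, n_ref = 2.4e8,
                                     lowstat_factor = 100,
                                     include_fom = TRUE,
                                     air_kerma_mGy = 49.28,
                                     opening_deg = c(3, 6)) {
  seed <- as.integer(seed)
  lib <- build_material_library()
  labels <- make_head_phantom(n_xy, n_z, spacing = spacing,
                              seed = phantom_seed)
  spectrum <- load_spectrum(system.file("extdata", "spectra",
                                        "spectrum_120kvp.csv",
                                        package = "dosekit"))
  setup <- beam_setup(0, opening_phi = opening_deg[1],
                      opening_theta = opening_deg[2], spectrum = spectrum)

  ref_res <- scale_to_air_kerma(
    simulate_dose(labels, lib, setup, n_ref, seed = seed * 100 + 1),
    air_kerma_mGy)
  ref <- total_dose(ref_res)
  mask <- beam_mask(labels, setup) & ref$values > 0
  ref_unc <- estimate_uncertainty(ref_res)

  guidance_hr <- absorption_map(labels, lib, spectrum)
  density_hr <- labels_to_density(labels, lib)

  mape_mode <- mape_fom <- mape_low <- stats::setNames(
    rep(NA_real_, length(scales)), paste0("s", scales))
  for (i in seq_along(scales)) {
    s <- scales[i]
    spec <- downsample_spec(s, "mode")
    rec <- reconstruct_from_simulation(
      labels, lib, setup, spec, n_histories = n_ref / 2,
      seed = seed * 100 + 10 + i, air_kerma_mGy = air_kerma_mGy)
    mape_mode[i] <- mape(rec$dose, ref, mask)

    if (include_fom) {
      coarse_fom <- downsample_fom(ref, density_hr, s)
      guidance_lr_fom <- downsample_fom(guidance_hr, density_hr, s)
      rec_fom <- upsample_dose(coarse_fom, guidance_hr, guidance_lr_fom,
                               downsample_spec(s, "fom"))
      mape_fom[i] <- mape(rec_fom, ref, mask)
    }
    if (!is.null(lowstat_factor)) {
      rec_lo <- reconstruct_from_simulation(
        labels, lib, setup, spec,
        n_histories = max(n_ref / 2 / lowstat_factor, 1000),
        seed = seed * 100 + 50 + i, air_kerma_mGy = air_kerma_mGy)
      mape_low[i] <- mape(rec_lo$dose, ref, mask)
    }
  }

  list(scales = scales, mape_mode = mape_mode,
       mape_fom = if (include_fom) mape_fom,
       mape_lowstat = if (!is.null(lowstat_factor)) mape_low,
       ref_median_2sigma = stats::median(ref_unc$values[mask]),
       n_ref = n_ref)
}
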