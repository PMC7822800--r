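#' X-ray spectrum
#'
#' A discrete photon-fluence spectrum: strictly increasing energies (keV)
#' with non-negative relative weights that are normalized to sum to one.
#' The peak tube voltage `kvp` bounds the maximum photon energy.
#'
#' @param energies Photon energies, keV, strictly increasing.
#' @param weights Relative photon fluence per bin, non-negative, not all
#'   zero; stored normalized.
#' @param kvp Peak tube voltage, kV; defaults to the maximum energy.
#' @return An object of class `xray_spectrum`.
#' @export
xray_spectrum <- function(energies, weights, kvp = max(energies)) {
  energies <- as.numeric(energies)
  weights <- as.numeric(weights)
  stopifnot(length(energies) == length(weights), length(energies) >= 1)
  if (any(diff(energies) <= 0)) {
    stop("spectrum energies must be strictly increasing", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("spectrum weights must be non-negative with positive sum",
         call. = FALSE)
  }
  if (max(energies) > kvp + 1e-9) {
    stop("spectrum energies must not exceed the peak tube voltage",
         call. = FALSE)
  }
  structure(list(energies = energies, weights = weights / sum(weights),
                 kvp = kvp),
            class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf(
    "<xray_spectrum> %d bins, %g-%g keV, kVp %g, mean energy %.2f keV\n",
    length(x$energies), min(x$energies), max(x$energies), x$kvp,
    spectrum_mean_energy(x)))
  invisible(x)
}

#' Fluence-weighted mean photon energy of a spectrum, keV
#' @param spectrum An `xray_spectrum`.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$weights * spectrum$energies)
}

#' Load a tabulated spectrum from CSV
#'
#' Expects a two-column CSV with header `energy_keV, relative_fluence`.
#'
#' @param path CSV file path.
#' @param kvp Optional peak voltage; defaults to the maximum tabulated
#'   energy.
#' @return An `xray_spectrum`.
#' @export
load_spectrum <- function(path, kvp = NULL) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    stop(sprintf("cannot read spectrum CSV '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  if (!all(c("energy_keV", "relative_fluence") %in% names(tab))) {
    stop("spectrum CSV must have columns 'energy_keV, relative_fluence'",
         call. = FALSE)
  }
  if (is.null(kvp)) kvp <- max(tab$energy_keV)
  xray_spectrum(tab$energy_keV, tab$relative_fluence, kvp)
}

#' Analytic bremsstrahlung spectrum
#'
#' Kramers-shaped photon fluence, proportional to `(kvp - E)`, hardened by
#' 2.3 mm aluminium-equivalent inherent filtration (tungsten-anode tube)
#' plus optional added filtration.  This is an acknowledged approximation
#' of measured or vendor-computed tube spectra; tabulated spectra loaded
#' with [load_spectrum()] are the accurate path.
#'
#' @param kvp Peak tube voltage, kV, in `[40, 150]`.
#' @param filtration Named numeric vector of added filtration thicknesses in
#'   mm, names resolving to library materials (e.g. `c(copper = 0.3)`).
#' @param lib Material library providing the filter attenuation
#'   coefficients.
#' @param inherent_al_mm Inherent filtration, mm of aluminium.
#' @param step Energy grid step, keV.
#' @return An `xray_spectrum`.
#' @examples
#' s <- make_analytic_spectrum(90)
#' spectrum_mean_energy(s)
#' @export
make_analytic_spectrum <- function(kvp, filtration = NULL,
                                   lib = build_material_library(),
                                   inherent_al_mm = 2.3, step = 1) {
  if (kvp < 40 || kvp > 150) {
    stop("kvp must be in [40, 150]", call. = FALSE)
  }
  energies <- seq(5, kvp, by = step)
  if (energies[length(energies)] >= kvp) {
    energies <- energies[energies < kvp]
  }
  w <- kvp - energies
  attenuate <- function(w, material_name, mm) {
    m <- lib_material(lib, material_name)
    mu_lin <- material_coefficient(m, energies, "attenuation") *
      m$density / 10  # cm^2/g * g/cm^3 -> 1/cm -> 1/mm
    w * exp(-mu_lin * mm)
  }
  w <- attenuate(w, "aluminum", inherent_al_mm)
  if (!is.null(filtration)) {
    if (is.null(names(filtration)) || any(!nzchar(names(filtration)))) {
      stop("filtration must be a named vector of thicknesses (mm)",
           call. = FALSE)
    }
    for (nm in names(filtration)) {
      w <- attenuate(w, nm, filtration[[nm]])
    }
  }
  keep <- w > max(w) * 1e-9
  xray_spectrum(energies[keep], w[keep], kvp)
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling over the discrete bins, driven by R's random number
#' generator (seed with [set.seed()] for reproducibility).
#'
#' @param spectrum An `xray_spectrum`.
#' @param n Number of draws.
#' @return Numeric vector of energies, keV.
#' @export
sample_spectrum_energy <- function(spectrum, n = 1) {
  if (length(spectrum$energies) == 1L) {
    return(rep(spectrum$energies, n))
  }
  spectrum$energies[findInterval(stats::runif(n),
                                 cumsum(spectrum$weights),
                                 rightmost.closed = TRUE) + 1L]
}
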