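#' X-ray interaction properties of a material
#'
#' A material bundles a mass density with energy-resolved photon interaction
#' data over the diagnostic energy range: the total mass attenuation
#' coefficient mu/rho, the mass energy-absorption coefficient muen/rho
#' (both cm^2/g), and the per-energy shares of the photoelectric, Compton
#' (incoherent) and Rayleigh (coherent) channels in mu.  Coefficients at
#' intermediate energies are obtained by log-log interpolation, the standard
#' behaviour for photon cross sections; no extrapolation outside the tabulated
#' grid is performed.
#'
#' @param name Material name.
#' @param density Mass density, g/cm^3; must be positive.
#' @param energy_keV Strictly increasing photon energies, keV.
#' @param mu_rho,muen_rho Mass attenuation / energy-absorption coefficients
#'   per energy, cm^2/g; `muen_rho <= mu_rho` everywhere.
#' @param f_photo,f_compton,f_rayleigh Non-negative interaction-type
#'   fractions of `mu_rho`; must sum to 1 at every energy.
#' @return An object of class `xray_material`.
#' @export
material <- function(name, density, energy_keV, mu_rho, muen_rho,
                     f_photo, f_compton, f_rayleigh) {
  energy_keV <- as.numeric(energy_keV)
  n <- length(energy_keV)
  stopifnot(n >= 2, length(mu_rho) == n, length(muen_rho) == n,
            length(f_photo) == n, length(f_compton) == n,
            length(f_rayleigh) == n)
  if (any(diff(energy_keV) <= 0)) {
    stop("energy grid must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("density must be a single positive number (g/cm^3)", call. = FALSE)
  }
  if (any(mu_rho <= 0) || any(muen_rho < 0)) {
    stop("coefficients must be positive", call. = FALSE)
  }
  if (any(muen_rho > mu_rho * (1 + 1e-9))) {
    stop("muen/rho must not exceed mu/rho", call. = FALSE)
  }
  fr <- cbind(f_photo, f_compton, f_rayleigh)
  if (any(fr < -1e-12) || any(abs(rowSums(fr) - 1) > 1e-3)) {
    stop("interaction fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  fr <- pmax(fr, 0)
  fr <- fr / rowSums(fr)
  structure(list(name = as.character(name), density = density,
                 energy_keV = energy_keV, mu_rho = as.numeric(mu_rho),
                 muen_rho = as.numeric(muen_rho),
                 f_photo = fr[, 1], f_compton = fr[, 2], f_rayleigh = fr[, 3]),
            class = "xray_material")
}

#' @export
print.xray_material <- function(x, ...) {
  cat(sprintf("<xray_material> %s: density %.4g g/cm^3, %d energies (%g-%g keV)\n",
              x$name, x$density, length(x$energy_keV),
              min(x$energy_keV), max(x$energy_keV)))
  invisible(x)
}

#' Material library: mapping from voxel labels to materials
#'
#' @param materials List of `xray_material` objects.
#' @param labels Integer vector of label ids, one per material, unique.
#' @return An object of class `material_library`.
#' @seealso [build_material_library()] for the packaged tissue set.
#' @export
material_library <- function(materials, labels) {
  stopifnot(length(materials) == length(labels))
  labels <- as.integer(labels)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  names_ <- vapply(materials, function(m) m$name, "")
  if (!"air" %in% names_) {
    stop("a material library must contain an 'air' entry", call. = FALSE)
  }
  structure(list(materials = stats::setNames(materials, names_),
                 labels = stats::setNames(labels, names_)),
            class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  cat("<material_library>\n")
  for (nm in names(x$materials)) {
    cat(sprintf("  %2d  %-12s rho = %.4g g/cm^3\n",
                x$labels[[nm]], nm, x$materials[[nm]]$density))
  }
  invisible(x)
}

#' Look up a material by label id or name
#' @param lib A `material_library`.
#' @param label Integer label id or material name.
#' @export
lib_material <- function(lib, label) {
  if (is.character(label)) {
    m <- lib$materials[[label]]
    if (is.null(m)) stop(sprintf("unknown material '%s'", label),
                         call. = FALSE)
    return(m)
  }
  i <- match(as.integer(label), lib$labels)
  if (is.na(i)) stop(sprintf("unknown label %d", as.integer(label)),
                     call. = FALSE)
  lib$materials[[i]]
}

#' Build the packaged tissue material library
#'
#' Loads the interaction-coefficient tables shipped with the package
#' (ICRU-44-style tissue compositions tabulated over 5-150 keV) and returns
#' a library covering air, soft tissue, adipose tissue, cortical bone,
#' brain, inflated lung and water, plus aluminium and copper for spectrum
#' filtration.  Label ids: air 0, soft_tissue 1, adipose 2, bone 3, brain 4,
#' lung 5, water 6, aluminum 7, copper 8.
#'
#' @return A `material_library`.
#' @examples
#' lib <- build_material_library()
#' lib_material(lib, "water")
#' @export
build_material_library <- function() {
  dir <- system.file("extdata", "materials", package = "dosekit")
  manifest_path <- file.path(dir, "manifest.csv")
  if (dir == "" || !file.exists(manifest_path)) {
    stop("packaged material tables are missing or corrupted", call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  order_ <- c("air", "soft_tissue", "adipose", "bone", "brain", "lung",
              "water", "aluminum", "copper")
  if (!setequal(manifest$name, order_)) {
    stop("packaged material manifest is corrupted", call. = FALSE)
  }
  mats <- lapply(order_, function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("packaged material table '%s' is missing", nm),
           call. = FALSE)
    }
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("energy_keV", "mu_rho", "muen_rho", "f_photo", "f_compton",
                "f_rayleigh")
    if (!all(needed %in% names(tab))) {
      stop(sprintf("packaged material table '%s' is corrupted", nm),
           call. = FALSE)
    }
    material(nm, manifest$density[manifest$name == nm], tab$energy_keV,
             tab$mu_rho, tab$muen_rho, tab$f_photo, tab$f_compton,
             tab$f_rayleigh)
  })
  material_library(mats, seq_along(order_) - 1L)
}

#' Interpolate a material coefficient at arbitrary energies
#'
#' Log-log interpolation of mu/rho or muen/rho; interaction fractions are
#' interpolated linearly.  Energies outside the tabulated grid raise an
#' error (no extrapolation).
#'
#' @param mat An `xray_material`.
#' @param energy_keV Energies, keV.
#' @param kind `"attenuation"` (mu/rho), `"absorption"` (muen/rho) or one of
#'   the fraction columns `"f_photo"`, `"f_compton"`, `"f_rayleigh"`.
#' @return Numeric vector, cm^2/g (dimensionless for fractions).
#' @export
material_coefficient <- function(mat, energy_keV,
                                 kind = c("attenuation", "absorption",
                                          "f_photo", "f_compton",
                                          "f_rayleigh")) {
  kind <- match.arg(kind)
  e <- mat$energy_keV
  if (any(energy_keV < e[1] - 1e-9) || any(energy_keV > e[length(e)] + 1e-9)) {
    stop(sprintf(
      "energy outside the tabulated range [%g, %g] keV for material '%s'",
      e[1], e[length(e)], mat$name), call. = FALSE)
  }
  energy_keV <- pmin(pmax(energy_keV, e[1]), e[length(e)])
  if (kind %in% c("attenuation", "absorption")) {
    y <- if (kind == "attenuation") mat$mu_rho else mat$muen_rho
    exp(stats::approx(log(e), log(pmax(y, 1e-300)), xout = log(energy_keV),
                      rule = 1)$y)
  } else {
    stats::approx(e, mat[[kind]], xout = energy_keV, rule = 1)$y
  }
}

#' Voxelwise mass-density map from a label volume
#'
#' @param labels A `label_volume`.
#' @param lib A `material_library` resolving every label.
#' @return A `scalar_volume` of densities, g/cm^3, on the same grid.
#' @export
labels_to_density <- function(labels, lib) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(lib, "material_library"))
  lut <- label_lookup(labels, lib)
  dens <- vapply(lib$materials, function(m) m$density, 0)[lut$name_of]
  scalar_volume(array(dens[lut$index], dim(labels$values)),
                labels$spacing, labels$origin)
}

# map the labels present in a volume onto library materials; errors name the
# offending label
label_lookup <- function(labels, lib) {
  present <- sort(unique(as.integer(labels$values)))
  miss <- setdiff(present, lib$labels)
  if (length(miss)) {
    stop(sprintf("label %d is not in the material library", miss[1]),
         call. = FALSE)
  }
  name_of <- names(lib$labels)[match(present, lib$labels)]
  # index: for each voxel, position of its label within `present`
  index <- match(labels$values, present)
  list(present = present, name_of = name_of, index = index)
}

#' Spectrum-averaged interaction coefficient
#'
#' Collapses the energy dependence of a coefficient over an X-ray spectrum
#' using energy-fluence weighting: each spectrum bin contributes its photon
#' fluence times its photon energy.  This is the weighting under which dose
#' relates to the energy fluence through muen/rho.
#'
#' @param mat An `xray_material`.
#' @param spectrum An [xray_spectrum()].
#' @param kind `"attenuation"` or `"absorption"`.
#' @return Single coefficient, cm^2/g.
#' @export
spectrum_averaged_coefficient <- function(mat, spectrum,
                                          kind = c("attenuation",
                                                   "absorption")) {
  kind <- match.arg(kind)
  stopifnot(inherits(spectrum, "xray_spectrum"))
  w <- spectrum$weights * spectrum$energies
  w <- w / sum(w)
  sum(w * material_coefficient(mat, spectrum$energies, kind))
}

#' Voxelized absorption guidance map
#'
#' Maps every voxel of a label volume to the spectrum-averaged mass
#' energy-absorption coefficient muen/rho of its tissue.  This is the
#' high-resolution guidance image of the guided-filter dose reconstruction:
#' it is piecewise constant per tissue region, so its edges are exactly the
#' tissue boundaries of the patient model.
#'
#' @inheritParams labels_to_density
#' @param spectrum An [xray_spectrum()].
#' @return A `scalar_volume` of muen/rho values, cm^2/g.
#' @export
absorption_map <- function(labels, lib, spectrum) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(lib, "material_library"))
  lut <- label_lookup(labels, lib)
  coef <- vapply(lut$name_of, function(nm) {
    spectrum_averaged_coefficient(lib$materials[[nm]], spectrum, "absorption")
  }, 0)
  scalar_volume(array(coef[lut$index], dim(labels$values)),
                labels$spacing, labels$origin)
}
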