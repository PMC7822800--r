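#' Rigid poses in SE(3)
#'
#' A pose is a rotation plus a translation mapping local coordinates into
#' world coordinates (mm).  Used to express the position and orientation of
#' the X-ray source and beam frame relative to the phantom.
#'
#' @param rotation 3x3 rotation matrix, orthonormal with determinant +1
#'   (checked to 1e-9).
#' @param translation Length-3 translation, mm.
#' @return An object of class `se3_pose`.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "se3_pose")
}

#' @rdname pose
#' @param a,b Poses; `pose_compose(a, b)` applies `b` first, then `a`.
#' @export
pose_compose <- function(a, b) {
  pose(a$rotation %*% b$rotation,
       as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname pose
#' @param p A pose.
#' @export
pose_inverse <- function(p) {
  pose(t(p$rotation), as.numeric(-t(p$rotation) %*% p$translation))
}

#' @rdname pose
#' @param points Length-3 vector or n x 3 matrix of points, mm.
#' @export
pose_apply <- function(p, points) {
  if (is.null(dim(points))) {
    as.numeric(p$rotation %*% points) + p$translation
  } else {
    sweep(points %*% t(p$rotation), 2, p$translation, `+`)
  }
}

#' C-arm beam setup
#'
#' Parameterizes the imaging geometry directly: the positioner primary angle
#' rotates the source about the phantom's longitudinal (z) axis, with 0
#' degrees the posteroanterior direction and 90 degrees lateral; secondary
#' and table angles are fixed at zero.  Collimation is a rectangular pyramid
#' matching a flat detector, with half-opening angles `opening_phi` (first
#' detector axis, in the axial plane) and `opening_theta` (longitudinal
#' axis), measured from the central ray to the field edge.
#'
#' @param primary_angle Positioner primary angle, degrees.
#' @param sod Source-to-isocenter distance, mm.
#' @param sid Source-to-image distance, mm; must exceed `sod`.
#' @param opening_phi,opening_theta Half-opening angles, degrees, in
#'   (0, 45).
#' @param isocenter World position of the isocenter, mm.
#' @param spectrum An [xray_spectrum()].
#' @param reference_offset Distance of the interventional reference point
#'   from the isocenter toward the source along the central ray, mm
#'   (IEC convention: 150 mm).
#' @return An object of class `beam_setup`.
#' @examples
#' s <- beam_setup(0, spectrum = xray_spectrum(60, 1))
#' source_pose(s)$translation
#' @export
beam_setup <- function(primary_angle = 0, sod = 800, sid = 1200,
                       opening_phi = 6, opening_theta = 6,
                       isocenter = c(0, 0, 0), spectrum,
                       reference_offset = 150) {
  stopifnot(inherits(spectrum, "xray_spectrum"), length(isocenter) == 3)
  if (!(sod > 0 && sod < sid)) {
    stop("need 0 < sod < sid", call. = FALSE)
  }
  if (opening_phi <= 0 || opening_phi >= 45 ||
      opening_theta <= 0 || opening_theta >= 45) {
    stop("opening angles must lie in (0, 45) degrees", call. = FALSE)
  }
  structure(list(primary_angle = primary_angle, sod = sod, sid = sid,
                 opening_phi = opening_phi, opening_theta = opening_theta,
                 isocenter = as.numeric(isocenter), spectrum = spectrum,
                 reference_offset = reference_offset),
            class = "beam_setup")
}

#' @export
print.beam_setup <- function(x, ...) {
  cat(sprintf(
    "<beam_setup> primary angle %g deg, SOD %g mm, SID %g mm, opening %g x %g deg, kVp %g\n",
    x$primary_angle, x$sod, x$sid, x$opening_phi, x$opening_theta,
    x$spectrum$kvp))
  invisible(x)
}

# beam frame unit vectors: e_u (first detector axis, axial plane),
# e_v (longitudinal), e_c (central ray direction, source -> isocenter)
beam_axes <- function(setup) {
  a <- setup$primary_angle * pi / 180
  # right-handed frame: e_u x e_v = e_c
  list(e_u = c(-cos(a), -sin(a), 0),
       e_v = c(0, 0, 1),
       e_c = c(-sin(a), cos(a), 0))
}

#' Pose of the X-ray focal spot
#'
#' The source sits at distance `sod` from the isocenter, rotated about the
#' longitudinal axis by the primary angle; the pose's third rotation column
#' is the central ray direction (pointing at the isocenter).
#'
#' @param setup A [beam_setup()].
#' @return An `se3_pose` whose translation is the source position.
#' @export
source_pose <- function(setup) {
  ax <- beam_axes(setup)
  pose(cbind(ax$e_u, ax$e_v, ax$e_c),
       setup$isocenter - setup$sod * ax$e_c)
}

#' Collimation test
#'
#' Returns whether the ray from the source through each point lies inside
#' the rectangular collimation pyramid.
#'
#' @param setup A [beam_setup()].
#' @param points Length-3 vector or n x 3 matrix of world points, mm.
#' @return Logical vector.
#' @export
beam_contains <- function(setup, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  ax <- beam_axes(setup)
  src <- setup$isocenter - setup$sod * ax$e_c
  v <- sweep(points, 2, src, `-`)
  if (any(rowSums(v * v) == 0)) {
    stop("point coincides with the X-ray source", call. = FALSE)
  }
  t_ <- as.numeric(v %*% ax$e_c)
  u <- as.numeric(v %*% ax$e_u)
  w <- as.numeric(v %*% ax$e_v)
  tan_phi <- tan(setup$opening_phi * pi / 180)
  tan_theta <- tan(setup$opening_theta * pi / 180)
  t_ > 0 & abs(u) <= t_ * tan_phi & abs(w) <= t_ * tan_theta
}

#' Interventional reference point
#'
#' Point on the central ray at `setup$reference_offset` millimetres from the
#' isocenter toward the source (IEC convention: 150 mm), where the free-in-air
#' collision kerma is scored and compared with the air kerma reported by the
#' X-ray system.
#'
#' @param setup A [beam_setup()].
#' @return World position, mm.
#' @export
reference_point <- function(setup) {
  if (setup$reference_offset >= setup$sod) {
    stop("reference offset must be smaller than the source-isocenter distance",
         call. = FALSE)
  }
  ax <- beam_axes(setup)
  setup$isocenter - setup$reference_offset * ax$e_c
}

#' Read a beam geometry configuration from YAML
#'
#' Recognized keys: `primary_angle_deg`, `sod_mm`, `sid_mm`,
#' `opening_phi_deg`, `opening_theta_deg`, `reference_offset_mm`, `kvp`,
#' `spectrum_csv` (optional; when absent an analytic spectrum at `kvp` is
#' used), `isocenter_mm` (optional).
#'
#' @param config Path to a YAML file or an already-parsed list.
#' @param lib Material library for the analytic-spectrum fallback.
#' @return A [beam_setup()].
#' @export
read_geometry_config <- function(config, lib = build_material_library()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  spectrum <- if (!is.null(config$spectrum_csv)) {
    load_spectrum(config$spectrum_csv)
  } else {
    make_analytic_spectrum(config$kvp, lib = lib)
  }
  beam_setup(
    primary_angle = config$primary_angle_deg %||% 0,
    sod = config$sod_mm %||% 800,
    sid = config$sid_mm %||% 1200,
    opening_phi = config$opening_phi_deg %||% 6,
    opening_theta = config$opening_theta_deg %||% 6,
    isocenter = config$isocenter_mm %||% c(0, 0, 0),
    spectrum = spectrum,
    reference_offset = config$reference_offset_mm %||% 150)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
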