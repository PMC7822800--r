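#' Down-sampling / reconstruction parameters
#'
#' Bundles the in-plane window size `s`, the down-sampling method, the
#' guided-filter radius (by default tied to `s` through [radius_from_scale()])
#' and the guided-filter regularizer `eps`.
#'
#' @param s Integer in-plane window size, >= 1.
#' @param method `"mode"` (statistical-mode label down-sampling, the
#'   simulation path) or `"fom"` (fraction-of-mass averaging, the comparison
#'   arm operating on dose volumes).
#' @param radius Guided-filter box radius in high-resolution pixels;
#'   defaults to `radius_from_scale(s)`.
#' @param eps Guided-filter regularizer on the guidance scale; `NULL` means
#'   `(0.01 * range(guidance))^2` is chosen when the filter is applied.
#' @return An object of class `downsample_spec`.
#' @export
downsample_spec <- function(s, method = c("mode", "fom"),
                            radius = radius_from_scale(s), eps = NULL) {
  method <- match.arg(method)
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (!is.null(eps) && eps <= 0) stop("eps must be positive", call. = FALSE)
  structure(list(s = s, method = method, radius = as.integer(radius),
                 eps = eps),
            class = "downsample_spec")
}

#' Guided-filter radius for a down-sampling window size
#'
#' `r(s)` is half the window size rounded to the nearest integer (half-up),
#' plus one, so the filter support tracks the size of the down-sampling
#' neighbourhood.
#'
#' @param s Integer window size, >= 1.
#' @return Integer radius.
#' @examples
#' radius_from_scale(c(2, 4, 8, 16))
#' @export
radius_from_scale <- function(s) {
  if (any(s < 1)) stop("s must be >= 1", call. = FALSE)
  as.integer(floor(0.5 * s + 0.5) + 1L)
}

# window index of each high-resolution in-plane position; trailing partial
# windows keep their actual (smaller) size rather than cropping anatomy
window_index <- function(n, s) (seq_len(n) - 1L) %/% s + 1L

# aggregate a matrix over s x s windows with function sum
window_sum <- function(m, s) {
  gi <- window_index(nrow(m), s)
  gj <- window_index(ncol(m), s)
  t(rowsum(t(rowsum(m, gi)), gj))
}

#' Fraction-of-mass down-sampling of a scalar volume
#'
#' Collapses each in-plane `s` x `s` neighbourhood (slice-wise; the axial
#' dimension is untouched) into a single voxel by mass-weighted averaging:
#' the output is `sum(m_x * f_x) / sum(m_x)` with voxel mass
#' `m_x = V * rho_x`.  This is the "hybrid mixture material" view of a
#' neighbourhood: the value each voxel contributes is proportional to its
#' fraction of the neighbourhood mass.  Windows with zero total mass fall
#' back to the unweighted mean, with a warning.
#'
#' @param values A `scalar_volume` to down-sample.
#' @param density A `scalar_volume` of mass densities on the same grid,
#'   g/cm^3.
#' @param s Integer in-plane window size.
#' @return A `scalar_volume` on the coarse grid (in-plane spacing scaled
#'   by `s`).
#' @export
downsample_fom <- function(values, density, s) {
  stopifnot(inherits(values, "scalar_volume"),
            inherits(density, "scalar_volume"))
  stop_if_grid_mismatch(values, density)
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  d <- dim(values$values)
  nz <- d[3]
  dc <- c(length(unique(window_index(d[1], s))),
          length(unique(window_index(d[2], s))), nz)
  out <- array(0, dc)
  warned <- FALSE
  for (k in seq_len(nz)) {
    mass <- matrix(density$values[, , k], d[1], d[2])  # V cancels
    vals <- matrix(values$values[, , k], d[1], d[2])
    num <- window_sum(vals * mass, s)
    den <- window_sum(mass, s)
    zero <- den <= 0
    if (any(zero)) {
      if (!warned) {
        warning("zero-mass window(s): falling back to unweighted mean")
        warned <- TRUE
      }
      num[zero] <- window_sum(vals, s)[zero]
      den[zero] <- window_sum(array(1, dim(mass)), s)[zero]
    }
    out[, , k] <- num / den
  }
  scalar_volume(out, spacing = values$spacing * c(s, s, 1),
                origin = values$origin)
}

#' Statistical-mode down-sampling of a label volume
#'
#' Replaces each in-plane `s` x `s` neighbourhood by its most frequent
#' tissue label, so at least the most often occurring tissue of the
#' neighbourhood is represented on the coarse grid.  Ties are broken
#' deterministically: the label with the highest mass density wins, then
#' the lowest label id.
#'
#' @param labels A `label_volume`.
#' @param s Integer in-plane window size.
#' @param lib Material library supplying densities for the tie-break.
#' @return A `label_volume` on the coarse grid.
#' @export
downsample_mode <- function(labels, s, lib = build_material_library()) {
  stopifnot(inherits(labels, "label_volume"))
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  d <- dim(labels$values)
  lut <- label_lookup(labels, lib)
  dens <- vapply(lib$materials, function(m) m$density, 0)[lut$name_of]
  # visit candidate labels from lowest to highest priority so that later
  # (higher-density, then lower-id) candidates win ties by strict >=
  prio <- order(dens, -lut$present)
  dc <- c(length(unique(window_index(d[1], s))),
          length(unique(window_index(d[2], s))), d[3])
  best_count <- array(-1, dc)
  best_label <- array(0L, dc)
  for (li in prio) {
    lab <- lut$present[li]
    cnt <- array(0, dc)
    for (k in seq_len(d[3])) {
      cnt[, , k] <- window_sum(matrix((labels$values[, , k] == lab) * 1,
                                      d[1], d[2]), s)
    }
    take <- cnt >= best_count
    best_count[take] <- cnt[take]
    best_label[take] <- lab
  }
  label_volume(best_label, spacing = labels$spacing * c(s, s, 1),
               origin = labels$origin)
}

#' Edge-preserving guided filter (2-D)
#'
#' The standard box-window guided filter: within every `(2r+1)` square
#' window a linear model `a * guide + b` is fitted to `src` by ridge
#' regression with regularizer `eps`, and each pixel outputs the average of
#' the models of all windows covering it.  Windows at the image border use
#' their valid (shrunken) area for normalization.
#'
#' @param guide,src Equal-shaped numeric matrices; all pixels finite.
#' @param r Integer box radius, >= 1.
#' @param eps Positive regularizer, on the squared scale of `guide`.
#' @return Filtered matrix of the same shape.
#' @examples
#' g <- matrix(rep(c(0, 1), each = 8), 4)
#' guided_filter_2d(g, g + 0.01, r = 2, eps = 1e-8)
#' @export
guided_filter_2d <- function(guide, src, r, eps) {
  stopifnot(is.matrix(guide), is.matrix(src),
            all(dim(guide) == dim(src)))
  if (!all(is.finite(guide)) || !all(is.finite(src))) {
    stop("guided filter inputs must be finite", call. = FALSE)
  }
  r <- as.integer(r)
  if (r < 1) stop("radius must be >= 1", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  cnt <- box_sum(matrix(1, nrow(guide), ncol(guide)), r)
  bx <- function(m) box_sum(m, r) / cnt
  mean_g <- bx(guide)
  mean_s <- bx(src)
  var_g <- bx(guide * guide) - mean_g^2
  cov_gs <- bx(guide * src) - mean_g * mean_s
  a <- cov_gs / (var_g + eps)
  b <- mean_s - a * mean_g
  bx(a) * guide + bx(b)
}

# sliding-window sums over (2r+1)^2 boxes clipped to the image
box_sum <- function(m, r) {
  along_rows <- function(x) {
    n <- nrow(x)
    cs <- rbind(0, apply(x, 2, cumsum))
    hi <- pmin(n, seq_len(n) + r)
    lo <- pmax(0, seq_len(n) - r - 1L)
    cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  t(along_rows(t(along_rows(m))))
}

#' Fluence-domain guided-filter dose reconstruction
#'
#' Reconstructs a high-resolution dose distribution from a coarse one.
#' Under charged-particle equilibrium the absorbed dose decouples into the
#' photon energy fluence times the tissue's mass energy-absorption
#' coefficient, `D = psi * (muen/rho)`.  The fluence is smooth across
#' tissue boundaries, so the coarse dose is first divided by the coarse
#' guidance map to yield a coarse fluence estimate, replicated onto the
#' high-resolution grid (nearest neighbour; the edge-aware filter supplies
#' all smoothing), filtered slice-wise with the high-resolution guidance
#' image, and finally multiplied back by the guidance map.  Negative
#' filter output is clamped to zero.
#'
#' @param coarse_dose Coarse `scalar_volume` of dose, mGy, on the same grid
#'   as `guidance_lr`.
#' @param guidance_hr High-resolution guidance `scalar_volume`
#'   (spectrum-averaged muen/rho map, see [absorption_map()]).
#' @param guidance_lr Down-sampled guidance map on the coarse grid.
#' @param spec A [downsample_spec()] providing `s`, `radius` and `eps`.
#' @return A `scalar_volume` of reconstructed dose on the high-resolution
#'   grid.
#' @export
upsample_dose <- function(coarse_dose, guidance_hr, guidance_lr, spec) {
  stopifnot(inherits(coarse_dose, "scalar_volume"),
            inherits(guidance_hr, "scalar_volume"),
            inherits(guidance_lr, "scalar_volume"),
            inherits(spec, "downsample_spec"))
  stop_if_grid_mismatch(coarse_dose, guidance_lr,
                        "coarse dose and coarse guidance")
  d_hr <- dim(guidance_hr$values)
  d_lr <- dim(coarse_dose$values)
  wi <- window_index(d_hr[1], spec$s)
  wj <- window_index(d_hr[2], spec$s)
  if (max(wi) != d_lr[1] || max(wj) != d_lr[2] || d_hr[3] != d_lr[3]) {
    stop("coarse grid does not match the high-resolution grid at scale s",
         call. = FALSE)
  }
  floor_lr <- guidance_floor(guidance_lr$values)
  floor_hr <- guidance_floor(guidance_hr$values)
  psi_n <- coarse_dose$values / pmax(guidance_lr$values, floor_lr)
  eps <- spec$eps %||% (0.01 * diff(range(guidance_hr$values)))^2
  if (eps <= 0) eps <- 1e-12  # uniform guidance: plain box smoothing
  out <- array(0, d_hr)
  for (k in seq_len(d_hr[3])) {
    psi_hr <- matrix(psi_n[wi, wj, k], d_hr[1], d_hr[2])
    guide <- matrix(guidance_hr$values[, , k], d_hr[1], d_hr[2])
    psi <- guided_filter_2d(guide, psi_hr, spec$radius, eps)
    out[, , k] <- pmax(psi * pmax(guide, floor_hr), 0)
  }
  scalar_volume(out, guidance_hr$spacing, guidance_hr$origin)
}

# smallest positive guidance value; division by the guidance map never hits
# zero (air carries its own small but positive muen/rho)
guidance_floor <- function(v) {
  pos <- v[v > 0]
  if (!length(pos)) {
    stop("guidance map has no positive values", call. = FALSE)
  }
  min(pos)
}

#' Coarse simulation plus guided-filter reconstruction
#'
#' Convenience composition of the accelerated simulation path: the label
#' volume is mode-down-sampled by `spec$s`, the Monte Carlo simulation runs
#' on the coarse grid, and the coarse dose is reconstructed on the original
#' grid by [upsample_dose()] with the spectrum-averaged muen/rho guidance.
#'
#' @param labels_hr High-resolution `label_volume`.
#' @param lib A `material_library`.
#' @param setup A [beam_setup()].
#' @param spec A [downsample_spec()].
#' @param n_histories Number of primary photon histories for the coarse
#'   simulation.
#' @param seed Integer seed for the simulation.
#' @param n_batches Batches for the uncertainty estimate.
#' @param air_kerma_mGy Optional measured reference-point air kerma the
#'   result is scaled to.
#' @return List with elements `dose` (reconstructed high-resolution
#'   `scalar_volume`, mGy) and `coarse` (the raw coarse [simulate_dose()]
#'   result).
#' @export
reconstruct_from_simulation <- function(labels_hr, lib, setup, spec,
                                        n_histories, seed = 1,
                                        n_batches = 10,
                                        air_kerma_mGy = NULL) {
  stopifnot(inherits(spec, "downsample_spec"))
  labels_lr <- if (spec$s == 1L) labels_hr else {
    downsample_mode(labels_hr, spec$s, lib)
  }
  res <- simulate_dose(labels_lr, lib, setup, n_histories,
                       seed = seed, n_batches = n_batches)
  if (!is.null(air_kerma_mGy)) {
    res <- scale_to_air_kerma(res, air_kerma_mGy)
  }
  guidance_hr <- absorption_map(labels_hr, lib, setup$spectrum)
  guidance_lr <- absorption_map(labels_lr, lib, setup$spectrum)
  dose <- upsample_dose(total_dose(res), guidance_hr, guidance_lr, spec)
  list(dose = dose, coarse = res)
}
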