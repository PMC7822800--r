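#' Synthetic voxel head phantom
#'
#' Generates a head-like label volume for simulation studies: an air
#' background, an ellipsoidal brain, a cranial bone shell fully enclosing
#' the brain, a soft-tissue scalp around the bone, and a few adipose
#' pockets embedded in the scalp.  The grid is an axial slab through the
#' head: the brain spans most of the axial extent and is capped by bone in
#' the outermost slices.  Shell thicknesses are anatomical (about 3.5 mm of
#' bone and 4 mm of scalp) and therefore adapt to the voxel spacing.  The
#' bone and scalp layers are built by morphological dilation of the brain
#' ellipsoid, which guarantees that any axis-aligned path leaving the brain
#' crosses bone before reaching air.  The grid is centred on the world
#' origin, so the phantom centre coincides with the default isocenter.
#'
#' Label ids follow the packaged material library: air 0, soft tissue 1,
#' adipose 2, bone 3, brain 4.
#'
#' @param n_xy In-plane grid size (square slices); at least 32.
#' @param n_z Number of axial slices; at least 6.
#' @param spacing Voxel size, mm.
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @param n_adipose Number of adipose pockets placed in the scalp.
#' @return A [label_volume()].
#' @examples
#' ph <- make_head_phantom(48, 8, seed = 0)
#' table(ph$values)
#' @export
make_head_phantom <- function(n_xy, n_z, spacing = c(1.8, 1.8, 5),
                              seed = 0, n_adipose = 4) {
  if (n_xy < 32) stop("n_xy must be at least 32", call. = FALSE)
  if (n_z < 6) {
    stop("grid too small to fit all shells: need n_z >= 6", call. = FALSE)
  }
  dims <- c(n_xy, n_xy, n_z)
  bone_vox <- max(1L, round(6 / spacing[1]))
  scalp_vox <- max(1L, round(5 / spacing[1]))

  # head ellipse fills most of the slice; the brain is what remains inside
  # the scalp and bone shells
  cx <- (n_xy - 1) / 2
  cz <- (n_z - 1) / 2
  ax <- 0.40 * n_xy - bone_vox - scalp_vox
  ay <- 0.46 * n_xy - bone_vox - scalp_vox
  az <- cz - 1
  if (ax < 4 || az < 1) {
    stop("grid too small to fit all shells", call. = FALSE)
  }
  i <- (seq_len(n_xy) - 1 - cx) / ax
  j <- (seq_len(n_xy) - 1 - cx) / ay
  k <- (seq_len(n_z) - 1 - cz) / az
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  brain <- r2 <= 1

  shift_or <- function(m, axis) {
    d <- m
    if (axis == 1) {
      d[-1, , ] <- d[-1, , ] | m[-dims[1], , ]
      d[-dims[1], , ] <- d[-dims[1], , ] | m[-1, , ]
    } else if (axis == 2) {
      d[, -1, ] <- d[, -1, ] | m[, -dims[2], ]
      d[, -dims[2], ] <- d[, -dims[2], ] | m[, -1, ]
    } else {
      d[, , -1] <- d[, , -1] | m[, , -dims[3]]
      d[, , -dims[3]] <- d[, , -dims[3]] | m[, , -1]
    }
    d
  }
  dilate_xy <- function(m, times) {
    for (t in seq_len(times)) m <- shift_or(shift_or(m, 1), 2)
    m
  }
  skull <- dilate_xy(shift_or(brain, 3), bone_vox)
  head <- dilate_xy(skull, scalp_vox)
  if (any(head[c(1, n_xy), , ]) || any(head[, c(1, n_xy), ])) {
    stop("grid too small to fit all shells inside an air border",
         call. = FALSE)
  }

  lab <- array(0L, dims)
  lab[head] <- 1L    # soft-tissue scalp
  lab[skull] <- 3L   # bone
  lab[brain] <- 4L   # brain

  # adipose pockets in the scalp, reproducible under the seed without
  # disturbing the caller's RNG stream
  scalp_idx <- which(lab == 1L)
  if (n_adipose > 0 && length(scalp_idx)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old_seed), add = TRUE)
    set.seed(seed)
    pocket_r <- max(2, round(3 / spacing[1]))
    centers <- arrayInd(sample(scalp_idx, n_adipose), dims)
    for (p in seq_len(nrow(centers))) {
      di <- slice.index(lab, 1) - centers[p, 1]
      dj <- slice.index(lab, 2) - centers[p, 2]
      dk <- slice.index(lab, 3) - centers[p, 3]
      pocket <- (di^2 + dj^2 <= pocket_r^2) & (dk == 0) & lab == 1L
      lab[pocket] <- 2L
    }
  }

  label_volume(lab, spacing = spacing, origin = -dims * spacing / 2)
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
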