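#' Point-dose measurement set
#'
#' Discrete dose probes (e.g. MOSFET dosimeters) with world positions,
#' repeat-averaged dose readings and their standard deviation.
#'
#' @param id Unique probe identifiers.
#' @param position `n x 3` matrix of world positions, mm.
#' @param dose_mGy Mean measured dose per probe, mGy.
#' @param sigma_mGy Standard deviation over repeats, mGy, non-negative.
#' @param n_repeats Number of repeat acquisitions per probe.
#' @return A data frame of class `measurement_set` with columns `id`,
#'   `x_mm`, `y_mm`, `z_mm`, `dose_mGy`, `sigma_mGy`, `n_repeats`.
#' @export
measurement_set <- function(id, position, dose_mGy, sigma_mGy,
                            n_repeats = 1L) {
  position <- as.matrix(position)
  n <- length(id)
  stopifnot(nrow(position) == n, ncol(position) == 3,
            length(dose_mGy) == n, length(sigma_mGy) == n)
  if (anyDuplicated(id)) stop("probe ids must be unique", call. = FALSE)
  if (any(!is.finite(position))) {
    stop("probe positions must be finite", call. = FALSE)
  }
  if (any(sigma_mGy < 0)) stop("sigma must be non-negative", call. = FALSE)
  structure(data.frame(id = as.character(id), x_mm = position[, 1],
                       y_mm = position[, 2], z_mm = position[, 3],
                       dose_mGy = dose_mGy, sigma_mGy = sigma_mGy,
                       n_repeats = rep_len(as.integer(n_repeats), n),
                       stringsAsFactors = FALSE),
            class = c("measurement_set", "data.frame"))
}

#' Read / write measurement-point tables
#'
#' CSV schema: `id, x_mm, y_mm, z_mm, dose_mGy, sigma_mGy, n_repeats`.
#'
#' @param path CSV file path.
#' @param points A `measurement_set`.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "x_mm", "y_mm", "z_mm", "dose_mGy", "sigma_mGy",
              "n_repeats")
  if (!all(needed %in% names(tab))) {
    stop("measurement CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  measurement_set(tab$id, as.matrix(tab[, c("x_mm", "y_mm", "z_mm")]),
                  tab$dose_mGy, tab$sigma_mGy, tab$n_repeats)
}

#' @rdname read_measurements
#' @export
write_measurements <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Mean absolute percentage error between dose volumes
#'
#' Mean over the masked voxels of `100 * |estimate - reference| /
#' reference`.  Scale-invariant: rescaling both volumes by the same factor
#' leaves the result unchanged.
#'
#' @param estimate,reference `scalar_volume`s on the same grid.
#' @param mask Optional logical array (or `label_volume` whose non-zero
#'   voxels are included); `NULL` evaluates all voxels.  The reference must
#'   be strictly positive inside the mask.
#' @return Percentage error (a single number).
#' @export
mape <- function(estimate, reference, mask = NULL) {
  stop_if_grid_mismatch(estimate, reference)
  sel <- resolve_mask(mask, dim(reference$values))
  if (!any(sel)) stop("empty evaluation mask", call. = FALSE)
  ref <- reference$values[sel]
  if (any(ref <= 0)) {
    stop("reference must be strictly positive inside the mask",
         call. = FALSE)
  }
  mean(abs(estimate$values[sel] - ref) / ref) * 100
}

resolve_mask <- function(mask, d) {
  if (is.null(mask)) return(array(TRUE, d))
  if (inherits(mask, "label_volume")) mask <- mask$values != 0
  if (!is.logical(mask)) mask <- mask != 0
  if (!identical(dim(mask), as.integer(d))) {
    stop("mask is not on the same grid", call. = FALSE)
  }
  mask
}

#' Voxel-wise absolute percentage error map
#'
#' `100 * |estimate - reference| / reference` per voxel; voxels where the
#' reference is zero are flagged `NA`.  The mean of the map over a mask
#' equals [mape()] over that mask.
#'
#' @inheritParams mape
#' @return A `scalar_volume`-shaped list with the same grid metadata whose
#'   `values` may contain `NA` at reference-zero voxels.
#' @export
error_map <- function(estimate, reference) {
  stop_if_grid_mismatch(estimate, reference)
  v <- abs(estimate$values - reference$values) / reference$values * 100
  v[reference$values == 0] <- NA_real_
  structure(list(values = v, spacing = reference$spacing,
                 origin = reference$origin),
            class = c("scalar_volume", "voxel_volume"))
}

#' Slice-wise organ-equivalent dose
#'
#' For each axial slice containing voxels of the organ, the mass-weighted
#' mean absorbed dose over the organ voxels of that slice.  With a single
#' tissue label the organ density is uniform, so mass weighting coincides
#' with the plain mean; the radiation weighting factor of photons is 1, so
#' equivalent dose equals absorbed dose.
#'
#' @param dose A `scalar_volume`, mGy.
#' @param labels A `label_volume` on the same grid.
#' @param organ_label Integer label of the organ.
#' @return Data frame with columns `slice` (1-based axial index),
#'   `dose_mGy`, `n_voxels`; zero rows (with a warning) if the organ is
#'   absent.
#' @export
slice_organ_dose <- function(dose, labels, organ_label) {
  stop_if_grid_mismatch(dose, labels, "dose and labels")
  d <- dim(dose$values)
  out <- lapply(seq_len(d[3]), function(k) {
    sel <- labels$values[, , k] == organ_label
    if (!any(sel)) return(NULL)
    data.frame(slice = k, dose_mGy = mean(dose$values[, , k][sel]),
               n_voxels = sum(sel))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    warning(sprintf("organ label %d not present in the volume", organ_label))
    out <- data.frame(slice = integer(), dose_mGy = numeric(),
                      n_voxels = integer())
  }
  out
}

#' Trilinear dose sampling at probe positions
#'
#' Interpolates the dose volume at each probe's world position using
#' trilinear interpolation between voxel centers (probes such as MOSFETs
#' are below voxel scale, so no volume averaging is applied).
#'
#' @param dose A `scalar_volume`.
#' @param points A `measurement_set` (positions must lie inside the
#'   volume).
#' @return Named numeric vector of interpolated doses, mGy.
#' @export
sample_dose_at_points <- function(dose, points) {
  stopifnot(inherits(points, "measurement_set"))
  d <- dim(dose$values)
  p <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  upper <- dose$origin + d * dose$spacing
  out_of_grid <- apply(p, 1, function(x) {
    any(x < dose$origin) || any(x > upper)
  })
  if (any(out_of_grid)) {
    stop(sprintf("measurement point '%s' lies outside the dose volume",
                 points$id[which(out_of_grid)[1]]), call. = FALSE)
  }
  ci <- sweep(sweep(p, 2, dose$origin, `-`), 2, dose$spacing, `/`) - 0.5
  vals <- vapply(seq_len(nrow(ci)), function(r) {
    c0 <- pmin(pmax(floor(ci[r, ]), 0), d - 1)
    c1 <- pmin(c0 + 1, d - 1)
    f <- pmin(pmax(ci[r, ] - c0, 0), 1)
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      idx <- c(if (dx) c1[1] else c0[1],
               if (dy) c1[2] else c0[2],
               if (dz) c1[3] else c0[3]) + 1
      acc <- acc + w * dose$values[idx[1], idx[2], idx[3]]
    }
    acc
  }, 0)
  stats::setNames(vals, points$id)
}

#' Compare simulated doses with point measurements
#'
#' Per probe: absolute and percentage error of the simulated dose against
#' the measured mean, and whether the simulation falls inside the
#' measurement's 2-sigma confidence interval.  The summary mean absolute
#' percentage error across probes is attached.
#'
#' @param simulated Named numeric vector of simulated doses, mGy (names are
#'   probe ids; see [sample_dose_at_points()]).
#' @param measured A `measurement_set` with matching ids.
#' @return A list of class `measurement_comparison` with elements `points`
#'   (data frame: `id, measured_mGy, sigma_mGy, simulated_mGy, abs_error_mGy,
#'   pct_error, within_2sigma`) and `mape` (mean absolute percentage error,
#'   %).
#' @export
compare_measurements <- function(simulated, measured) {
  stopifnot(inherits(measured, "measurement_set"))
  if (is.null(names(simulated)) ||
      !setequal(names(simulated), measured$id)) {
    stop("simulated doses must be named by the measured probe ids",
         call. = FALSE)
  }
  sim <- simulated[measured$id]
  abs_err <- abs(sim - measured$dose_mGy)
  pct_err <- abs_err / measured$dose_mGy * 100
  structure(list(
    points = data.frame(id = measured$id,
                        measured_mGy = measured$dose_mGy,
                        sigma_mGy = measured$sigma_mGy,
                        simulated_mGy = as.numeric(sim),
                        abs_error_mGy = as.numeric(abs_err),
                        pct_error = as.numeric(pct_err),
                        within_2sigma =
                          as.numeric(abs_err) <= 2 * measured$sigma_mGy,
                        stringsAsFactors = FALSE),
    mape = mean(pct_err)),
    class = "measurement_comparison")
}

#' @export
print.measurement_comparison <- function(x, ...) {
  cat(sprintf(
    "<measurement_comparison> %d points, mean |error| %.2f %%, %d/%d within 2 sigma\n",
    nrow(x$points), x$mape, sum(x$points$within_2sigma), nrow(x$points)))
  print(x$points, digits = 4)
  invisible(x)
}

#' Synthetic brain probe layout
#'
#' Places `n` probes on a regular axial grid restricted to brain voxels,
#' emulating the discrete sampling pattern of MOSFET probes inserted into
#' an anthropomorphic head phantom.  Positions are voxel centers.
#'
#' @param labels A [label_volume()].
#' @param n Number of probes requested.
#' @param organ_label Label to sample within (default brain, 4).
#' @return An `n x 3` matrix of world positions, mm (row names `p1..pn`).
#' @export
brain_probe_grid <- function(labels, n = 13, organ_label = 4L) {
  idx <- which(labels$values == organ_label)
  if (!length(idx)) stop("organ label not present", call. = FALSE)
  pick <- idx[round(seq(1, length(idx), length.out = n))]
  sub <- arrayInd(pick, dim(labels$values))
  pos <- sweep(sweep(sub - 0.5, 2, labels$spacing, `*`), 2, labels$origin,
               `+`)
  rownames(pos) <- paste0("p", seq_len(nrow(pos)))
  pos
}
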