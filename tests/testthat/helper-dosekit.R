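# shared fixtures and independent oracles, built in code at test time

# material with energy-independent coefficients; handy for analytic checks
flat_material <- function(name, density, mu_rho, muen_rho = mu_rho * 0.5,
                          f = c(photo = 1, compton = 0, rayleigh = 0)) {
  e <- c(5, 150)
  material(name, density, e, rep(mu_rho, 2), rep(muen_rho, 2),
           rep(f[1], 2), rep(f[2], 2), rep(f[3], 2))
}

# two-entry library: near-vacuum air plus one configurable absorber
slab_library <- function(mu_rho = 0.2059, muen_rho = 0.03,
                         density = 1,
                         f = c(photo = 1, compton = 0, rayleigh = 0)) {
  material_library(
    list(flat_material("air", 1.2e-3, 1e-4, 1e-4, f = c(1, 0, 0)),
         flat_material("absorber", density, mu_rho, muen_rho, f = f)),
    labels = c(0L, 1L))
}

# homogeneous slab of the absorber, centred on the origin
slab_volume <- function(nx = 20, ny = 40, nz = 5, spacing = c(4, 2, 5)) {
  label_volume(array(1L, c(nx, ny, nz)), spacing = spacing,
               origin = -c(nx, ny, nz) * spacing / 2)
}

delta_spectrum <- function(e_kev = 60) xray_spectrum(e_kev, 1)

pencil_setup <- function(spectrum = delta_spectrum(), opening = 0.2,
                         ...) {
  beam_setup(0, opening_phi = opening, opening_theta = opening,
             spectrum = spectrum, ...)
}

# brute-force guided filter: per-pixel windowed ridge regression over
# shrunken boxes, the direct O(n r^2) transcription of the definition
guided_filter_oracle <- function(guide, src, r, eps) {
  n <- nrow(guide); m <- ncol(guide)
  a <- matrix(0, n, m); b <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      wi <- max(1, i - r):min(n, i + r)
      wj <- max(1, j - r):min(m, j + r)
      g <- guide[wi, wj]; s <- src[wi, wj]
      mg <- mean(g); ms <- mean(s)
      vg <- mean(g * g) - mg^2
      cv <- mean(g * s) - mg * ms
      a[i, j] <- cv / (vg + eps)
      b[i, j] <- ms - a[i, j] * mg
    }
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      wi <- max(1, i - r):min(n, i + r)
      wj <- max(1, j - r):min(m, j + r)
      out[i, j] <- mean(a[wi, wj]) * guide[i, j] + mean(b[wi, wj])
    }
  }
  out
}

# independent reference transport: exact voxel-by-voxel ray marching with
# optical-depth sampling (no majorant / delta tracking), same physics
# (photoelectric, Kahn Klein-Nishina Compton, Thomson Rayleigh, 5 keV
# cutoff), driven by R's RNG
raymarch_transport <- function(labels, lib, setup, n_histories,
                               e_cutoff = 5) {
  d <- dim(labels$values)
  sp <- labels$spacing
  org <- labels$origin
  upper <- org + d * sp
  lut_names <- names(lib$labels)[match(sort(unique(as.integer(labels$values))),
                                       lib$labels)]
  present <- sort(unique(as.integer(labels$values)))
  mats <- lib$materials[lut_names]
  mu_of <- function(lab, e) {
    m <- mats[[match(lab, present)]]
    material_coefficient(m, e, "attenuation") * m$density / 10
  }
  frac_of <- function(lab, e) {
    m <- mats[[match(lab, present)]]
    c(material_coefficient(m, e, "f_photo"),
      material_coefficient(m, e, "f_compton"))
  }
  ax <- dosekit:::beam_axes(setup)
  src <- setup$isocenter - setup$sod * ax$e_c
  tphi <- tan(setup$opening_phi * pi / 180)
  tthe <- tan(setup$opening_theta * pi / 180)

  kahn_r <- function(e) {
    alpha <- e / 510.99895
    repeat {
      r <- stats::runif(3)
      if (r[1] <= (1 + 2 * alpha) / (9 + 2 * alpha)) {
        x <- 1 + 2 * alpha * r[2]
        if (r[3] <= 4 * (1 / x - 1 / x^2)) break
      } else {
        x <- (1 + 2 * alpha) / (1 + 2 * alpha * r[2])
        ct <- 1 - (x - 1) / alpha
        if (r[3] <= 0.5 * (ct^2 + 1 / x)) break
      }
    }
    c(e_out = e / x, cos_t = 1 - (x - 1) / alpha)
  }
  rotate_r <- function(dir, ct, phi) {
    st <- sqrt(max(0, 1 - ct^2))
    e1 <- if (abs(dir[3]) < 0.99) c(-dir[2], dir[1], 0) else
      c(0, -dir[3], dir[2])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
            dir[3] * e1[1] - dir[1] * e1[3],
            dir[1] * e1[2] - dir[2] * e1[1])
    nd <- st * (cos(phi) * e1 + sin(phi) * e2) + ct * dir
    nd / sqrt(sum(nd^2))
  }
  # advance to the grid entry along dir; NA if the ray misses
  entry_t <- function(pos, dir) {
    t0 <- 0; t1 <- Inf
    for (a in 1:3) {
      if (abs(dir[a]) < 1e-15) {
        if (pos[a] <= org[a] || pos[a] >= upper[a]) return(NA_real_)
      } else {
        tt <- sort(c((org[a] - pos[a]) / dir[a], (upper[a] - pos[a]) / dir[a]))
        t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
      }
    }
    if (t0 >= t1) NA_real_ else t0
  }

  energy <- array(0, d)
  deposited <- 0; emitted <- 0
  for (h in seq_len(n_histories)) {
    e <- sample_spectrum_energy(setup$spectrum, 1)
    emitted <- emitted + e
    u <- (2 * stats::runif(1) - 1) * tphi
    v <- (2 * stats::runif(1) - 1) * tthe
    dir <- ax$e_c + u * ax$e_u + v * ax$e_v
    dir <- dir / sqrt(sum(dir^2))
    pos <- src
    repeat {
      te <- entry_t(pos, dir)
      if (is.na(te)) break
      pos <- pos + (te + 1e-9) * dir
      tau_target <- -log(stats::runif(1))
      interacted <- FALSE
      # exact traversal: accumulate optical depth voxel by voxel
      repeat {
        idx <- floor((pos - org) / sp)
        if (any(idx < 0) || any(idx >= d)) break
        lab <- labels$values[idx[1] + 1, idx[2] + 1, idx[3] + 1]
        mu <- mu_of(lab, e)
        # distance to the next voxel face
        tstep <- Inf
        for (a in 1:3) {
          if (abs(dir[a]) > 1e-15) {
            edge <- org[a] + (idx[a] + (dir[a] > 0)) * sp[a]
            tstep <- min(tstep, (edge - pos[a]) / dir[a])
          }
        }
        tstep <- max(tstep, 1e-9)
        if (mu * tstep >= tau_target) {
          pos <- pos + (tau_target / mu) * dir
          interacted <- TRUE
          break
        }
        tau_target <- tau_target - mu * tstep
        pos <- pos + (tstep + 1e-9) * dir
      }
      if (!interacted) break
      idx <- pmin(pmax(floor((pos - org) / sp), 0), d - 1)
      vox <- idx + 1
      lab <- labels$values[vox[1], vox[2], vox[3]]
      fr <- frac_of(lab, e)
      un <- stats::runif(1)
      if (un < fr[1]) {
        energy[vox[1], vox[2], vox[3]] <-
          energy[vox[1], vox[2], vox[3]] + e
        deposited <- deposited + e
        break
      } else if (un < fr[1] + fr[2]) {
        kc <- kahn_r(e)
        dep <- e - kc["e_out"]
        energy[vox[1], vox[2], vox[3]] <-
          energy[vox[1], vox[2], vox[3]] + dep
        deposited <- deposited + dep
        dir <- rotate_r(dir, kc["cos_t"], 2 * pi * stats::runif(1))
        if (kc["e_out"] < e_cutoff) {
          energy[vox[1], vox[2], vox[3]] <-
            energy[vox[1], vox[2], vox[3]] + kc["e_out"]
          deposited <- deposited + kc["e_out"]
          break
        }
        e <- kc[["e_out"]]
      } else {
        repeat {
          ct <- 2 * stats::runif(1) - 1
          if (stats::runif(1) <= 0.5 * (1 + ct^2)) break
        }
        dir <- rotate_r(dir, ct, 2 * pi * stats::runif(1))
      }
    }
  }
  list(energy = energy, emitted = emitted, deposited = deposited)
}

# memoized acceptance-scale benchmark shared by the acceptance test blocks
acceptance_cache <- new.env(parent = emptyenv())
acceptance_benchmark <- function() {
  if (is.null(acceptance_cache$bench)) {
    acceptance_cache$bench <- benchmark_reconstruction(seed = 1)
  }
  acceptance_cache$bench
}
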