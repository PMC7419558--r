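#' Acquisition geometry for a DBT arc
#'
#' Rotating-source, stationary-detector tomosynthesis layout. The detector
#' lies in the z = 0 plane; the source swings on an arc of `arc_span_deg`
#' about a rotation centre `scd_mm` below it along the source axis, with
#' projection angles equally spaced and symmetric about the detector
#' normal. The per-view exposure is `total_dose_mGy / n_projections`.
#'
#' @param n_projections number of equally spaced projections P (>= 1).
#' @param arc_span_deg angular span of the arc in degrees (default 60).
#' @param sdd_mm source-to-detector distance at the central view (default
#'   650; the source arc radius is `scd_mm`).
#' @param scd_mm source-to-rotation-centre distance (default 600).
#' @param pitch_mm detector pixel pitch in mm (scalar or length 2).
#' @param det_shape detector size in pixels, `c(nu, nv)`.
#' @param det_origin_mm world (x, y) of the centre of detector pixel (0, 0).
#' @param rot_center_mm world (x, y) of the rotation centre axis (its z is
#'   `sdd_mm - scd_mm`).
#' @param total_dose_mGy total dose split evenly across views (default 1.5).
#' @return An `acquisition_geometry` list.
#' @export
acquisition_geometry <- function(n_projections, arc_span_deg = 60,
                                 sdd_mm = 650, scd_mm = 600,
                                 pitch_mm = 0.27, det_shape = c(256, 256),
                                 det_origin_mm = NULL,
                                 rot_center_mm = NULL,
                                 total_dose_mGy = 1.5) {
  n_projections <- as.integer(n_projections)
  .assert(length(n_projections) == 1 && n_projections >= 1,
          "n_projections must be an integer >= 1")
  .assert(total_dose_mGy > 0, "total_dose_mGy must be > 0")
  .assert(scd_mm < sdd_mm, "rotation centre must sit above the detector")
  pitch_mm <- rep(pitch_mm, length.out = 2)
  det_shape <- as.integer(det_shape)
  if (is.null(rot_center_mm)) {
    rot_center_mm <- c((det_shape[1] - 1) * pitch_mm[1] / 2,
                       (det_shape[2] - 1) * pitch_mm[2] / 2)
  }
  if (is.null(det_origin_mm)) {
    det_origin_mm <- c(rot_center_mm[1] - (det_shape[1] - 1) * pitch_mm[1] / 2,
                       rot_center_mm[2] - (det_shape[2] - 1) * pitch_mm[2] / 2)
  }
  structure(list(n_projections = n_projections,
                 arc_span_deg = arc_span_deg,
                 sdd_mm = sdd_mm, scd_mm = scd_mm,
                 pitch_mm = pitch_mm, det_shape = det_shape,
                 det_origin_mm = det_origin_mm,
                 rot_center_mm = rot_center_mm,
                 total_dose_mGy = total_dose_mGy),
            class = "acquisition_geometry")
}

#' Geometry sized to a phantom's footprint
#'
#' Places the phantom just above the detector (1 mm air gap), centred under
#' the rotation axis, and sizes the detector so the magnified footprint of
#' the phantom stays on it at every view angle.
#'
#' @param phantom a `breast_phantom`.
#' @param n_projections number of views.
#' @param pitch_mm detector pixel pitch.
#' @param margin multiplicative footprint margin (default 1.35).
#' @inheritParams acquisition_geometry
#' @return List with `geometry` (an `acquisition_geometry`) and
#'   `phantom_origin_mm` (world corner of voxel (0,0,0)).
#' @export
default_geometry <- function(phantom, n_projections, arc_span_deg = 60,
                             pitch_mm = 0.27, sdd_mm = 650, scd_mm = 600,
                             total_dose_mGy = 1.5, margin = 1.35) {
  d <- dim(phantom$labels)
  vs <- phantom$voxel_size
  ext <- d * vs
  nu <- as.integer(ceiling(ext[1] * margin / pitch_mm))
  nv <- as.integer(ceiling(ext[2] * margin / pitch_mm))
  geom <- acquisition_geometry(n_projections, arc_span_deg, sdd_mm, scd_mm,
                               pitch_mm, c(nu, nv),
                               total_dose_mGy = total_dose_mGy)
  org <- c(geom$rot_center_mm[1] - ext[1] / 2,
           geom$rot_center_mm[2] - ext[2] / 2,
           1.0)
  list(geometry = geom, phantom_origin_mm = org)
}

#' Source positions for every view
#'
#' @param geometry an `acquisition_geometry`.
#' @return `P x 3` matrix of world source positions (mm). Views are ordered
#'   from `-arc/2` to `+arc/2`; a single view sits on the detector normal.
#' @export
source_positions <- function(geometry) {
  P <- geometry$n_projections
  half <- geometry$arc_span_deg / 2
  ang <- if (P == 1) 0 else seq(-half, half, length.out = P)
  th <- ang * pi / 180
  zc <- geometry$sdd_mm - geometry$scd_mm
  cbind(geometry$rot_center_mm[1] + geometry$scd_mm * sin(th),
        rep(geometry$rot_center_mm[2], P),
        zc + geometry$scd_mm * cos(th))
}

#' Per-view exposure under an even dose split
#'
#' @param total_dose total dose in mGy (> 0).
#' @param P number of projections (>= 1).
#' @return `total_dose / P` in mGy.
#' @export
per_view_exposure <- function(total_dose, P) {
  .assert(is.numeric(total_dose) && total_dose > 0, "total_dose must be > 0")
  .assert(is.numeric(P) && P >= 1 && P == as.integer(P),
          "P must be an integer >= 1")
  total_dose / P
}

#' Monoenergetic spectrum helper
#'
#' @param energy_keV single energy.
#' @return Spectrum data frame with columns `energy_keV`, `weight`.
#' @export
mono_spectrum <- function(energy_keV = 20) {
  data.frame(energy_keV = energy_keV, weight = 1)
}

#' Read a spectrum CSV (`energy_keV`, `weight`)
#' @param path file path.
#' @return Spectrum data frame.
#' @export
read_spectrum <- function(path) {
  sp <- utils::read.csv(path)
  .assert(all(c("energy_keV", "weight") %in% names(sp)),
          "spectrum needs columns energy_keV, weight")
  sp
}

# Nominal detector-entrance fluence: photons per detector pixel per mGy at
# the reference geometry. Only relative noise across P matters downstream;
# this constant sets the absolute quantum noise floor.
.PHOTONS_PER_PIXEL_PER_MGY <- 2000

#' Siddon ray trace through a voxel grid
#'
#' Exact radiological path of a ray through an axis-aligned voxel grid.
#' Voxels follow a half-open convention with the (0,0,0) corner at the grid
#' origin; rays tangent to a voxel face are assigned to the lower-index
#' voxel.
#'
#' @param src,dst world endpoints of the ray (mm), length-3 vectors. The
#'   segment is traced from `src` to `dst`; portions outside the grid are
#'   clipped.
#' @param origin world corner of voxel (1,1,1) (mm).
#' @param voxel voxel size per axis (mm), length 3.
#' @param dims voxel counts per axis.
#' @return List with `idx` (m x 3 matrix of 1-based voxel indices, ordered
#'   along the ray) and `len` (positive intersection lengths, mm). Rays
#'   missing the grid return zero rows.
#' @export
siddon_trace <- function(src, dst, origin, voxel, dims) {
  .assert(length(src) == 3 && length(dst) == 3, "ray endpoints must be 3D")
  .assert(sum((dst - src)^2) > 0, "zero-length ray")
  siddon_trace_cpp(as.numeric(src), as.numeric(dst), as.numeric(origin),
                   as.numeric(voxel), as.integer(dims))
}

#' Noiseless projection of a phantom
#'
#' Beer-Lambert line integrals through the voxelized phantom for every
#' detector pixel and view. With an energy grid `E` of normalized weights
#' `w`, the expected pixel count is
#' `I0 * sum_E w(E) * exp(-sum_m mu(m, E) * L_m)` where `L_m` is the Siddon
#' path length through material `m`. Air-only rays give the unattenuated
#' per-view reference `I0 = fluence_per_mGy * total_dose / P`.
#'
#' @param phantom a `breast_phantom`.
#' @param geometry an `acquisition_geometry`.
#' @param materials a `material_table`.
#' @param spectrum data frame (`energy_keV`, `weight`); weights are
#'   normalized internally. Default monoenergetic 20 keV.
#' @param phantom_origin_mm world corner of the phantom grid; default from
#'   [default_geometry()] placement.
#' @param fluence_per_mGy photons per pixel per mGy (documented nominal
#'   constant by default).
#' @return A `projection_set`: list with `images` (list of P nu-x-nv count
#'   matrices), `I0`, `per_energy` (per-view pixel-by-energy matrices when
#'   the spectrum is polychromatic, else NULL), `energies`, `weights`,
#'   `geometry`, `phantom_origin_mm`, `noise_meta` (NULL until
#'   [apply_detector()]).
#' @export
project_noiseless <- function(phantom, geometry, materials = default_material_table(),
                              spectrum = mono_spectrum(),
                              phantom_origin_mm = NULL,
                              fluence_per_mGy = .PHOTONS_PER_PIXEL_PER_MGY) {
  .assert(all(spectrum$weight >= 0) && any(spectrum$weight > 0),
          "spectrum weights must be nonnegative with at least one positive")
  if (is.null(phantom_origin_mm)) {
    phantom_origin_mm <- default_geometry(
      phantom, geometry$n_projections)$phantom_origin_mm
  }
  w <- spectrum$weight / sum(spectrum$weight)
  energies <- spectrum$energy_keV
  mu <- mu_matrix(materials, energies)            # [6 x nE]
  nE <- length(energies)

  dims <- dim(phantom$labels)
  vs <- rep(phantom$voxel_size, 3)
  nu <- geometry$det_shape[1]; nv <- geometry$det_shape[2]
  du <- geometry$pitch_mm[1];  dv <- geometry$pitch_mm[2]
  det_pts <- cbind(
    rep(geometry$det_origin_mm[1] + (seq_len(nu) - 1) * du, times = nv),
    rep(geometry$det_origin_mm[2] + (seq_len(nv) - 1) * dv, each = nu),
    0)
  srcs <- source_positions(geometry)
  I0 <- fluence_per_mGy *
    per_view_exposure(geometry$total_dose_mGy, geometry$n_projections)

  images <- vector("list", geometry$n_projections)
  per_energy <- if (nE > 1) vector("list", geometry$n_projections) else NULL
  for (v in seq_len(geometry$n_projections)) {
    L <- forward_paths_cpp(phantom$labels, as.integer(dims),
                           as.numeric(phantom_origin_mm), vs,
                           as.numeric(srcs[v, ]), det_pts,
                           length(.MATERIALS))
    att <- exp(-L %*% mu)                          # [npix x nE]
    cnts <- sweep(att, 2, I0 * w, `*`)
    if (nE > 1) per_energy[[v]] <- cnts
    images[[v]] <- matrix(rowSums(cnts), nrow = nu, ncol = nv)
  }
  structure(list(images = images, I0 = I0, per_energy = per_energy,
                 energies = energies, weights = w,
                 geometry = geometry, phantom_origin_mm = phantom_origin_mm,
                 noise_meta = NULL),
            class = "projection_set")
}

# separable Gaussian blur with reflection padding; sigma in pixels
.gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    pad <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      out <- out + k[o + r + 1] * pad[(1 + r + o):(n + r + o), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

#' Detector cascade: Poisson quanta, blur, gain and electronic noise
#'
#' Applies, per view: Poisson sampling of the expected quanta (per energy
#' bin when the spectrum is polychromatic), a Gaussian blur of the given
#' FWHM combining focal-spot and scintillator blur, a multiplicative gain,
#' and additive zero-mean Gaussian electronic noise. With Poisson sampling
#' disabled and zero blur/noise the output is exactly `gain * input`.
#'
#' @param pset a noiseless `projection_set`.
#' @param blur_fwhm_mm blur FWHM in mm (>= 0, 0 disables).
#' @param gain multiplicative detector gain (> 0).
#' @param electronic_sd additive Gaussian SD in output counts (>= 0).
#' @param seed integer RNG seed.
#' @param poisson logical; sample quantum noise (default TRUE).
#' @return A `projection_set` with noisy `images` and `noise_meta` filled
#'   in; `noiseless` keeps the input images.
#' @export
apply_detector <- function(pset, blur_fwhm_mm = 0, gain = 1,
                           electronic_sd = 0, seed = 1, poisson = TRUE) {
  .assert(gain > 0, "gain must be > 0")
  .assert(blur_fwhm_mm >= 0, "blur_fwhm_mm must be >= 0")
  .assert(electronic_sd >= 0, "electronic_sd must be >= 0")
  for (img in pset$images) {
    .assert(all(img >= 0), "noiseless projections must be nonnegative")
  }
  set.seed(as.integer(seed))
  sigma_px <- blur_fwhm_mm / 2.3548 / mean(pset$geometry$pitch_mm)
  out <- pset
  out$noiseless <- pset$images
  for (v in seq_along(pset$images)) {
    nu <- nrow(pset$images[[v]]); nv <- ncol(pset$images[[v]])
    if (poisson) {
      if (!is.null(pset$per_energy)) {
        q <- rowSums(matrix(
          rpois(length(pset$per_energy[[v]]), pset$per_energy[[v]]),
          nrow = nu * nv))
        q <- matrix(q, nu, nv)
      } else {
        q <- matrix(rpois(nu * nv, pset$images[[v]]), nu, nv)
      }
    } else {
      q <- pset$images[[v]]
    }
    q <- .gauss_blur(q, sigma_px) * gain
    if (electronic_sd > 0) q <- q + matrix(rnorm(nu * nv, 0, electronic_sd),
                                           nu, nv)
    out$images[[v]] <- q
  }
  out$noise_meta <- list(blur_fwhm_mm = blur_fwhm_mm, gain = gain,
                         electronic_sd = electronic_sd, seed = as.integer(seed),
                         poisson = poisson)
  out$I0 <- pset$I0 * gain
  out
}
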