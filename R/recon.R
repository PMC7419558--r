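#' Reconstruction grid specification
#'
#' @param origin world corner of voxel (1,1,1), mm.
#' @param voxel voxel size per axis, mm (default in-plane 0.27, slices 0.2
#'   to preserve lesion-depth bookkeeping before slabbing).
#' @param dims voxel counts per axis.
#' @return A `recon_grid` list.
#' @export
recon_grid <- function(origin, voxel = c(0.27, 0.27, 0.2), dims) {
  .assert(length(origin) == 3 && length(voxel) == 3 && length(dims) == 3,
          "origin, voxel and dims must all have length 3")
  .assert(all(voxel > 0) && all(dims >= 1), "invalid recon grid")
  structure(list(origin = as.numeric(origin), voxel = as.numeric(voxel),
                 dims = as.integer(dims)),
            class = "recon_grid")
}

#' Default reconstruction grid covering a phantom
#'
#' @param phantom a `breast_phantom`.
#' @param phantom_origin_mm world corner of the phantom grid.
#' @param in_plane in-plane pixel size, mm (default 0.27).
#' @param slice slice spacing, mm (default 0.2).
#' @return A [recon_grid()].
#' @export
default_recon_grid <- function(phantom, phantom_origin_mm,
                               in_plane = 0.27, slice = 0.2) {
  ext <- dim(phantom$labels) * phantom$voxel_size
  recon_grid(origin = phantom_origin_mm,
             voxel = c(in_plane, in_plane, slice),
             dims = c(ceiling(ext[1] / in_plane), ceiling(ext[2] / in_plane),
                      ceiling(ext[3] / slice)))
}

# ramp filter applied along the source-motion (u) axis of one projection
.ramp_filter <- function(proj) {
  nu <- nrow(proj)
  nfft <- 2^ceiling(log2(2 * nu))
  pad <- matrix(0, nfft, ncol(proj))
  pad[seq_len(nu), ] <- proj
  f <- c(seq(0, nfft / 2), seq(nfft / 2 - 1, 1)) / nfft
  Fp <- mvfft(pad) * f
  Re(mvfft(Fp, inverse = TRUE) / nfft)[seq_len(nu), , drop = FALSE]
}

#' Feldkamp-style filtered back projection
#'
#' Converts each projection to air-normalized line integrals
#' `-log(I / I0)` using the projector's known unattenuated reference, ramp
#' filters along the source-motion axis, and back projects over the views
#' with 1/P weighting onto the requested grid. Deterministic given its
#' inputs.
#'
#' @param pset a `projection_set` (noisy or noiseless).
#' @param grid a [recon_grid()].
#' @param line_integrals logical; if TRUE, `pset$images` already hold line
#'   integrals and log conversion is skipped.
#' @param min_counts photon-starvation floor applied before the log
#'   (default 0.5 counts): a detector pixel cannot inform attenuation
#'   beyond its noise floor, and electronic noise can push raw values to
#'   or below zero. The floor also guards the noiseless path via
#'   `I0 * 1e-12`.
#' @return A `recon_volume`: list with `voxels` (3D array), `grid`,
#'   `geometry`, `provenance`.
#' @export
fbp_reconstruct <- function(pset, grid, line_integrals = FALSE,
                            min_counts = 0.5) {
  geom <- pset$geometry
  P <- geom$n_projections
  .assert(P >= 1, "need at least one projection")
  if (!line_integrals) {
    .assert(!is.null(pset$I0) && is.finite(pset$I0) && pset$I0 > 0,
            "missing air reference value I0 for normalization")
  }
  eps <- if (line_integrals) NA else max(min_counts, pset$I0 * 1e-12)
  proj <- array(0, dim = c(geom$det_shape[1], geom$det_shape[2], P))
  for (v in seq_len(P)) {
    li <- if (line_integrals) pset$images[[v]]
          else -log(pmax(pset$images[[v]], eps) / pset$I0)
    proj[, , v] <- .ramp_filter(li)
  }
  vol <- backproject_cpp(proj, dim(proj), source_positions(geom),
                         as.numeric(geom$det_origin_mm),
                         as.numeric(geom$pitch_mm),
                         grid$origin, grid$voxel, grid$dims)
  structure(list(voxels = vol, grid = grid, geometry = geom,
                 provenance = list(noise_meta = pset$noise_meta,
                                   phantom_origin_mm = pset$phantom_origin_mm)),
            class = "recon_volume")
}

#' 3D Butterworth low-pass apodization
#'
#' Frequency-domain gain `1 / sqrt(1 + (f / cutoff)^(2 * order))` applied
#' isotropically in cycles/pixel (radial frequency pooled over the three
#' axes in per-sample units). DC is preserved exactly; the gain at the
#' cutoff is `1/sqrt(2)`.
#'
#' @param volume a `recon_volume` (or plain 3D array).
#' @param cutoff cutoff frequency in cycles/pixel, in (0, 0.5] (default
#'   0.25).
#' @param order filter order (default 4; larger is sharper).
#' @return Object of the same type with filtered voxels.
#' @export
butterworth3d <- function(volume, cutoff = 0.25, order = 4L) {
  .assert(cutoff > 0 && cutoff <= 0.5, "cutoff must lie in (0, 0.5]")
  arr <- if (inherits(volume, "recon_volume")) volume$voxels else volume
  d <- dim(arr)
  fax <- function(n) {
    f <- (seq_len(n) - 1) / n
    pmin(f, 1 - f)
  }
  fx <- fax(d[1]); fy <- fax(d[2]); fz <- fax(d[3])
  f2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  gain <- 1 / sqrt(1 + (sqrt(f2) / cutoff)^(2 * order))
  out <- Re(fft(fft(arr) * gain, inverse = TRUE)) / prod(d)
  if (inherits(volume, "recon_volume")) {
    volume$voxels <- out
    volume$provenance$butterworth <- list(cutoff = cutoff, order = order)
    volume
  } else {
    out
  }
}

#' Extract thin display slabs from a reconstructed volume
#'
#' Contiguous, non-overlapping groups of slices are reduced (mean by
#' default, maximum-intensity optionally) into `floor(depth / thickness)`
#' slabs. Ground-truth lesion metadata is attached to the slab whose depth
#' interval contains the lesion centre.
#'
#' @param volume a `recon_volume`.
#' @param thickness slab thickness in mm (default 1).
#' @param method `"mean"` (default) or `"max"`.
#' @param mask optional 2D breast mask to attach to every slab.
#' @param lesion optional list with `center_mm` (world x, y, z) and
#'   `diameter_mm` describing the inserted lesion.
#' @param condition optional condition descriptor attached to every slab.
#' @return List of `slab_image` objects: `pixels`, `pixel_size`, `mask`,
#'   `truth` (list `present`, `center_px`, `diameter_mm`), `condition`,
#'   `slab_index` (0-based from the detector side).
#' @export
slab_volume <- function(volume, thickness = 1, method = c("mean", "max"),
                        mask = NULL, lesion = NULL, condition = NULL) {
  .assert(thickness > 0, "thickness must be > 0")
  method <- match.arg(method)
  d <- dim(volume$voxels)
  dz <- volume$grid$voxel[3]
  depth <- d[3] * dz
  .assert(depth >= thickness, "volume thinner than one slab")
  n_slabs <- floor(depth / thickness)
  per <- thickness / dz
  .assert(abs(per - round(per)) < 1e-6,
          "slab thickness must be a multiple of the slice spacing")
  per <- as.integer(round(per))

  lesion_slab <- -1L
  truth_center_px <- NULL
  if (!is.null(lesion)) {
    zrel <- lesion$center_mm[3] - volume$grid$origin[3]
    lesion_slab <- as.integer(floor(zrel / thickness))
    truth_center_px <- c(
      (lesion$center_mm[1] - volume$grid$origin[1]) / volume$grid$voxel[1] + 0.5,
      (lesion$center_mm[2] - volume$grid$origin[2]) / volume$grid$voxel[2] + 0.5)
  }

  out <- vector("list", n_slabs)
  for (s in seq_len(n_slabs)) {
    sl <- volume$voxels[, , ((s - 1L) * per + 1L):(s * per), drop = FALSE]
    px <- if (method == "mean") {
      apply(sl, c(1, 2), mean)
    } else {
      apply(sl, c(1, 2), max)
    }
    present <- (s - 1L) == lesion_slab
    out[[s]] <- structure(
      list(pixels = px,
           pixel_size = volume$grid$voxel[1:2],
           mask = mask,
           truth = list(present = present,
                        center_px = if (present) truth_center_px else NULL,
                        diameter_mm = if (present) lesion$diameter_mm else NULL),
           condition = condition,
           slab_index = s - 1L),
      class = "slab_image")
  }
  out
}

#' Breast support mask on a reconstruction grid
#'
#' Geometric mask from the phantom support itself (not image thresholding):
#' a recon pixel is inside the breast iff its (x, y) centre falls over a
#' phantom column containing any non-air voxel.
#'
#' @param phantom a `breast_phantom`.
#' @param grid a [recon_grid()].
#' @param phantom_origin_mm world corner of the phantom grid.
#' @return Logical matrix `dims[1] x dims[2]`.
#' @export
build_breast_mask <- function(phantom, grid, phantom_origin_mm) {
  foot <- apply(phantom$labels != .MATERIALS[["air"]], c(1, 2), any)
  .assert(any(foot), "phantom has empty support")
  vs <- phantom$voxel_size
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$voxel[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$voxel[2]
  ii <- floor((xs - phantom_origin_mm[1]) / vs) + 1
  jj <- floor((ys - phantom_origin_mm[2]) / vs) + 1
  ok_i <- ii >= 1 & ii <= nrow(foot)
  ok_j <- jj >= 1 & jj <= ncol(foot)
  mask <- matrix(FALSE, grid$dims[1], grid$dims[2])
  mask[ok_i, ok_j] <- foot[ii[ok_i], jj[ok_j]]
  .assert(any(mask), "empty breast mask on this grid")
  mask
}
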