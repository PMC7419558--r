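#' Generate a voxelized compressed-breast phantom
#'
#' Builds a procedural stand-in for an anthropomorphic compressed breast:
#' a 50-mm-thick slab (at the default 0.2 mm voxels) whose in-plane support
#' is a half-elliptical compressed-breast outline with the chest wall on the
#' low-x face, wrapped in a one-voxel skin rind. The interior is partitioned
#' into Voronoi compartments around seeded random sites; thin ligament
#' sheets are carved on compartment boundaries and whole compartments are
#' assigned to adipose or fibroglandular tissue so that the realized
#' volumetric glandular fraction (VGF) lands close to `vgf_target`.
#'
#' The generator aims for structural variability across seeds, not for
#' anatomical fidelity of any particular growth model.
#'
#' @param vgf_target target volumetric glandular fraction, in (0, 1).
#' @param grid_shape integer vector `c(nx, ny, nz)` of voxel counts; `nz`
#'   spans the compression axis.
#' @param seed integer RNG seed; fixed seed gives a bit-identical phantom.
#' @param voxel_size isotropic voxel edge in mm (default 0.2).
#' @param n_compartments number of Voronoi compartments; default scales with
#'   interior volume at one compartment per `target_compartment_mm3`.
#' @param target_compartment_mm3 characteristic compartment volume in mm^3
#'   used when `n_compartments` is NULL (default 512, an 8 mm cube).
#' @return A `breast_phantom`: list with `labels` (3D integer array coded
#'   air=0, adipose=1, fibroglandular=2, ligament=3, skin=4, lesion=5),
#'   `voxel_size`, `thickness_mm`, `vgf_target`, `vgf_realized`, `lesion`
#'   (NULL until [insert_lesion()]), and `seed`.
#' @export
generate_phantom <- function(vgf_target, grid_shape, seed,
                             voxel_size = 0.2, n_compartments = NULL,
                             target_compartment_mm3 = 512) {
  .assert(is.numeric(vgf_target) && length(vgf_target) == 1 &&
            vgf_target > 0 && vgf_target < 1,
          "vgf_target must lie in (0, 1)")
  grid_shape <- as.integer(grid_shape)
  .assert(length(grid_shape) == 3 && all(grid_shape >= 8),
          "grid_shape must be c(nx, ny, nz) with every dim >= 8 (skin + interior)")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]

  set.seed(as.integer(seed))

  # in-plane support: half ellipse, flat chest wall at the low-x face
  xs <- seq_len(nx) - 0.5
  ys <- seq_len(ny) - 0.5
  cy <- ny / 2
  rx <- nx - 0.5
  ry <- ny / 2 - 0.5
  supp2d <- outer(xs, ys, function(x, y) (x / rx)^2 + ((y - cy) / ry)^2 <= 1)
  .assert(sum(supp2d) > 0, "degenerate in-plane support")
  support <- array(rep(supp2d, nz), dim = c(nx, ny, nz))

  # skin: support voxels adjacent (6-neighborhood) to non-support or to the
  # top/bottom compression faces
  skin <- support & !.erode6(support)
  interior <- support & !skin
  .assert(sum(interior) > 0,
          "grid too small to contain skin plus interior tissue")

  idx_int <- which(interior)
  n_int <- length(idx_int)
  if (is.null(n_compartments)) {
    vol_mm3 <- n_int * voxel_size^3
    n_compartments <- max(8L, as.integer(round(vol_mm3 / target_compartment_mm3)))
  }
  n_compartments <- min(n_compartments, n_int)

  coords <- arrayInd(idx_int, dim(interior))
  sites <- coords[sample.int(n_int, n_compartments), , drop = FALSE]

  # nearest-site labelling (squared Euclidean in voxel units)
  comp <- integer(n_int)
  best <- rep(Inf, n_int)
  cx <- coords[, 1]; cyv <- coords[, 2]; cz <- coords[, 3]
  for (s in seq_len(n_compartments)) {
    d2 <- (cx - sites[s, 1])^2 + (cyv - sites[s, 2])^2 + (cz - sites[s, 3])^2
    hit <- d2 < best
    comp[hit] <- s
    best[hit] <- d2[hit]
  }
  comp_arr <- array(NA_integer_, dim = c(nx, ny, nz))
  comp_arr[idx_int] <- comp

  # ligament sheets: one-voxel layer on the low-index side of every
  # compartment boundary
  lig <- array(FALSE, dim = c(nx, ny, nz))
  d <- dim(comp_arr)
  a <- comp_arr[-d[1], , , drop = FALSE]; b <- comp_arr[-1, , , drop = FALSE]
  m <- !is.na(a) & !is.na(b) & a != b
  lig[-d[1], , ][m] <- TRUE
  a <- comp_arr[, -d[2], , drop = FALSE]; b <- comp_arr[, -1, , drop = FALSE]
  m <- !is.na(a) & !is.na(b) & a != b
  lig[, -d[2], ][m] <- TRUE
  a <- comp_arr[, , -d[3], drop = FALSE]; b <- comp_arr[, , -1, drop = FALSE]
  m <- !is.na(a) & !is.na(b) & a != b
  lig[, , -d[3]][m] <- TRUE
  lig <- lig & interior

  # greedy whole-compartment assignment toward the target glandular count;
  # the VGF denominator includes ligament voxels, so target against n_int
  comp_of_nonlig <- comp_arr[interior & !lig]
  sizes <- tabulate(comp_of_nonlig, nbins = n_compartments)
  target_fib <- vgf_target * n_int
  order_c <- sample.int(n_compartments)
  fib_comps <- logical(n_compartments)
  acc <- 0
  for (s in order_c) {
    if (abs(acc + sizes[s] - target_fib) < abs(acc - target_fib)) {
      fib_comps[s] <- TRUE
      acc <- acc + sizes[s]
    }
  }

  labels <- array(.MATERIALS[["air"]], dim = c(nx, ny, nz))
  labels[skin] <- .MATERIALS[["skin"]]
  fib_mask <- interior & !lig & array(fib_comps[comp_arr], dim = dim(comp_arr))
  fib_mask[is.na(fib_mask)] <- FALSE
  labels[interior] <- .MATERIALS[["adipose"]]
  labels[fib_mask] <- .MATERIALS[["fibroglandular"]]
  labels[lig] <- .MATERIALS[["ligament"]]
  storage.mode(labels) <- "integer"

  ph <- structure(list(labels = labels,
                       voxel_size = voxel_size,
                       thickness_mm = nz * voxel_size,
                       vgf_target = vgf_target,
                       vgf_realized = NA_real_,
                       lesion = NULL,
                       seed = as.integer(seed)),
                  class = "breast_phantom")
  ph$vgf_realized <- measure_vgf(ph)
  ph
}

# interior of a 3D logical mask under 6-connectivity, treating the array
# border as background
.erode6 <- function(m) {
  d <- dim(m)
  out <- m
  pad <- function(shift_axis, dir) {
    r <- array(FALSE, d)
    if (shift_axis == 1) {
      if (dir > 0) r[-d[1], , ] <- m[-1, , ] else r[-1, , ] <- m[-d[1], , ]
    } else if (shift_axis == 2) {
      if (dir > 0) r[, -d[2], ] <- m[, -1, ] else r[, -1, ] <- m[, -d[2], ]
    } else {
      if (dir > 0) r[, , -d[3]] <- m[, , -1] else r[, , -1] <- m[, , -d[3]]
    }
    r
  }
  for (ax in 1:3) for (dir in c(-1, 1)) out <- out & pad(ax, dir)
  out
}

#' Measure the realized volumetric glandular fraction
#'
#' Fibroglandular voxel count divided by the total interior tissue voxel
#' count (adipose + fibroglandular + ligament); lesion and skin voxels are
#' excluded from both numerator and denominator.
#'
#' @param phantom a `breast_phantom`.
#' @return Fraction in \[0, 1\].
#' @export
measure_vgf <- function(phantom) {
  lab <- phantom$labels
  n_fib <- sum(lab == .MATERIALS[["fibroglandular"]])
  n_den <- n_fib + sum(lab == .MATERIALS[["adipose"]]) +
    sum(lab == .MATERIALS[["ligament"]])
  .assert(n_den > 0, "phantom has no interior tissue voxels")
  n_fib / n_den
}

#' Insert a spherical lesion into fibroglandular tissue
#'
#' Picks (seeded, uniformly among feasible candidates) a fibroglandular
#' voxel at the requested depth whose surrounding sphere fits entirely
#' inside interior tissue, and relabels all voxels within `diameter/2` of
#' its centre as lesion. Background tissue is removed, not blended. Depth is
#' measured along the compression axis from the detector-side surface
#' (low z).
#'
#' @param phantom a `breast_phantom` without prior lesion at the target
#'   location.
#' @param diameter lesion diameter in mm (must be > 0).
#' @param depth centre depth in mm from the detector-side surface.
#' @param seed integer RNG seed for the centre choice.
#' @param max_candidates number of candidate centres examined before giving
#'   up with a placement error.
#' @return The phantom with lesion voxels relabelled and a `lesion` record
#'   (`center` voxel index, `diameter_mm`, `depth_mm`).
#' @export
insert_lesion <- function(phantom, diameter, depth, seed,
                          max_candidates = 500L) {
  .assert(is.numeric(diameter) && diameter > 0,
          "lesion diameter must be > 0 mm")
  vs <- phantom$voxel_size
  lab <- phantom$labels
  d <- dim(lab)
  kc <- as.integer(floor(depth / vs)) + 1L
  .assert(kc >= 1 && kc <= d[3], "depth outside the phantom thickness")

  r_vox <- (diameter / 2) / vs
  interior_codes <- .MATERIALS[c("adipose", "fibroglandular", "ligament")]

  slice <- lab[, , kc]
  cand <- which(slice == .MATERIALS[["fibroglandular"]], arr.ind = TRUE)
  .assert(nrow(cand) > 0,
          "no fibroglandular tissue at the requested depth")

  set.seed(as.integer(seed))
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  n_try <- min(nrow(cand), max_candidates)

  rr <- ceiling(r_vox)
  off <- expand.grid(i = -rr:rr, j = -rr:rr, k = -rr:rr)
  keep <- sqrt(off$i^2 + off$j^2 + off$k^2) <= r_vox
  off <- as.matrix(off[keep, , drop = FALSE])

  for (t in seq_len(n_try)) {
    ci <- cand[t, 1]; cj <- cand[t, 2]
    pts <- cbind(off[, 1] + ci, off[, 2] + cj, off[, 3] + kc)
    if (any(pts[, 1] < 1 | pts[, 1] > d[1] |
            pts[, 2] < 1 | pts[, 2] > d[2] |
            pts[, 3] < 1 | pts[, 3] > d[3])) next
    vals <- lab[pts]
    if (all(vals %in% interior_codes)) {
      lab[pts] <- .MATERIALS[["lesion"]]
      phantom$labels <- lab
      phantom$lesion <- list(center = c(ci, cj, kc),
                             diameter_mm = diameter, depth_mm = depth,
                             seed = as.integer(seed))
      return(phantom)
    }
  }
  stop("no feasible lesion centre at this depth; retry with another seed or depth",
       call. = FALSE)
}

#' @export
print.breast_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("breast_phantom: %d x %d x %d voxels @ %.3g mm (%.1f mm thick)\n",
              d[1], d[2], d[3], x$voxel_size, x$thickness_mm))
  cat(sprintf("  VGF target %.3f, realized %.3f\n",
              x$vgf_target, x$vgf_realized))
  if (!is.null(x$lesion)) {
    cat(sprintf("  lesion: %.1f mm at voxel (%d, %d, %d)\n",
                x$lesion$diameter_mm, x$lesion$center[1],
                x$lesion$center[2], x$lesion$center[3]))
  }
  invisible(x)
}
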