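#' Study configuration
#'
#' Defaults reproduce the full observer-study design: 6 phantoms (half at
#' 25% VGF, half at 50%), 8 lesion-present variants plus one lesion-free
#' run each, 12 projection numbers over a 60 degree arc at 1.5 mGy total
#' dose, and both filter arms.
#'
#' @param n_phantoms number of phantoms (default 6).
#' @param vgfs per-phantom glandular fractions (default half 0.25, half
#'   0.5).
#' @param n_variants lesion-present variants per phantom (default 8); the
#'   lesion-free run contributes the same number of absent slabs at
#'   matched depths.
#' @param P_list projection numbers (default the 12 study values).
#' @param arc_span_deg arc span (default 60).
#' @param total_dose_mGy total dose (default 1.5).
#' @param arms filter arms as logical vector (default unfiltered and
#'   filtered).
#' @param observer_P projection numbers used in observer sessions (default
#'   3, 7, 11, 25, 45).
#' @param texture list of texture settings (`levels`, `roi_side`, `d`,
#'   `n`).
#' @param observer list of observer settings (`n_train`, `n_test`,
#'   `loc_radius_px`, `loc_error_scale`).
#' @param seed base seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_phantoms = 6L,
                         vgfs = rep(c(0.25, 0.5), each = ceiling(n_phantoms / 2))[seq_len(n_phantoms)],
                         n_variants = 8L,
                         P_list = c(3L, 7L, 11L, 15L, 19L, 21L, 25L, 31L,
                                    35L, 41L, 45L, 51L),
                         arc_span_deg = 60, total_dose_mGy = 1.5,
                         arms = c(FALSE, TRUE),
                         observer_P = c(3L, 7L, 11L, 25L, 45L),
                         texture = list(levels = 256L, roi_side = 35L,
                                        d = 1L, n = 1L),
                         observer = list(n_train = 18L, n_test = 54L,
                                         loc_radius_px = 15,
                                         loc_error_scale = 2),
                         seed = 1L) {
  .assert(n_phantoms >= 1, "need at least one phantom")
  .assert(length(vgfs) == n_phantoms, "one VGF per phantom")
  .assert(all(vgfs > 0 & vgfs < 1), "VGFs must lie in (0, 1)")
  .assert(n_variants >= 1, "need at least one lesion variant")
  .assert(length(P_list) >= 1 && all(P_list >= 1), "invalid P_list")
  structure(list(n_phantoms = as.integer(n_phantoms), vgfs = vgfs,
                 n_variants = as.integer(n_variants),
                 P_list = as.integer(P_list),
                 arc_span_deg = arc_span_deg,
                 total_dose_mGy = total_dose_mGy, arms = arms,
                 observer_P = as.integer(observer_P),
                 texture = texture, observer = observer,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Enumerate the study image inventory
#'
#' One row per unique 2D slab: per phantom, `n_variants` lesion-present
#' slabs (the slab containing each variant's lesion centre) plus the same
#' number of lesion-absent slabs taken at matched depths from the
#' lesion-free run, crossed with the requested projection numbers and
#' filter arms. No images are simulated.
#'
#' @param config a [study_config()].
#' @param P_values projection numbers to include (default all of
#'   `config$P_list`).
#' @param arms filter arms to include (default `config$arms`).
#' @return Data frame with columns `phantom`, `vgf`, `variant`, `truth`,
#'   `P`, `filtered`, `slab_id`.
#' @export
build_inventory <- function(config = study_config(),
                            P_values = config$P_list, arms = config$arms) {
  .assert(inherits(config, "study_config"), "config must be a study_config")
  per_phantom <- rbind(
    data.frame(variant = seq_len(config$n_variants), truth = TRUE),
    data.frame(variant = seq_len(config$n_variants), truth = FALSE))
  base <- do.call(rbind, lapply(seq_len(config$n_phantoms), function(ph) {
    cbind(data.frame(phantom = ph, vgf = config$vgfs[ph]), per_phantom)
  }))
  out <- do.call(rbind, lapply(arms, function(arm) {
    do.call(rbind, lapply(P_values, function(p) {
      cbind(base, data.frame(P = p, filtered = arm))
    }))
  }))
  out$slab_id <- sprintf("ph%02d_%s%02d_P%02d_%s", out$phantom,
                         ifelse(out$truth, "les", "abs"), out$variant,
                         out$P, ifelse(out$filtered, "wf", "nf"))
  rownames(out) <- NULL
  out
}

#' Reduced-scale simulation options
#'
#' A desk-scale preset of the imaging chain used by the qualitative trend
#' study and the end-to-end smoke tests: 0.5-mm phantom voxels on a
#' 48 x 48 x 96 grid (a 24 x 24 x 48 mm slab, full compressed thickness),
#' 0.3-mm detector pitch (finer than the 0.6-mm reconstruction pixel, so
#' sparse-view streaks stay sharp, as with a thin-CsI panel), monoenergetic
#' 20 keV spectrum, 8-mm lesions, 2-mm display slabs, 64 grey levels and
#' 12-pixel lattice ROIs. Fluence and electronic noise (30000 photons per
#' pixel per mGy, SD 10 counts) keep every view above photon starvation
#' while letting per-view noise grow markedly toward P = 45 at the fixed
#' 1.5 mGy total dose.
#'
#' @param grid_shape phantom voxel counts; the default keeps the full
#'   ~50 mm compressed thickness (96 voxels at 0.5 mm) because the
#'   artifact-reduction mechanism at the lesion scale depends on the
#'   out-of-plane smear range `z * tan(arc/2)` exceeding the lesion size.
#' @param voxel_size phantom voxel size, mm.
#' @param pitch_mm detector pitch, mm.
#' @param lesion_diameter_mm lesion diameter, mm.
#' @param electronic_sd additive electronic noise SD, counts.
#' @param blur_fwhm_mm detector blur FWHM, mm.
#' @param fluence_per_mGy photons per pixel per mGy.
#' @param total_dose_mGy total dose, mGy.
#' @param slab_thickness_mm display slab thickness, mm.
#' @param levels,roi_side texture quantization levels and ROI side.
#' @param recon_in_plane,recon_slice reconstruction sampling, mm.
#' @param obs_integration_px effective pixel count over which the
#'   synthetic observer averages pixel-scale fluctuations (default 1: a
#'   masking-limited observer whose detectability is suppressed by the
#'   total local fluctuation, the regime in which human performance
#'   degrades with quantum noise and streak artifacts).
#' @param obs_efficiency multiplicative mapping from the contrast-to-noise
#'   index to observer detectability (default 6, placing the studied
#'   conditions in the AUC 0.6-0.85 operating range).
#' @param compartment_mm3 characteristic parenchymal compartment volume
#'   (default 64, a 4 mm scale: fibroglandular texture is fine-grained
#'   relative to the 8 mm lesion).
#' @return List of options consumed by [simulate_case()] and
#'   [run_trend_study()].
#' @export
reduced_study_options <- function(grid_shape = c(48L, 48L, 96L),
                                  voxel_size = 0.5, pitch_mm = 0.3,
                                  lesion_diameter_mm = 8,
                                  electronic_sd = 10, blur_fwhm_mm = 0.15,
                                  fluence_per_mGy = 3e4,
                                  total_dose_mGy = 1.5,
                                  slab_thickness_mm = 2,
                                  levels = 64L, roi_side = 12L,
                                  recon_in_plane = 0.6, recon_slice = 0.5,
                                  obs_integration_px = 1,
                                  obs_efficiency = 6,
                                  compartment_mm3 = 64) {
  list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
       pitch_mm = pitch_mm, lesion_diameter_mm = lesion_diameter_mm,
       electronic_sd = electronic_sd, blur_fwhm_mm = blur_fwhm_mm,
       fluence_per_mGy = fluence_per_mGy, total_dose_mGy = total_dose_mGy,
       slab_thickness_mm = slab_thickness_mm, levels = as.integer(levels),
       roi_side = as.integer(roi_side),
       recon_in_plane = recon_in_plane, recon_slice = recon_slice,
       obs_integration_px = obs_integration_px,
       obs_efficiency = obs_efficiency,
       compartment_mm3 = compartment_mm3)
}

#' Background fluctuation summary of a slab at the lesion scale
#'
#' Standard deviation of the lesion-sized disk-averaged background field
#' (computed by FFT convolution over all positions whose disk lies fully
#' inside the mask) together with the per-pixel standard deviation inside
#' the mask. The disk term carries anatomical and artifact clutter at the
#' lesion scale; the pixel term carries quantum/electronic noise and
#' streaks.
#'
#' @param pixels 2D slab pixel matrix.
#' @param mask logical breast mask.
#' @param r_px disk radius in pixels.
#' @return List with `disk_sd` and `pixel_sd`.
#' @export
slab_noise_summary <- function(pixels, mask, r_px) {
  n <- dim(pixels)
  kern <- matrix(0, n[1], n[2])
  kc <- floor(n / 2) + 1
  kern[(row(kern) - kc[1])^2 + (col(kern) - kc[2])^2 <= r_px^2] <- 1
  kern <- kern / sum(kern)
  fk <- Conj(fft(kern))
  conv <- Re(fft(fft(pixels) * fk, inverse = TRUE)) / prod(n)
  erod <- Re(fft(fft(mask + 0) * fk, inverse = TRUE)) / prod(n)
  valid <- erod > 1 - 1e-3
  .assert(sum(valid) > 10, "mask too small for the disk summary")
  list(disk_sd = stats::sd(conv[valid]),
       pixel_sd = stats::sd(pixels[mask]))
}

#' Synthetic-observer detectability from slab summaries
#'
#' Maps the lesion contrast (from the noiseless reconstruction pair) and
#' the measured background fluctuations of the noisy lesion-absent slab to
#' a latent-score separation:
#' `d' = k * contrast / sqrt(disk_sd^2 + pixel_sd^2 / n_int)`.
#' The denominator combines lesion-scale clutter with pixel-scale
#' fluctuation; with the default `n_int = 1` the observer is
#' masking-limited, i.e. suppressed by the total local fluctuation
#' (streaks at sparse sampling, quantum/electronic noise at dense
#' sampling) and not just by lesion-sized clutter.
#'
#' @param contrast lesion-disk contrast of the noiseless pair.
#' @param noise a [slab_noise_summary()].
#' @param n_int perceptual integration pixel count.
#' @param k efficiency scaling to latent-score units.
#' @return Nonnegative detectability.
#' @export
detectability_index <- function(contrast, noise, n_int = 1, k = 6) {
  den <- sqrt(noise$disk_sd^2 + noise$pixel_sd^2 / n_int)
  max(0, k * contrast / den)
}

#' Simulate one imaging case (lesion-present and depth-matched absent)
#'
#' Projects a phantom with and without an inserted lesion, applies the
#' detector cascade (and optionally the adaptive Wiener filter to the
#' projections), reconstructs both volumes, and returns the display slab
#' containing the lesion centre together with the depth-matched
#' lesion-absent slab, the breast mask, and a lesion contrast-to-noise
#' summary: `(mean(present disk) - mean(absent disk)) / sd(absent in
#' mask)` over the lesion-sized disk at the true centre.
#'
#' @param phantom a `breast_phantom` (without lesion).
#' @param P number of projections.
#' @param filtered logical; apply the Wiener filter to the projections.
#' @param lesion_seed seed for lesion placement.
#' @param noise_seed seed for detector noise.
#' @param opts options from [reduced_study_options()].
#' @param materials a `material_table`.
#' @param noiseless_absent optional cached noiseless `projection_set` of
#'   the lesion-free phantom at this geometry.
#' @param noiseless_present optional cached noiseless projection of a
#'   lesioned phantom; when given, `lesion` must carry its lesion record
#'   and `lesion_seed` is unused.
#' @param lesion lesion record matching `noiseless_present`.
#' @return List: `slab_present`, `slab_absent` (`slab_image`s), `mask`,
#'   `cnr`, `lesion`, `center_px`, `noiseless_absent`, `noiseless_present`.
#' @export
simulate_case <- function(phantom, P, filtered = FALSE, lesion_seed = 1L,
                          noise_seed = 1L, opts = reduced_study_options(),
                          materials = default_material_table(),
                          noiseless_absent = NULL,
                          noiseless_present = NULL, lesion = NULL) {
  place <- default_geometry(phantom, P, pitch_mm = opts$pitch_mm,
                            total_dose_mGy = opts$total_dose_mGy)
  geom <- place$geometry
  org <- place$phantom_origin_mm

  if (is.null(noiseless_absent)) {
    noiseless_absent <- project_noiseless(
      phantom, geom, materials, phantom_origin_mm = org,
      fluence_per_mGy = opts$fluence_per_mGy)
  }
  if (is.null(noiseless_present)) {
    thick <- phantom$thickness_mm
    set.seed(as.integer(lesion_seed))
    depth <- runif(1, 0.3 * thick, 0.7 * thick)
    ph_les <- insert_lesion(phantom, opts$lesion_diameter_mm, depth,
                            seed = lesion_seed + 7L)
    lesion <- ph_les$lesion
    noiseless_present <- project_noiseless(
      ph_les, geom, materials, phantom_origin_mm = org,
      fluence_per_mGy = opts$fluence_per_mGy)
  }
  .assert(!is.null(lesion), "lesion record required with cached projections")

  noisy_p <- apply_detector(noiseless_present, opts$blur_fwhm_mm, 1,
                            opts$electronic_sd, seed = noise_seed)
  noisy_a <- apply_detector(noiseless_absent, opts$blur_fwhm_mm, 1,
                            opts$electronic_sd, seed = noise_seed + 100003L)
  if (filtered) {
    noisy_p <- wiener_filter_projections(noisy_p)
    noisy_a <- wiener_filter_projections(noisy_a)
  }

  grid <- default_recon_grid(phantom, org, in_plane = opts$recon_in_plane,
                             slice = opts$recon_slice)
  vol_p <- butterworth3d(fbp_reconstruct(noisy_p, grid))
  vol_a <- butterworth3d(fbp_reconstruct(noisy_a, grid))
  mask <- build_breast_mask(phantom, grid, org)

  vs <- phantom$voxel_size
  lesion_world <- c(org[1] + (lesion$center[1] - 0.5) * vs,
                    org[2] + (lesion$center[2] - 0.5) * vs,
                    org[3] + (lesion$center[3] - 0.5) * vs)
  les_info <- list(center_mm = lesion_world,
                   diameter_mm = lesion$diameter_mm)
  cond <- list(P = P, filtered = filtered)
  slabs_p <- slab_volume(vol_p, opts$slab_thickness_mm, mask = mask,
                         lesion = les_info, condition = cond)
  slabs_a <- slab_volume(vol_a, opts$slab_thickness_mm, mask = mask,
                         condition = cond)
  idx <- which(vapply(slabs_p, function(s) s$truth$present, logical(1)))
  .assert(length(idx) == 1, "lesion centre not contained in any slab")
  slab_p <- slabs_p[[idx]]
  slab_a <- slabs_a[[idx]]

  ctr <- slab_p$truth$center_px
  r_px <- (lesion$diameter_mm / 2) / grid$voxel[1]
  rr <- row(slab_p$pixels); cc <- col(slab_p$pixels)
  disk <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= r_px^2
  sd_bg <- stats::sd(slab_a$pixels[mask])
  cnr <- if (sd_bg > 0) {
    (mean(slab_p$pixels[disk]) - mean(slab_a$pixels[disk])) / sd_bg
  } else {
    Inf
  }
  list(slab_present = slab_p, slab_absent = slab_a, mask = mask, cnr = cnr,
       lesion = lesion, center_px = ctr,
       noiseless_absent = noiseless_absent,
       noiseless_present = noiseless_present)
}

#' Reduced-scale qualitative trend study
#'
#' Runs the whole chain at desk scale: two phantoms (25% and 50% VGF), a
#' small set of projection numbers, both filter arms, many noise seeds.
#' Per seed and condition it measures a lesion contrast-to-noise summary
#' on simulated slabs (clean-pair lesion contrast over the measured
#' background fluctuation of the noisy lesion-absent slab, see
#' [detectability_index()]), drives the synthetic observer with it, and
#' scores an LROC AUC; texture features are extracted from the noisy
#' lesion-absent slabs.
#'
#' @param n_seeds number of noise seeds (default 20).
#' @param P_values projection numbers simulated (default 3, 11, 25, 45).
#' @param auc_P subset of `P_values` at which AUC is scored on both arms
#'   (default 3, 11, 45).
#' @param n_variants cached lesion variants per phantom cycled across
#'   seeds (default 3).
#' @param base_seed base seed; all derived seeds stay below 2^31.
#' @param opts [reduced_study_options()].
#' @param n_trials observer trials per AUC estimate (default 800).
#' @param progress print per-seed progress to stderr.
#' @return List with `auc` (seed, P, filtered, cnr, auc) and `features`
#'   (seed, P, filtered, feature, mean over ROIs and phantoms).
#' @export
run_trend_study <- function(n_seeds = 20L, P_values = c(3L, 11L, 25L, 45L),
                            auc_P = c(3L, 11L, 45L), n_variants = 3L,
                            base_seed = 1L, opts = reduced_study_options(),
                            n_trials = 800L, progress = FALSE) {
  base_seed <- as.integer(base_seed) %% 100000L
  materials <- default_material_table()
  vgfs <- c(0.25, 0.5)
  phantoms <- lapply(seq_along(vgfs), function(i) {
    generate_phantom(vgfs[i], opts$grid_shape, seed = base_seed + 11L * i,
                     voxel_size = opts$voxel_size,
                     target_compartment_mm3 = opts$compartment_mm3)
  })
  r_px <- (opts$lesion_diameter_mm / 2) / opts$recon_in_plane

  # one lesion per (phantom, variant), shared across all P so that the
  # P-trend is not confounded by placement
  lesioned <- list()
  for (i in seq_along(phantoms)) {
    thick <- phantoms[[i]]$thickness_mm
    for (v in seq_len(n_variants)) {
      for (try_k in 0:19) {    # some depths have no feasible centre: retry
        ls <- base_seed + 997L * i + 131L * v + 7681L * try_k
        set.seed(ls)
        depth <- runif(1, 0.3 * thick, 0.7 * thick)
        ph_l <- tryCatch(
          insert_lesion(phantoms[[i]], opts$lesion_diameter_mm, depth,
                        seed = ls + 7L),
          error = function(e) NULL)
        if (!is.null(ph_l)) break
      }
      .assert(!is.null(ph_l), "no feasible lesion placement after 20 tries")
      lesioned[[paste(i, v)]] <- ph_l
    }
  }

  # deterministic setup per (phantom, P): noiseless projections of the
  # lesion-free phantom, clean reconstruction, and per-variant lesion
  # contrast from the clean present/absent pair
  setup <- list()
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    for (p in P_values) {
      if (progress) message(sprintf("setup phantom %d, P=%d", i, p))
      place <- default_geometry(ph, p, pitch_mm = opts$pitch_mm,
                                total_dose_mGy = opts$total_dose_mGy)
      org <- place$phantom_origin_mm
      proj_a <- project_noiseless(ph, place$geometry, materials,
                                  phantom_origin_mm = org,
                                  fluence_per_mGy = opts$fluence_per_mGy)
      grid <- default_recon_grid(ph, org, in_plane = opts$recon_in_plane,
                                 slice = opts$recon_slice)
      clean_a <- butterworth3d(fbp_reconstruct(proj_a, grid))
      mask <- build_breast_mask(ph, grid, org)
      vars <- list()
      for (v in seq_len(n_variants)) {
        ph_l <- lesioned[[paste(i, v)]]
        proj_p <- project_noiseless(ph_l, place$geometry, materials,
                                    phantom_origin_mm = org,
                                    fluence_per_mGy = opts$fluence_per_mGy)
        clean_p <- butterworth3d(fbp_reconstruct(proj_p, grid))
        lw <- org + (ph_l$lesion$center - 0.5) * opts$voxel_size
        les_info <- list(center_mm = lw,
                         diameter_mm = ph_l$lesion$diameter_mm)
        sl_p <- slab_volume(clean_p, opts$slab_thickness_mm, mask = mask,
                            lesion = les_info)
        sl_a <- slab_volume(clean_a, opts$slab_thickness_mm, mask = mask)
        idx <- which(vapply(sl_p, function(s) s$truth$present, logical(1)))
        ctr <- sl_p[[idx]]$truth$center_px
        rr <- row(sl_p[[idx]]$pixels); cc <- col(sl_p[[idx]]$pixels)
        disk <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= r_px^2
        vars[[v]] <- list(
          slab_idx = idx,
          contrast = mean(sl_p[[idx]]$pixels[disk]) -
            mean(sl_a[[idx]]$pixels[disk]))
      }
      sl_a0 <- slab_volume(clean_a, opts$slab_thickness_mm, mask = mask)
      rng_p <- range(unlist(lapply(sl_a0, function(s) s$pixels[mask])))
      setup[[paste(i, p)]] <- list(proj_a = proj_a, grid = grid,
                                   mask = mask, vars = vars, rng = rng_p)
    }
  }
  # fixed per-phantom quantization window: pooled clean-slab range across
  # all P, so features respond to structure and noise rather than to
  # per-image range renormalization
  qranges <- lapply(seq_along(phantoms), function(i) {
    rngs <- do.call(rbind, lapply(P_values, function(p) setup[[paste(i, p)]]$rng))
    c(min(rngs[, 1]), max(rngs[, 2]))
  })

  auc_rows <- list()
  feat_rows <- list()
  for (s in seq_len(n_seeds)) {
    if (progress) message(sprintf("trend study seed %d/%d", s, n_seeds))
    v <- ((s - 1L) %% n_variants) + 1L
    for (p in P_values) {
      arms <- if (p %in% auc_P) c(FALSE, TRUE) else FALSE
      for (arm in arms) {
        dps <- numeric(length(phantoms))
        fmat <- matrix(NA_real_, length(.FEATURE_NAMES), length(phantoms),
                       dimnames = list(.FEATURE_NAMES, NULL))
        for (i in seq_along(phantoms)) {
          su <- setup[[paste(i, p)]]
          noisy <- apply_detector(
            su$proj_a, opts$blur_fwhm_mm, 1, opts$electronic_sd,
            seed = base_seed + 20011L * s + 211L * i + 2L * p +
              as.integer(arm))
          if (arm) noisy <- wiener_filter_projections(noisy)
          vol <- butterworth3d(fbp_reconstruct(noisy, su$grid))
          slabs <- slab_volume(vol, opts$slab_thickness_mm, mask = su$mask)
          sl <- slabs[[su$vars[[v]]$slab_idx]]
          noise <- slab_noise_summary(sl$pixels, su$mask, r_px)
          dps[i] <- detectability_index(su$vars[[v]]$contrast, noise,
                                        n_int = opts$obs_integration_px,
                                        k = opts$obs_efficiency)
          q <- quantize(sl$pixels, levels = opts$levels, mask = su$mask,
                        range = qranges[[i]])
          rois <- suppressWarnings(
            lattice_rois(q, su$mask, side = opts$roi_side,
                         levels = opts$levels))
          if (length(rois)) {
            fv <- vapply(rois, roi_features, numeric(13))
            fmat[, i] <- rowMeans(fv, na.rm = TRUE)
          }
          if (i == 1L) mask1 <- su$mask
        }
        dp <- mean(dps)
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          seed = s, P = p, filtered = arm, feature = .FEATURE_NAMES,
          mean = rowMeans(fmat, na.rm = TRUE))
        if (p %in% auc_P) {
          auc <- observer_auc(dp, n_trials = n_trials,
                              guess_area = mask1, loc_error_scale = 2,
                              seed = base_seed + 40009L * s + 5L * p +
                                as.integer(arm))
          auc_rows[[length(auc_rows) + 1L]] <- data.frame(
            seed = s, P = p, filtered = arm, detectability = dp, auc = auc)
        }
      }
    }
  }
  list(auc = do.call(rbind, auc_rows),
       features = do.call(rbind, feat_rows))
}

#' Run the configurable study pipeline and write artifacts
#'
#' Desk-scale orchestration of the full chain with per-stage artifacts and
#' resume: a stage whose output file already exists is skipped. Stages:
#' `"simulate"` (trend study; writes `auc.csv` and `features.csv`),
#' `"correlate"` (per-feature correlations over the simulated conditions;
#' writes `correlations.csv` and `concavity.json`), `"report"` (writes
#' `report.json` with inventory counts and headline numbers).
#'
#' @param config a [study_config()] (its `observer_P` intersected with the
#'   simulated P values drives the correlation subset).
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "correlate", "report")`.
#' @param n_seeds,P_values,auc_P,opts forwarded to [run_trend_study()].
#' @return Invisibly, a list of the stage artifact paths.
#' @export
run_study <- function(config = study_config(), out_dir,
                      stages = c("simulate", "correlate", "report"),
                      n_seeds = 5L, P_values = c(3L, 11L, 25L, 45L),
                      auc_P = c(3L, 11L, 45L),
                      opts = reduced_study_options()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(auc = file.path(out_dir, "auc.csv"),
                features = file.path(out_dir, "features.csv"),
                correlations = file.path(out_dir, "correlations.csv"),
                concavity = file.path(out_dir, "concavity.json"),
                report = file.path(out_dir, "report.json"))

  if ("simulate" %in% stages &&
      !(file.exists(paths$auc) && file.exists(paths$features))) {
    res <- run_trend_study(n_seeds = n_seeds, P_values = P_values,
                           auc_P = auc_P, base_seed = config$seed,
                           opts = opts)
    utils::write.csv(res$auc, paths$auc, row.names = FALSE)
    utils::write.csv(res$features, paths$features, row.names = FALSE)
  }

  if ("correlate" %in% stages && !file.exists(paths$correlations)) {
    .assert(file.exists(paths$auc) && file.exists(paths$features),
            "correlate stage requires the simulate stage artifacts")
    aucs_raw <- utils::read.csv(paths$auc)
    feats_raw <- utils::read.csv(paths$features)
    aucs <- stats::aggregate(auc ~ P + filtered, aucs_raw, mean)
    feats <- stats::aggregate(mean ~ P + filtered + feature, feats_raw, mean)
    subset_P <- intersect(auc_P, unique(aucs$P))
    tab <- correlate_conditions(feats, aucs, subset = subset_P)
    utils::write.csv(as.data.frame(tab), paths$correlations,
                     row.names = FALSE)
    unf <- feats[!feats$filtered, ]
    conc <- lapply(split(unf, unf$feature), function(df) {
      df <- df[order(df$P), ]
      if (nrow(df) >= 4) classify_concavity(df$mean, df$P) else "indeterminate"
    })
    jsonlite::write_json(conc, paths$concavity, auto_unbox = TRUE)
  }

  if ("report" %in% stages && !file.exists(paths$report)) {
    inv_all <- build_inventory(config)
    rep <- list(
      inventory = list(
        per_condition = nrow(build_inventory(
          config, P_values = config$P_list[1], arms = FALSE)),
        unfiltered = nrow(build_inventory(config, arms = FALSE)),
        total = nrow(inv_all)),
      config_seed = config$seed)
    if (file.exists(paths$auc)) {
      aucs_raw <- utils::read.csv(paths$auc)
      rep$auc_by_condition <- stats::aggregate(auc ~ P + filtered,
                                               aucs_raw, mean)
    }
    jsonlite::write_json(rep, paths$report, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(paths)
}
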