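#' Quantize an image into discrete grey levels
#'
#' Per-image linear min-max binning into `[0, levels - 1]`. The range is
#' taken over masked pixels when a mask is given (the rest of the image is
#' clamped into range). Monotone: pixel ordering is preserved. A constant
#' image maps everywhere to level 0. The result is invariant under any
#' positive affine rescaling of the input.
#'
#' @param image numeric matrix (finite values).
#' @param levels number of grey levels, >= 2 (default 256).
#' @param mask optional logical matrix; range computed over `mask == TRUE`.
#' @param range optional fixed `c(lo, hi)` quantization window
#'   ("global-range mode"): values outside are clamped to the extreme
#'   levels and the per-image min-max is not used. A fixed window keeps
#'   the binning comparable across images of one study, so that noise and
#'   artifacts change local grey-level relations rather than renormalizing
#'   the whole scale.
#' @return Integer matrix of levels in `[0, levels - 1]`.
#' @export
quantize <- function(image, levels = 256L, mask = NULL, range = NULL) {
  .assert(is.matrix(image) && all(is.finite(image)),
          "image must be a finite numeric matrix")
  levels <- as.integer(levels)
  .assert(levels >= 2, "levels must be >= 2")
  if (!is.null(range)) {
    .assert(length(range) == 2 && range[2] >= range[1],
            "range must be c(lo, hi)")
    mn <- range[1]; mx <- range[2]
  } else {
    ref <- if (is.null(mask)) image else image[mask]
    mn <- min(ref); mx <- max(ref)
  }
  if (mx <= mn) {
    q <- matrix(0L, nrow(image), ncol(image))
    return(q)
  }
  q <- floor((image - mn) / (mx - mn) * levels)
  q[q < 0] <- 0
  q[q > levels - 1] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Tile the breast region into lattice ROIs
#'
#' Non-overlapping square tiles anchored at the origin of the mask's
#' bounding box, enumerated in row-major order; only tiles lying fully
#' inside the mask are kept.
#'
#' @param qimage quantized integer matrix (see [quantize()]).
#' @param mask logical matrix, same shape; must be nonempty.
#' @param side tile side in pixels (default 35; at the 0.27 mm display
#'   pixel this is 9.45 mm, slightly larger than an 8-mm lesion).
#' @param levels number of grey levels in `qimage` (default 256), recorded
#'   on each ROI.
#' @return List of `quantized_roi` objects (`pixels`, `row0`, `col0`,
#'   `side`, `levels`); empty (with a warning) when no complete tile fits.
#' @export
lattice_rois <- function(qimage, mask, side = 35L, levels = 256L) {
  .assert(is.matrix(mask) && any(mask), "mask must be nonempty")
  .assert(all(dim(qimage) == dim(mask)), "image/mask shape mismatch")
  side <- as.integer(side)
  .assert(side >= 2, "ROI side must be >= 2")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  r0 <- min(rows); c0 <- min(cols)
  out <- list()
  r <- r0
  while (r + side - 1L <= nrow(mask)) {
    cc <- c0
    while (cc + side - 1L <= ncol(mask)) {
      sub <- mask[r:(r + side - 1L), cc:(cc + side - 1L)]
      if (all(sub)) {
        out[[length(out) + 1L]] <- structure(
          list(pixels = qimage[r:(r + side - 1L), cc:(cc + side - 1L)],
               row0 = r, col0 = cc, side = side, levels = as.integer(levels)),
          class = "quantized_roi")
      }
      cc <- cc + side
    }
    r <- r + side
  }
  if (length(out) == 0) warning("no complete lattice tile fits inside the mask")
  out
}

.GLCM_ANGLES <- c(0, 45, 90, 135)

# displacement (drow, dcol) for a GLCM/RLM direction; rows grow downward
.angle_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Grey level co-occurrence matrix
#'
#' Symmetric, normalized GLCM at pixel displacement `d` along one of the
#' four directions. Each ordered pair is counted in both orders
#' (Haralick's symmetric convention) and the matrix is normalized to sum
#' to 1.
#'
#' @param roi a `quantized_roi` (or integer matrix of levels in
#'   `[0, levels - 1]`).
#' @param d displacement in pixels (default 1).
#' @param angle one of 0, 45, 90, 135 degrees.
#' @param levels number of grey levels; taken from the ROI when available.
#' @return `levels x levels` matrix of co-occurrence probabilities; class
#'   `glcm` with attributes `d` and `angle`.
#' @export
compute_glcm <- function(roi, d = 1L, angle = 0, levels = NULL) {
  px <- if (inherits(roi, "quantized_roi")) roi$pixels else roi
  if (is.null(levels)) {
    levels <- if (inherits(roi, "quantized_roi")) roi$levels else max(px) + 1L
  }
  d <- as.integer(d)
  .assert(d >= 1, "d must be >= 1")
  .assert(d < nrow(px) && d < ncol(px), "d must be smaller than the ROI side")
  off <- .angle_offset(angle, d)
  nr <- nrow(px); nc <- ncol(px)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- px[r1, c1, drop = FALSE]
  b <- px[r1 + off[1], c1 + off[2], drop = FALSE]
  idx <- as.vector(a) * levels + as.vector(b) + 1L
  counts <- tabulate(idx, nbins = levels * levels)
  G <- matrix(counts, levels, levels, byrow = TRUE) # row i = first level
  G <- G + t(G)
  G <- G / sum(G)
  structure(G, class = "glcm", d = d, angle = angle)
}

#' GLCM scalar features
#'
#' Correlation, Homogeneity (inverse difference), Energy (angular second
#' moment) and Entropy (log base 2, with `0 log 0 = 0`) of a normalized
#' GLCM, using 1-based grey level values `i, j = 1..N_grey`:
#' \itemize{
#'   \item Correlation: `(sum_ij i*j*G(i,j) - mu_x*mu_y) / (sigma_x*sigma_y)`
#'   \item Homogeneity: `sum_ij G(i,j) / (1 + |i - j|)`
#'   \item Energy: `sum_ij G(i,j)^2`
#'   \item Entropy: `-sum_ij G(i,j) log2 G(i,j)`
#' }
#' Correlation is `NA` when either marginal has zero variance (constant
#' ROI); callers exclude such values rather than reporting a silent zero.
#'
#' @param glcm normalized GLCM matrix.
#' @return Named numeric vector `correlation`, `homogeneity`, `energy`,
#'   `entropy`.
#' @export
glcm_features <- function(glcm) {
  N <- nrow(glcm)
  .assert(abs(sum(glcm) - 1) < 1e-9, "GLCM must be normalized")
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  mu_x <- sum(i * glcm)
  mu_y <- sum(j * glcm)
  sx <- sqrt(sum((i - mu_x)^2 * glcm))
  sy <- sqrt(sum((j - mu_y)^2 * glcm))
  corr <- if (sx * sy > 0) (sum(i * j * glcm) - mu_x * mu_y) / (sx * sy)
          else NA_real_
  hom <- sum(glcm / (1 + abs(i - j)))
  ene <- sum(glcm^2)
  pos <- glcm > 0
  ent <- -sum(glcm[pos] * log2(glcm[pos]))
  c(correlation = corr, homogeneity = hom, energy = ene, entropy = ent)
}

#' Neighborhood grey tone difference matrix
#'
#' For every "centre" pixel with a complete `(2n+1) x (2n+1)` neighborhood,
#' the absolute difference between its grey value and the mean of the
#' surrounding neighborhood (centre excluded) is accumulated per grey
#' level: `D(i) = sum over centres of level i of |i - A_i|`. Grey level
#' occurrence probabilities `p_i` are computed over centre pixels.
#'
#' @param roi a `quantized_roi` or integer matrix.
#' @param n neighborhood radius (default 1, i.e. the 8 adjacent pixels).
#' @return An `ngtdm` list: `levels` (1-based grey values `i` present among
#'   centres), `D`, `p` (aligned with `levels`), `n2` (number of centre
#'   pixels), `Ng` (number of distinct levels present), `n`.
#' @export
compute_ngtdm <- function(roi, n = 1L) {
  px <- if (inherits(roi, "quantized_roi")) roi$pixels else roi
  n <- as.integer(n)
  .assert(nrow(px) > 2 * n && ncol(px) > 2 * n,
          "ROI side must exceed 2n")
  W <- 2L * n + 1L
  nr <- nrow(px); nc <- ncol(px)
  num <- matrix(as.numeric(px), nr, nc)
  # neighborhood sums via separable box filter (no padding; centres only)
  ones <- rep(1, W)
  sum_r <- apply(num, 2, function(col) {
    as.numeric(stats::filter(col, ones, sides = 2))
  })
  box <- t(apply(t(sum_r), 2, function(row) {
    as.numeric(stats::filter(row, ones, sides = 2))
  }))
  # stats::filter centres the window for odd lengths; valid rows/cols:
  ctr_r <- (n + 1L):(nr - n)
  ctr_c <- (n + 1L):(nc - n)
  box <- box[ctr_r, ctr_c, drop = FALSE]
  centre <- num[ctr_r, ctr_c, drop = FALSE]
  nbr_mean <- (box - centre) / (W * W - 1)
  lvls1 <- centre + 1          # 1-based grey values
  diffs <- abs(lvls1 - (nbr_mean + 1))
  lv <- sort(unique(as.vector(lvls1)))
  D <- vapply(lv, function(l) sum(diffs[lvls1 == l]), numeric(1))
  cnt <- vapply(lv, function(l) sum(lvls1 == l), numeric(1))
  n2 <- length(centre)
  structure(list(levels = lv, D = D, p = cnt / n2, n2 = n2,
                 Ng = length(lv), n = n),
            class = "ngtdm")
}

#' NGTDM scalar features
#'
#' Contrast, Coarseness, Busyness and Complexity from the grey tone
#' difference sums, with all sums restricted to grey levels of nonzero
#' occurrence probability:
#' \itemize{
#'   \item Contrast:
#'     `[1/(Ng(Ng-1)) sum_ij p_i p_j (i-j)^2] * [1/n2 sum_i D(i)]`
#'     (0 for a single-level ROI).
#'   \item Coarseness: `1 / (sum_i p_i D(i) + eps)` with `eps = 1e-12`
#'     guarding the constant-ROI divergence.
#'   \item Busyness: `sum_i p_i D(i) / sum_ij |i p_i - j p_j|`; `NA` when
#'     the denominator vanishes (single grey level).
#'   \item Complexity:
#'     `sum_ij (|i-j| / (n2 p_i + n2 p_j)) (p_i D(i) + p_j D(j))`.
#' }
#'
#' @param res an `ngtdm` from [compute_ngtdm()].
#' @return Named numeric vector `contrast`, `coarseness`, `busyness`,
#'   `complexity`.
#' @export
ngtdm_features <- function(res) {
  .assert(inherits(res, "ngtdm"), "res must be an ngtdm")
  i <- res$levels; p <- res$p; D <- res$D
  Ng <- res$Ng; n2 <- res$n2
  pDsum <- sum(p * D)
  coarse <- 1 / (pDsum + 1e-12)
  if (Ng < 2) {
    return(c(contrast = 0, coarseness = coarse, busyness = NA_real_,
             complexity = 0))
  }
  ii <- matrix(i, Ng, Ng); jj <- t(ii)
  pi_m <- matrix(p, Ng, Ng); pj_m <- t(pi_m)
  Di_m <- matrix(D, Ng, Ng); Dj_m <- t(Di_m)
  contrast <- (sum(pi_m * pj_m * (ii - jj)^2) / (Ng * (Ng - 1))) *
    (sum(D) / n2)
  busy_den <- sum(abs(ii * pi_m - jj * pj_m))
  busyness <- if (busy_den > 0) pDsum / busy_den else NA_real_
  complexity <- sum((abs(ii - jj) / (n2 * pi_m + n2 * pj_m)) *
                      (pi_m * Di_m + pj_m * Dj_m))
  c(contrast = contrast, coarseness = coarse, busyness = busyness,
    complexity = complexity)
}

#' Grey level run length matrix
#'
#' Counts of maximal constant-level runs per scan line along one of the
#' four directions. Every pixel belongs to exactly one maximal run per
#' direction, so `sum_ij j * R(i, j)` equals the pixel count.
#'
#' @param roi a `quantized_roi` or integer matrix.
#' @param angle one of 0 (rows), 45 (anti-diagonals, up-right), 90
#'   (columns), 135 (down-right diagonals).
#' @param levels number of grey levels.
#' @return An `rlm` list: `R` (`levels x N_run` count matrix, `N_run =
#'   max(dim(roi))`), `N` (total runs), `P` (pixels in the ROI), `angle`.
#' @export
compute_rlm <- function(roi, angle = 0, levels = NULL) {
  px <- if (inherits(roi, "quantized_roi")) roi$pixels else roi
  if (is.null(levels)) {
    levels <- if (inherits(roi, "quantized_roi")) roi$levels else max(px) + 1L
  }
  nr <- nrow(px); nc <- ncol(px)
  nrun <- max(nr, nc)
  lines <- switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(r) px[r, ]),
    "90" = lapply(seq_len(nc), function(c) px[, c]),
    "45" = {
      s <- row(px) + col(px)
      lapply(sort(unique(as.vector(s))), function(k) {
        sel <- which(s == k)
        # order by increasing column => decreasing row: up-right traversal
        px[sel[order(col(px)[sel])]]
      })
    },
    "135" = {
      s <- row(px) - col(px)
      lapply(sort(unique(as.vector(s))), function(k) {
        sel <- which(s == k)
        px[sel[order(col(px)[sel])]]
      })
    },
    stop("angle must be one of 0, 45, 90, 135"))
  R <- matrix(0, levels, nrun)
  for (ln in lines) {
    rl <- rle(as.vector(ln))
    for (q in seq_along(rl$lengths)) {
      R[rl$values[q] + 1L, rl$lengths[q]] <- R[rl$values[q] + 1L, rl$lengths[q]] + 1
    }
  }
  structure(list(R = R, N = sum(R), P = nr * nc, angle = angle),
            class = "rlm")
}

#' RLM scalar features
#'
#' Short/Long Run Emphasis, Grey Level Nonuniformity, Run Length
#' Nonuniformity and Run Percentage, computed per direction and averaged
#' over the supplied direction matrices:
#' `SRE = (1/N) sum_ij R(i,j)/j^2`, `LRE = (1/N) sum_ij j^2 R(i,j)`,
#' `GLN = (1/N) sum_i (sum_j R)^2`, `RLN = (1/N) sum_j (sum_i R)^2`,
#' `RP = N / P`.
#'
#' @param rlms a single `rlm` or a list of them (typically the four
#'   directions).
#' @return Named numeric vector `sre`, `lre`, `gln`, `rln`, `rp`.
#' @export
rlm_features <- function(rlms) {
  if (inherits(rlms, "rlm")) rlms <- list(rlms)
  one <- function(rl) {
    .assert(rl$N > 0, "empty ROI: no runs")
    j2 <- (seq_len(ncol(rl$R)))^2
    rsum <- rowSums(rl$R)
    csum <- colSums(rl$R)
    c(sre = sum(sweep(rl$R, 2, j2, `/`)) / rl$N,
      lre = sum(sweep(rl$R, 2, j2, `*`)) / rl$N,
      gln = sum(rsum^2) / rl$N,
      rln = sum(csum^2) / rl$N,
      rp = rl$N / rl$P)
  }
  vals <- vapply(rlms, one, numeric(5))
  rowMeans(vals)
}

#' All 13 texture features of one ROI
#'
#' GLCM features are averaged over the four direction matrices (GLCM
#' correlation: over the directions where it is defined, `NA` if none);
#' NGTDM features come from the single neighborhood matrix; RLM features
#' are averaged over the four directions.
#'
#' @param roi a `quantized_roi` or integer level matrix.
#' @param d GLCM displacement (default 1).
#' @param n NGTDM neighborhood radius (default 1).
#' @param levels grey levels (from the ROI when available).
#' @return Named numeric vector of length 13 (see
#'   [texture_feature_names()]).
#' @export
roi_features <- function(roi, d = 1L, n = 1L, levels = NULL) {
  g <- vapply(.GLCM_ANGLES, function(a) {
    glcm_features(compute_glcm(roi, d = d, angle = a, levels = levels))
  }, numeric(4))
  g_mean <- rowMeans(g, na.rm = TRUE)
  if (all(is.na(g["correlation", ]))) g_mean["correlation"] <- NA_real_
  ng <- ngtdm_features(compute_ngtdm(roi, n = n))
  rl <- rlm_features(lapply(.GLCM_ANGLES, function(a) {
    compute_rlm(roi, angle = a, levels = levels)
  }))
  out <- c(g_mean[c("correlation", "homogeneity", "energy", "entropy")],
           ng[c("contrast", "coarseness", "busyness", "complexity")],
           rl[c("sre", "lre", "gln", "rln", "rp")])
  names(out) <- .FEATURE_NAMES
  out
}

#' Per-ROI and per-condition texture feature tables
#'
#' Quantizes each slab over its breast mask, tiles the mask into lattice
#' ROIs and computes the 13 features per ROI, then aggregates mean and SD
#' per condition over all ROIs of all slabs (lesion-present and
#' lesion-absent pooled). Conditions contributing zero ROIs are reported
#' with `n_roi = 0` and `NA` summaries rather than dropped.
#'
#' @param slabs list of `slab_image` objects; each needs a nonempty `mask`
#'   and a `condition` list (coerced to a key with
#'   `paste(..., collapse = "|")`).
#' @param levels quantization levels (default 256).
#' @param roi_side lattice tile side in pixels (default 35).
#' @param d,n GLCM displacement and NGTDM radius.
#' @return List with `per_roi` (one row per ROI: condition, slab, roi,
#'   13 features) and `summary` (condition x feature: mean, sd, n).
#' @export
condition_feature_table <- function(slabs, levels = 256L, roi_side = 35L,
                                    d = 1L, n = 1L) {
  .assert(length(slabs) > 0, "no slabs supplied")
  rows <- list()
  keys <- character(length(slabs))
  for (s in seq_along(slabs)) {
    sl <- slabs[[s]]
    key <- paste(unlist(sl$condition), collapse = "|")
    keys[s] <- key
    q <- quantize(sl$pixels, levels = levels, mask = sl$mask)
    rois <- suppressWarnings(
      lattice_rois(q, sl$mask, side = roi_side, levels = levels))
    for (rix in seq_along(rois)) {
      fv <- roi_features(rois[[rix]], d = d, n = n)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = key, slab = s, roi = rix,
                   as.list(fv), check.names = FALSE)
    }
  }
  per_roi <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), slab = integer(), roi = integer())
  summ <- list()
  for (key in unique(keys)) {
    sub <- per_roi[per_roi$condition == key, , drop = FALSE]
    for (f in .FEATURE_NAMES) {
      v <- if (nrow(sub)) sub[[f]] else numeric(0)
      v_ok <- v[!is.na(v)]
      summ[[length(summ) + 1L]] <- data.frame(
        condition = key, feature = f,
        mean = if (length(v_ok)) mean(v_ok) else NA_real_,
        sd = if (length(v_ok) > 1) stats::sd(v_ok) else
          if (length(v_ok) == 1) 0 else NA_real_,
        n_roi = length(v_ok))
    }
  }
  list(per_roi = per_roi, summary = do.call(rbind, summ))
}
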