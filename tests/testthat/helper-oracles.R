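# Independent brute-force oracles used to validate the texture matrices,
# the feature formulas and the LROC estimator. These deliberately use
# explicit loops and direct summation, not the package's vectorized paths.

oracle_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d))
}

# symmetric GLCM by per-pixel partner enumeration
oracle_glcm <- function(px, d, angle, levels) {
  off <- oracle_offset(angle, d)
  G <- matrix(0, levels, levels)
  for (r in seq_len(nrow(px))) {
    for (c in seq_len(ncol(px))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(px) && c2 >= 1 && c2 <= ncol(px)) {
        a <- px[r, c] + 1L; b <- px[r2, c2] + 1L
        G[a, b] <- G[a, b] + 1
        G[b, a] <- G[b, a] + 1
      }
    }
  }
  G / sum(G)
}

oracle_glcm_features <- function(G) {
  N <- nrow(G)
  mu_x <- 0; mu_y <- 0
  for (i in 1:N) for (j in 1:N) {
    mu_x <- mu_x + i * G[i, j]; mu_y <- mu_y + j * G[i, j]
  }
  sx2 <- 0; sy2 <- 0; ij <- 0; hom <- 0; ene <- 0; ent <- 0
  for (i in 1:N) for (j in 1:N) {
    g <- G[i, j]
    sx2 <- sx2 + (i - mu_x)^2 * g
    sy2 <- sy2 + (j - mu_y)^2 * g
    ij <- ij + i * j * g
    hom <- hom + g / (1 + abs(i - j))
    ene <- ene + g^2
    if (g > 0) ent <- ent - g * log2(g)
  }
  corr <- if (sx2 * sy2 > 0) (ij - mu_x * mu_y) / sqrt(sx2 * sy2) else NA_real_
  c(correlation = corr, homogeneity = hom, energy = ene, entropy = ent)
}

oracle_ngtdm <- function(px, n = 1L) {
  nr <- nrow(px); nc <- ncol(px)
  lv_all <- integer(0); dv_all <- numeric(0)
  for (r in (n + 1):(nr - n)) {
    for (c in (n + 1):(nc - n)) {
      nb <- px[(r - n):(r + n), (c - n):(c + n)]
      A <- (sum(nb) - px[r, c]) / (length(nb) - 1)
      lv_all <- c(lv_all, px[r, c] + 1L)
      dv_all <- c(dv_all, abs((px[r, c] + 1) - (A + 1)))
    }
  }
  lv <- sort(unique(lv_all))
  D <- sapply(lv, function(l) sum(dv_all[lv_all == l]))
  p <- sapply(lv, function(l) mean(lv_all == l))
  list(levels = lv, D = D, p = p, n2 = length(lv_all), Ng = length(lv))
}

oracle_ngtdm_features <- function(o) {
  i <- o$levels; p <- o$p; D <- o$D; Ng <- o$Ng; n2 <- o$n2
  pD <- sum(p * D)
  coarse <- 1 / (pD + 1e-12)
  if (Ng < 2) {
    return(c(contrast = 0, coarseness = coarse, busyness = NA_real_,
             complexity = 0))
  }
  s1 <- 0; busy_den <- 0; comp <- 0
  for (a in seq_len(Ng)) for (b in seq_len(Ng)) {
    s1 <- s1 + p[a] * p[b] * (i[a] - i[b])^2
    busy_den <- busy_den + abs(i[a] * p[a] - i[b] * p[b])
    comp <- comp + (abs(i[a] - i[b]) / (n2 * p[a] + n2 * p[b])) *
      (p[a] * D[a] + p[b] * D[b])
  }
  c(contrast = (s1 / (Ng * (Ng - 1))) * (sum(D) / n2),
    coarseness = coarse,
    busyness = if (busy_den > 0) pD / busy_den else NA_real_,
    complexity = comp)
}

# run-length matrix by explicit per-line while-loop scanning
oracle_rlm <- function(px, angle, levels) {
  nr <- nrow(px); nc <- ncol(px)
  lines <- list()
  if (angle == 0) {
    for (r in seq_len(nr)) lines[[length(lines) + 1]] <- px[r, ]
  } else if (angle == 90) {
    for (c in seq_len(nc)) lines[[length(lines) + 1]] <- px[, c]
  } else if (angle == 45) {
    for (k in 2:(nr + nc)) {
      v <- integer(0)
      for (c in seq_len(nc)) {
        r <- k - c
        if (r >= 1 && r <= nr) v <- c(v, px[r, c])
      }
      if (length(v)) lines[[length(lines) + 1]] <- v
    }
  } else {
    for (k in (1 - nc):(nr - 1)) {
      v <- integer(0)
      for (c in seq_len(nc)) {
        r <- k + c
        if (r >= 1 && r <= nr) v <- c(v, px[r, c])
      }
      if (length(v)) lines[[length(lines) + 1]] <- v
    }
  }
  R <- matrix(0, levels, max(nr, nc))
  for (ln in lines) {
    q <- 1
    while (q <= length(ln)) {
      len <- 1
      while (q + len <= length(ln) && ln[q + len] == ln[q]) len <- len + 1
      R[ln[q] + 1L, len] <- R[ln[q] + 1L, len] + 1
      q <- q + len
    }
  }
  list(R = R, N = sum(R), P = nr * nc)
}

oracle_rlm_features <- function(o) {
  sre <- 0; lre <- 0
  for (i in seq_len(nrow(o$R))) for (j in seq_len(ncol(o$R))) {
    sre <- sre + o$R[i, j] / j^2
    lre <- lre + j^2 * o$R[i, j]
  }
  gln <- sum(rowSums(o$R)^2)
  rln <- sum(colSums(o$R)^2)
  c(sre = sre / o$N, lre = lre / o$N, gln = gln / o$N, rln = rln / o$N,
    rp = o$N / o$P)
}

# exhaustive pair-counting LROC AUC
oracle_lroc_auc <- function(trials) {
  pres <- trials[trials$truth, ]
  abs_ <- trials[!trials$truth, ]
  tot <- 0
  for (a in seq_len(nrow(pres))) {
    for (b in seq_len(nrow(abs_))) {
      cp <- if (isTRUE(pres$correct_loc[a])) 1 else 0
      tot <- tot + cp * ((pres$rating[a] > abs_$rating[b]) +
                           0.5 * (pres$rating[a] == abs_$rating[b]))
    }
  }
  tot / (nrow(pres) * nrow(abs_))
}

random_roi <- function(nr, nc, levels, seed) {
  set.seed(seed)
  matrix(sample.int(levels, nr * nc, replace = TRUE) - 1L, nr, nc)
}

# analytic chord length of a segment clipped to an axis-aligned box
box_chord_length <- function(a, b, lo, hi) {
  d <- b - a
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-300) {
      if (a[ax] < lo[ax] || a[ax] >= hi[ax]) return(0)
    } else {
      ta <- (lo[ax] - a[ax]) / d[ax]
      tb <- (hi[ax] - a[ax]) / d[ax]
      lohi <- sort(c(ta, tb))
      t0 <- max(t0, lohi[1]); t1 <- min(t1, lohi[2])
      if (t0 >= t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

# hand-built phantom with every interior voxel set to one material
uniform_phantom <- function(dims, material = "fibroglandular",
                            voxel_size = 0.5) {
  labs <- array(tomotex:::.MATERIALS[[material]], dim = dims)
  storage.mode(labs) <- "integer"
  structure(list(labels = labs, voxel_size = voxel_size,
                 thickness_mm = dims[3] * voxel_size,
                 vgf_target = NA_real_, vgf_realized = NA_real_,
                 lesion = NULL, seed = 0L),
            class = "breast_phantom")
}

# all-air phantom containing a single fibroglandular sphere
sphere_phantom <- function(dims, ctr, r_vox, voxel_size = 0.5) {
  ph <- uniform_phantom(dims, "air", voxel_size)
  d2 <- (slice.index(ph$labels, 1) - ctr[1])^2 +
    (slice.index(ph$labels, 2) - ctr[2])^2 +
    (slice.index(ph$labels, 3) - ctr[3])^2
  ph$labels[d2 <= r_vox^2] <- 2L
  ph
}
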