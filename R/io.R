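#' Write / read a slab image as portable greymap (ASCII PGM)
#'
#' Plain-text 16-bit PGM with linear min-max scaling; the scaling interval
#' is stored in a JSON sidecar (`<path>.json`) together with the mask
#' bounding box, truth metadata and condition, so a slab round-trips up to
#' the 16-bit quantization of `write_slab_pgm`.
#'
#' @param slab a `slab_image`.
#' @param path output path (conventionally `.pgm`).
#' @return `write_slab_pgm` returns `path` invisibly; `read_slab_pgm`
#'   returns a `slab_image` (mask restored as the full field when no mask
#'   was stored).
#' @export
write_slab_pgm <- function(slab, path) {
  px <- slab$pixels
  mn <- min(px); mx <- max(px)
  scl <- if (mx > mn) (px - mn) / (mx - mn) else px * 0
  q <- round(scl * 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(px), ncol(px)), "65535"), con)
  write(as.integer(q), file = con, ncolumns = 16L)
  meta <- list(min = mn, max = mx,
               pixel_size = slab$pixel_size,
               truth = slab$truth, condition = slab$condition,
               slab_index = slab$slab_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_slab_pgm
#' @export
read_slab_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  .assert(txt[1] == "P2", "not an ASCII PGM (P2) file")
  nr <- as.integer(txt[2]); nc <- as.integer(txt[3])
  maxv <- as.numeric(txt[4])
  vals <- as.numeric(txt[-(1:4)])
  .assert(length(vals) == nr * nc, "corrupt PGM payload")
  px <- matrix(vals, nrow = nr, ncol = nc)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(min = 0, max = maxv)
  }
  if (!is.null(meta$max) && meta$max > meta$min) {
    px <- px / maxv * (meta$max - meta$min) + meta$min
  }
  truth <- meta$truth
  if (is.null(truth)) truth <- list(present = FALSE, center_px = NULL)
  structure(list(pixels = px,
                 pixel_size = meta$pixel_size,
                 mask = matrix(TRUE, nr, nc),
                 truth = truth,
                 condition = meta$condition,
                 slab_index = meta$slab_index),
            class = "slab_image")
}

#' Write / read an image manifest CSV
#'
#' The manifest is the contract between the reconstruction stage and the
#' texture / LROC stages: one row per slab with its condition, truth flag
#' and truth location.
#'
#' @param manifest data frame.
#' @param path CSV path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) utils::read.csv(path)
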