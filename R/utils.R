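#' Round half away from zero
#'
#' Plain commercial rounding. `base::round()` rounds half to even, which is
#' the wrong convention for pixel-size arithmetic here: 100 um at
#' 0.2528 um/px is 395.57 px and must become 396, and exact .5 ties go away
#' from zero.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a stage seed from a global seed and a stage name
#'
#' All randomness in the package flows from one explicit integer seed.
#' Per-stage seeds are derived by mixing the global seed with a hash of the
#' stage name, so re-running one stage is independent of execution order.
#' The result is always in `[0, 2^31 - 1)`.
#'
#' @param global_seed integer global seed.
#' @param stage character scalar naming the stage.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  # golden-ratio style integer mix, kept in 32-bit-safe range via %%
  s <- (as.numeric(global_seed) %% m) * 69069 %% m
  as.integer((s + h * 40503) %% m)
}

#' Even-odd (ray casting) point-in-polygon test
#'
#' Vectorized over points. The boundary itself is not treated specially;
#' callers that need boundary-inclusive behaviour nudge their test points
#' (see [tile_grid()]).
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((ys[i] > py) != (ys[j] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Signed polygon area (shoelace)
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Bilinear resize of an H x W x C image array
#'
#' Thin wrapper around [EBImage::resize()]. Input and output use the
#' row-major raster convention (dim 1 = y/rows, dim 2 = x/columns); both
#' sides are resized with bilinear filtering.
#'
#' @param img numeric array, H x W x C (or H x W).
#' @param side integer output side (square output).
#' @return array side x side x C.
#' @keywords internal
resize_bilinear <- function(img, side) {
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[1] == side && dim(img)[2] == side) return(img)
  out <- EBImage::resize(img, w = side, h = side, filter = "bilinear")
  array(as.numeric(out), c(side, side, dim(img)[3]))
}

#' Clamp numeric values to a range
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Write an 8-bit RGB array (values 0..255) as PNG
#' @keywords internal
write_image_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
  invisible(path)
}

#' Read a PNG as an 8-bit RGB array (values 0..255)
#' @keywords internal
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  round(x * 255)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
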