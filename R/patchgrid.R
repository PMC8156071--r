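# Grid tiling of annotated tissue regions into fixed-physical-size patches.
#
# Conventions (documented once, used everywhere): pixel coordinates are
# 0-based, x to the right, y down; a tile occupies the half-open square
# [x0, x0 + side) x [y0, y0 + side). Polygons are in pixel coordinates.

#' Patch side length in pixels for a physical patch size
#'
#' Converts a physical patch size (micrometres) to pixels at a given scan
#' scale, rounding half away from zero. At the reference scanning scale of
#' 100/395 um/px, a 100 um patch is exactly 395 px.
#'
#' @param patch_size_um physical patch side in micrometres (> 0).
#' @param um_per_px scan scale in micrometres per pixel (> 0).
#' @return integer pixel side length.
#' @examples
#' patch_side_px(100, 100 / 395)  # 395
#' patch_side_px(100, 1.0)        # 100
#' @export
patch_side_px <- function(patch_size_um, um_per_px) {
  stopifnot(is.numeric(patch_size_um), is.numeric(um_per_px))
  if (patch_size_um <= 0 || um_per_px <= 0) {
    stop("patch_size_um and um_per_px must both be positive")
  }
  as.integer(round_half_away(patch_size_um / um_per_px))
}

#' Construct an annotated image
#'
#' Bundles a raster with its physical scale and polygon annotations.
#' Polygon vertices outside the image bounds are clipped to the bounds with
#' a warning.
#'
#' @param pixels numeric H x W x 3 array (8-bit values 0..255).
#' @param um_per_px micrometres per pixel (> 0).
#' @param annotations list of annotations, each a list with elements
#'   `polygon` (n x 2 matrix, pixel coords), `class` (character) and
#'   `case_id` (character).
#' @return an object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, um_per_px, annotations) {
  stopifnot(length(dim(pixels)) == 3L, um_per_px > 0, is.list(annotations))
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  annotations <- lapply(annotations, function(a) {
    stopifnot(!is.null(a$polygon), !is.null(a$class), !is.null(a$case_id))
    p <- as.matrix(a$polygon)
    if (any(p[, 1] < 0 | p[, 1] > w | p[, 2] < 0 | p[, 2] > h)) {
      warning("annotation polygon for case ", a$case_id,
              " extends beyond image bounds; clipping vertices")
      p[, 1] <- clamp(p[, 1], 0, w)
      p[, 2] <- clamp(p[, 2], 0, h)
    }
    a$polygon <- p
    a
  })
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 annotations = annotations),
            class = "annotated_image")
}

#' Tile a polygon with an axis-aligned grid of fully contained squares
#'
#' Lays a non-overlapping grid of `patch_size_um`-sided squares over a
#' polygon, anchored at the polygon bounding-box top-left (rounded up to
#' whole pixels), with stride equal to the side. A tile is kept iff it lies
#' fully inside both the polygon and the image bounds: the four corners and
#' the centre must fall inside the polygon, with corners nudged a hair
#' towards the tile centre so that tiles exactly touching the polygon
#' boundary still count as inside. Output is row-major (left-to-right,
#' top-to-bottom).
#'
#' @param polygon n x 2 matrix of vertices in pixel coordinates.
#' @param patch_size_um physical tile side (um).
#' @param um_per_px scan scale (um/px).
#' @param image_bounds `c(width, height)` in pixels, or NULL for unbounded.
#' @param anchor optional `c(x, y)` grid anchor; defaults to the polygon
#'   bounding-box top-left.
#' @return data.frame with columns `x`, `y` (0-based integer tile origins)
#'   and `side_px`.
#' @export
tile_grid <- function(polygon, patch_size_um, um_per_px,
                      image_bounds = NULL, anchor = NULL) {
  polygon <- as.matrix(polygon)
  side <- patch_side_px(patch_size_um, um_per_px)
  empty <- data.frame(x = integer(0), y = integer(0), side_px = integer(0))
  if (nrow(polygon) < 3L || polygon_area(polygon) == 0) return(empty)

  if (is.null(anchor)) anchor <- c(min(polygon[, 1]), min(polygon[, 2]))
  x0 <- ceiling(anchor[1]); y0 <- ceiling(anchor[2])
  xmax <- max(polygon[, 1]); ymax <- max(polygon[, 2])
  nx <- floor((xmax - x0) / side); ny <- floor((ymax - y0) / side)
  if (nx < 1L || ny < 1L) return(empty)

  xs <- x0 + (seq_len(nx) - 1L) * side
  ys <- y0 + (seq_len(ny) - 1L) * side
  # row-major: y slow, x fast
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))

  if (!is.null(image_bounds)) {
    ok <- gx >= 0 & gy >= 0 &
      (gx + side) <= image_bounds[1] & (gy + side) <= image_bounds[2]
    gx <- gx[ok]; gy <- gy[ok]
  }
  if (length(gx) == 0L) return(empty)

  eps <- 1e-6 * side
  cx <- gx + side / 2; cy <- gy + side / 2
  keep <- point_in_polygon(cx, cy, polygon)
  for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    px <- gx + corner[1] * side; py <- gy + corner[2] * side
    # nudge towards the tile centre: boundary-touching corners pass
    px <- px + sign(cx - px) * eps
    py <- py + sign(cy - py) * eps
    keep <- keep & point_in_polygon(px, py, polygon)
  }
  out <- data.frame(x = as.integer(gx[keep]), y = as.integer(gy[keep]),
                    side_px = side)
  ord <- order(out$y, out$x)
  out[ord, , drop = FALSE]
}

#' Extract image patches from every annotation of an annotated image
#'
#' Runs [tile_grid()] for each annotation and crops the kept tiles.
#' Overlapping annotations are handled independently: each record carries
#' its own annotation's case and class, and duplicates across annotations
#' are not merged.
#'
#' @param image an [annotated_image()].
#' @param patch_size_um physical patch side (um), default 100.
#' @return list with elements
#'   \describe{
#'     \item{records}{list of patch records, each with `patch_id`,
#'       `case_id`, `true_class`, `tile` (side x side x 3 array, 0..255),
#'       `origin_px` and `side_px`.}
#'     \item{report}{data.frame of per-case patch counts.}
#'   }
#' @export
extract_patches <- function(image, patch_size_um = 100) {
  stopifnot(inherits(image, "annotated_image"))
  if (is.null(image$um_per_px) || !is.finite(image$um_per_px)) {
    stop("annotated image is missing its um_per_px scale")
  }
  if (length(image$annotations) == 0L) {
    stop("annotated image has no annotations")
  }
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  records <- list()
  k <- 0L
  for (a in image$annotations) {
    tiles <- tile_grid(a$polygon, patch_size_um, image$um_per_px,
                       image_bounds = c(w, h))
    if (nrow(tiles) == 0L) next
    for (i in seq_len(nrow(tiles))) {
      k <- k + 1L
      x <- tiles$x[i]; y <- tiles$y[i]; s <- tiles$side_px[i]
      records[[k]] <- list(
        patch_id = sprintf("%s_tile%d", a$case_id, i),
        case_id = a$case_id,
        true_class = a$class,
        tile = image$pixels[(y + 1L):(y + s), (x + 1L):(x + s), , drop = FALSE],
        origin_px = c(x = x, y = y),
        side_px = s
      )
    }
  }
  report <- patch_report(records)
  # annotated cases that produced no tiles still appear, with a zero count
  ann_cases <- unique(data.frame(
    case_id = vapply(image$annotations, `[[`, "", "case_id"),
    true_class = vapply(image$annotations, `[[`, "", "class")
  ))
  missing <- !(ann_cases$case_id %in% report$case_id)
  if (any(missing)) {
    report <- rbind(report,
                    cbind(ann_cases[missing, , drop = FALSE], n_patches = 0L))
    report <- report[order(report$case_id), , drop = FALSE]
  }
  rownames(report) <- NULL
  list(records = records, report = report)
}

#' Per-case patch-count report
#'
#' @param records list of patch records (as from [extract_patches()]).
#' @return data.frame with columns `case_id`, `true_class`, `n_patches`.
#' @export
patch_report <- function(records) {
  if (length(records) == 0L) {
    return(data.frame(case_id = character(0), true_class = character(0),
                      n_patches = integer(0)))
  }
  idx <- data.frame(
    case_id = vapply(records, `[[`, "", "case_id"),
    true_class = vapply(records, `[[`, "", "true_class")
  )
  agg <- aggregate(list(n_patches = seq_len(nrow(idx))), by = idx, FUN = length)
  agg[order(agg$case_id), , drop = FALSE]
}

#' Flag cases that fall below a minimum patch count
#'
#' The extraction protocol aims for at least 10 patches per patient; cases
#' below the minimum are flagged for review (strict `<`).
#'
#' @param report data.frame with `case_id` and `n_patches` columns.
#' @param minimum integer minimum patch count (default 10).
#' @return character vector of flagged case ids.
#' @export
flag_low_patch_cases <- function(report, minimum = 10L) {
  stopifnot(nrow(report) > 0, all(c("case_id", "n_patches") %in% names(report)))
  report$case_id[report$n_patches < minimum]
}
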