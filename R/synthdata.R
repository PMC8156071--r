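# Synthetic H&E-like lymph-node substrate.
#
# Three morphology groups are emulated at the level a patch classifier
# needs: small uniform lymphocyte nuclei (SLL/CLL), large pleomorphic
# nuclei (DLBCL), and mixed reactive lymph node (tumor-free reference, in
# lung / colon / pancreas variants; the lung variant carries dark
# anthracosis pigment clumps, the others differ by pale sinus spaces).
# Nuclei are rendered as jittered ellipses on an eosin-pink background —
# the simplest texture that preserves the class-ordered morphology
# (DLBCL nuclei strictly larger than SLL/CLL nuclei).
#
# All sizes are physical (micrometres); the raster scale is um_per_px.
# The default scale 100/395 um/px makes a 100 um patch exactly 395 px.

DEFAULT_UM_PER_PX <- 100 / 395

#' Morphology parameters of one synthetic tissue class
#'
#' Defaults are artifact choices informed by standard histology: small
#' lymphocyte nuclei around 6.5 um, large-cell lymphoma nuclei around
#' 15 um, reactive lymph node in between; densities per 100 x 100 um are
#' chosen so rendered chromatin coverage looks plausible and the classes
#' stay machine-separable.
#'
#' @param class_label one of the training classes (see [TRAINING_CLASSES]).
#' @param nucleus_diameter_um length-2 `c(mean, sd)` in micrometres.
#' @param nucleus_density nuclei per 100 x 100 um tissue area.
#' @param eccentricity_range length-2 interval in `[0, 1)`.
#' @param pigment_clump_rate anthracosis clumps per 100 x 100 um (lung
#'   lymph nodes only by default).
#' @param sinus_space_rate pale sinus ellipses per 100 x 100 um (reactive
#'   lymph-node variants).
#' @param stain_palette list with `nucleus`, `background` RGB triplets
#'   (0..255) and `noise_sd` (8-bit units).
#' @return object of class `morphology_params`.
#' @export
morphology_params <- function(class_label,
                              nucleus_diameter_um = NULL,
                              nucleus_density = NULL,
                              eccentricity_range = NULL,
                              pigment_clump_rate = NULL,
                              sinus_space_rate = NULL,
                              stain_palette = NULL) {
  defaults <- list(
    SLL_CLL = list(d = c(6.5, 0.8), dens = 70, ecc = c(0, 0.3),
                   pig = 0, sinus = 0),
    DLBCL = list(d = c(15, 2.5), dens = 22, ecc = c(0.1, 0.6),
                 pig = 0, sinus = 0),
    LN_LUNG = list(d = c(7.5, 1.5), dens = 45, ecc = c(0, 0.5),
                   pig = 1.5, sinus = 0.5),
    LN_COLON = list(d = c(7.5, 1.5), dens = 45, ecc = c(0, 0.5),
                    pig = 0, sinus = 1.0),
    LN_PANCREAS = list(d = c(7.5, 1.5), dens = 50, ecc = c(0, 0.5),
                       pig = 0, sinus = 0.5)
  )
  if (!class_label %in% names(defaults)) {
    stop("unknown class label: ", class_label)
  }
  d <- defaults[[class_label]]
  p <- list(
    class_label = class_label,
    nucleus_diameter_um = nucleus_diameter_um %||% d$d,
    nucleus_density = nucleus_density %||% d$dens,
    eccentricity_range = eccentricity_range %||% d$ecc,
    pigment_clump_rate = pigment_clump_rate %||% d$pig,
    sinus_space_rate = sinus_space_rate %||% d$sinus,
    stain_palette = stain_palette %||% list(
      nucleus = c(72, 52, 124),       # hematoxylin purple
      background = c(235, 205, 215),  # eosin pink
      noise_sd = 6)
  )
  stopifnot(p$nucleus_diameter_um[1] > 0, p$nucleus_density >= 0,
            p$eccentricity_range[1] >= 0, p$eccentricity_range[2] < 1,
            p$pigment_clump_rate >= 0, p$sinus_space_rate >= 0)
  structure(p, class = "morphology_params")
}

# linear pixel indices (into an h x w matrix) of a filled rotated ellipse
ellipse_pixels <- function(cx, cy, a_px, b_px, theta, h, w) {
  r <- max(a_px, b_px)
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  idx <- outer(ys, (xs - 1L) * h, `+`)
  idx[inside]
}

# core renderer over an arbitrary h x w raster (no seed handling here);
# draws into per-channel matrices so per-nucleus updates stay in place
render_region <- function(params, h_px, w_px, um_per_px) {
  pal <- params$stain_palette
  chans <- lapply(pal$background, function(v) matrix(v, h_px, w_px))
  mask <- matrix(FALSE, h_px, w_px)
  area_units <- (h_px * w_px) * um_per_px^2 / 1e4  # in 100x100 um units

  n_sinus <- stats::rpois(1, params$sinus_space_rate * area_units)
  sinus_col <- clamp(pal$background + 14, 0, 255)
  for (i in seq_len(n_sinus)) {
    d_px <- stats::runif(1, 10, 25) / um_per_px
    idx <- ellipse_pixels(stats::runif(1, 1, w_px), stats::runif(1, 1, h_px),
                          d_px / 2, d_px / 2 * stats::runif(1, 0.4, 0.8),
                          stats::runif(1, 0, pi), h_px, w_px)
    # sinus spaces do not enter the nucleus mask
    for (ch in 1:3) chans[[ch]][idx] <- sinus_col[ch]
  }

  lam <- params$nucleus_density * area_units
  n_nuc <- stats::rpois(1, lam)
  if (lam >= 1 && n_nuc == 0L) n_nuc <- 1L
  if (params$nucleus_density == 0) n_nuc <- 0L
  for (i in seq_len(n_nuc)) {
    d_um <- max(stats::rnorm(1, params$nucleus_diameter_um[1],
                             params$nucleus_diameter_um[2]),
                0.4 * params$nucleus_diameter_um[1])
    ecc <- stats::runif(1, params$eccentricity_range[1],
                        params$eccentricity_range[2])
    a <- (d_um / um_per_px) / 2
    b <- a * sqrt(1 - ecc^2)
    col <- clamp(pal$nucleus * stats::runif(1, 0.85, 1.2), 0, 255)
    idx <- ellipse_pixels(stats::runif(1, 1, w_px), stats::runif(1, 1, h_px),
                          a, b, stats::runif(1, 0, pi), h_px, w_px)
    for (ch in 1:3) chans[[ch]][idx] <- col[ch]
    mask[idx] <- TRUE
  }

  n_clump <- stats::rpois(1, params$pigment_clump_rate * area_units)
  pigment_col <- c(32, 28, 24)
  for (i in seq_len(n_clump)) {
    cx <- stats::runif(1, 1, w_px); cy <- stats::runif(1, 1, h_px)
    for (j in seq_len(stats::rpois(1, 5) + 3L)) {
      d_px <- stats::runif(1, 1.2, 3) / um_per_px
      idx <- ellipse_pixels(cx + stats::rnorm(1, 0, 4 / um_per_px),
                            cy + stats::rnorm(1, 0, 4 / um_per_px),
                            d_px / 2, d_px / 2, 0, h_px, w_px)
      # pigment is extracellular: not in the nucleus mask
      for (ch in 1:3) chans[[ch]][idx] <- pigment_col[ch]
    }
  }

  img <- array(c(chans[[1]], chans[[2]], chans[[3]]), c(h_px, w_px, 3))
  if (pal$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, pal$noise_sd), dim(img))
  }
  img <- round(clamp(img, 0, 255))
  attr(img, "nucleus_mask") <- mask
  img
}

#' Render one synthetic tissue patch
#'
#' Deterministic for a fixed seed. The returned 8-bit RGB array carries the
#' rendered nucleus footprint as a logical `"nucleus_mask"` attribute
#' (pigment clumps and sinus spaces are extracellular and excluded from the
#' mask).
#'
#' @param params a [morphology_params()].
#' @param size_px square side in pixels (>= 32).
#' @param seed integer seed.
#' @param um_per_px raster scale (default 100/395: a 100 um patch is
#'   395 px).
#' @return size_px x size_px x 3 array with values 0..255 and attribute
#'   `nucleus_mask`.
#' @export
render_patch <- function(params, size_px = 395L, seed = 1L,
                         um_per_px = DEFAULT_UM_PER_PX) {
  stopifnot(inherits(params, "morphology_params"))
  if (!is.numeric(size_px) || size_px < 32) {
    stop("size_px must be at least 32")
  }
  withr::with_seed(as.integer(seed),
                   render_region(params, as.integer(size_px),
                                 as.integer(size_px), um_per_px))
}

#' Configuration of a synthetic cohort
#'
#' @param cases_per_class number of cases per class label.
#' @param patches_per_case length-2 integer range; each case's extractable
#'   patch count is drawn from it (lower bound >= 1).
#' @param um_per_px raster scale (default 100/395).
#' @param patch_size_um physical patch side used to shape the tissue
#'   regions (default 100).
#' @param classes class labels to generate (default all five).
#' @param seed integer seed.
#' @return object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(cases_per_class = 20L,
                                    patches_per_case = c(10L, 250L),
                                    um_per_px = DEFAULT_UM_PER_PX,
                                    patch_size_um = 100,
                                    classes = TRAINING_CLASSES,
                                    seed = 1L) {
  stopifnot(patches_per_case[1] >= 1, patches_per_case[2] >= patches_per_case[1],
            um_per_px > 0, cases_per_class >= 0)
  structure(list(cases_per_class = as.integer(cases_per_class),
                 patches_per_case = as.integer(patches_per_case),
                 um_per_px = um_per_px, patch_size_um = patch_size_um,
                 classes = classes, seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Generate a synthetic annotated cohort
#'
#' Each case gets one tissue image (a rectangular tissue region of
#' morphology-rendered parenchyma on a glass-colored slide margin), one
#' class-labeled polygon annotation covering the tissue region, and a
#' manifest row. Tissue regions are whole multiples of the patch size, so
#' the number of extractable patches is controlled exactly and falls within
#' the configured range.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list with `images` (named list of [annotated_image()]),
#'   `manifest` (data.frame: `case_id`, `class`, `n_patches_target`) and
#'   the `config`.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (config$cases_per_class == 0L) {
    warning("zero cases per class requested; returning an empty cohort")
    return(list(images = list(),
                manifest = data.frame(case_id = character(0),
                                      class = character(0),
                                      n_patches_target = integer(0)),
                config = config))
  }
  side <- patch_side_px(config$patch_size_um, config$um_per_px)
  margin <- max(8L, round(side / 8))
  lo <- config$patches_per_case[1]; hi <- config$patches_per_case[2]
  glass <- c(250, 248, 250)

  images <- list(); manifest <- list()
  for (cls in config$classes) {
    params <- morphology_params(cls)
    for (k in seq_len(config$cases_per_class)) {
      case_id <- sprintf("%s_%03d", cls, k)
      case_seed <- stage_seed(config$seed, paste0("case_", case_id))
      withr::with_seed(case_seed, {
        n_target <- sample(lo:hi, 1L)
        r <- max(1L, floor(sqrt(n_target)))
        cc <- as.integer(clamp(round(n_target / r),
                               ceiling(lo / r), floor(hi / r)))
        h <- r * side + 2L * margin
        w <- cc * side + 2L * margin
        img <- array(rep(glass, each = h * w), c(h, w, 3))
        tissue <- render_region(params, r * side, cc * side, config$um_per_px)
        img[(margin + 1L):(margin + r * side),
            (margin + 1L):(margin + cc * side), ] <- tissue
        poly <- cbind(x = c(margin, margin + cc * side,
                            margin + cc * side, margin),
                      y = c(margin, margin,
                            margin + r * side, margin + r * side))
        images[[case_id]] <- annotated_image(
          img, config$um_per_px,
          list(list(polygon = poly, class = cls, case_id = case_id)))
        attr(images[[case_id]], "nucleus_mask") <- attr(tissue, "nucleus_mask")
        manifest[[length(manifest) + 1L]] <-
          data.frame(case_id = case_id, class = cls,
                     n_patches_target = r * cc)
      })
    }
  }
  list(images = images, manifest = do.call(rbind, manifest), config = config)
}

#' Write a synthetic cohort to disk
#'
#' PNG image, GeoJSON FeatureCollection annotation (one polygon feature
#' with `case_id` and `class` properties) per case, plus a `manifest.csv`
#' (`case_id`, `class`, `image_path`, `annotation_path`).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (invisibly), as written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(cohort$images), function(cid) {
    im <- cohort$images[[cid]]
    img_path <- file.path(dir, paste0(cid, ".png"))
    ann_path <- file.path(dir, paste0(cid, ".geojson"))
    write_image_png(im$pixels, img_path)
    ann <- im$annotations[[1]]
    poly <- rbind(ann$polygon, ann$polygon[1, ])  # closed ring
    fc <- list(
      type = "FeatureCollection",
      features = list(list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(poly)),
                                                  function(i) poly[i, ]))),
        properties = list(case_id = ann$case_id, class = ann$class,
                          um_per_px = im$um_per_px)
      ))
    )
    jsonlite::write_json(fc, ann_path, auto_unbox = TRUE, digits = NA)
    data.frame(case_id = cid,
               class = cohort$manifest$class[cohort$manifest$case_id == cid],
               image_path = img_path, annotation_path = ann_path)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one case back as an annotated image
#'
#' @param image_path PNG path.
#' @param annotation_path GeoJSON path as written by [write_cohort()].
#' @return an [annotated_image()].
#' @export
read_annotated_image <- function(image_path, annotation_path) {
  px <- read_image_png(image_path)
  fc <- jsonlite::read_json(annotation_path, simplifyVector = TRUE)
  anns <- lapply(seq_len(nrow(fc$features)), function(i) {
    geom <- fc$features$geometry
    coords <- geom$coordinates[[i]]
    poly <- if (is.list(coords)) do.call(rbind, coords[[1]]) else coords[1, , ]
    props <- fc$features$properties
    list(polygon = poly[-nrow(poly), , drop = FALSE],
         class = props$class[i], case_id = props$case_id[i])
  })
  um <- fc$features$properties$um_per_px[1]
  annotated_image(px, um, anns)
}

#' Configuration of synthetic per-patch prediction fixtures
#'
#' Controls a simplex-valued probability generator with independent knobs
#' for patch accuracy (probability that the argmax hits the true class),
#' how peaked the vectors are, and how much more confident correct patches
#' are than incorrect ones.
#'
#' @param patch_accuracy target argmax accuracy, in `(0, 1]`.
#' @param confidence_concentration positive Dirichlet concentration; larger
#'   is flatter, smaller is more peaked.
#' @param confidence_correct_boost multiplier (>= 1) applied to the
#'   true-class component of correct patches before renormalization.
#' @param seed integer seed.
#' @return object of class `prediction_fixture_config`.
#' @export
prediction_fixture_config <- function(patch_accuracy = 0.8,
                                      confidence_concentration = 0.5,
                                      confidence_correct_boost = 2,
                                      seed = 1L) {
  if (!is.numeric(patch_accuracy) || patch_accuracy <= 0 || patch_accuracy > 1) {
    stop("patch_accuracy must lie in (0, 1]")
  }
  stopifnot(confidence_concentration > 0, confidence_correct_boost >= 1)
  structure(list(patch_accuracy = patch_accuracy,
                 confidence_concentration = confidence_concentration,
                 confidence_correct_boost = confidence_correct_boost,
                 seed = as.integer(seed)),
            class = "prediction_fixture_config")
}

#' Generate a synthetic per-patch prediction table
#'
#' For every case in the manifest, draws `n_patches_per_case` probability
#' vectors over `class_list` from a symmetric Dirichlet. A patch is
#' "correct" with probability `patch_accuracy`: its largest component is
#' moved onto the true class and multiplied by the confidence boost
#' (renormalized); otherwise the largest component is moved onto a random
#' wrong class. Row sums are exactly 1 up to floating-point addition.
#'
#' @param manifest data.frame with `case_id` and `class` columns; every
#'   class must appear in `class_list`.
#' @param n_patches_per_case integer scalar, or length-2 range to draw
#'   from per case.
#' @param config a [prediction_fixture_config()].
#' @param class_list ordered class vocabulary (default [TRAINING_CLASSES]).
#' @return prediction table: `patch_id`, `case_id`, `true_class`,
#'   `p_<class>` columns.
#' @export
generate_prediction_fixture <- function(manifest, n_patches_per_case,
                                        config = prediction_fixture_config(),
                                        class_list = TRAINING_CLASSES) {
  stopifnot(inherits(config, "prediction_fixture_config"),
            all(manifest$class %in% class_list))
  k <- length(class_list)
  withr::with_seed(config$seed, {
    per_case <- lapply(seq_len(nrow(manifest)), function(i) {
      n <- if (length(n_patches_per_case) == 2L) {
        sample(n_patches_per_case[1]:n_patches_per_case[2], 1L)
      } else as.integer(n_patches_per_case)
      true_idx <- match(manifest$class[i], class_list)
      g <- matrix(stats::rgamma(n * k, shape = config$confidence_concentration),
                  n, k)
      p <- g / rowSums(g)
      correct <- stats::runif(n) < config$patch_accuracy
      top <- max.col(p, ties.method = "first")
      for (j in seq_len(n)) {
        target <- if (correct[j]) true_idx else {
          wrong <- setdiff(seq_len(k), true_idx)
          wrong[sample.int(length(wrong), 1L)]
        }
        tmp <- p[j, target]; p[j, target] <- p[j, top[j]]; p[j, top[j]] <- tmp
        if (correct[j] && config$confidence_correct_boost > 1) {
          p[j, target] <- p[j, target] * config$confidence_correct_boost
          p[j, ] <- p[j, ] / sum(p[j, ])
        }
      }
      df <- data.frame(
        patch_id = sprintf("%s_patch%04d", manifest$case_id[i], seq_len(n)),
        case_id = manifest$case_id[i],
        true_class = manifest$class[i])
      colnames(p) <- paste0("p_", class_list)
      cbind(df, as.data.frame(p))
    })
  })
  out <- do.call(rbind, per_case)
  rownames(out) <- NULL
  out
}
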