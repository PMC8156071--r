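# SmoothGrad saliency maps.
#
# The map for a patch and a target class is the average, over n Gaussian
# perturbations of the input, of the gradient of the target-class score
# with respect to the input pixels. The adaptation used here: absolute
# gradients, collapsed across color channels by the per-pixel maximum, and
# min-max normalized to [0, 1) (the divisor carries a small epsilon so the
# supremum is strictly below 1; an all-constant gradient field maps to an
# all-zero heatmap).

SALIENCY_EPS <- 2^-23

#' SmoothGrad configuration
#'
#' @param noise_fraction Gaussian noise standard deviation as a fraction of
#'   the input intensity range (default 0.005, i.e. 0.5%).
#' @param n_samples number of perturbed copies averaged (default 50).
#' @param seed integer seed.
#' @return object of class `saliency_config`.
#' @export
saliency_config <- function(noise_fraction = 0.005, n_samples = 50L,
                            seed = 1L) {
  stopifnot(noise_fraction >= 0, n_samples >= 1)
  structure(list(noise_fraction = noise_fraction,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "saliency_config")
}

#' SmoothGrad heatmap of a patch for a target class
#'
#' Draws `n_samples` Gaussian perturbations with standard deviation
#' `noise_fraction` times the input intensity range (1 for unit-scaled
#' images, 255 for 8-bit images), averages the input gradients of the
#' target-class score via [input_gradient()], takes absolute values,
#' collapses channels by the per-pixel maximum, and min-max normalizes to
#' `[0, 1)`. Deterministic for a fixed seed; with `noise_fraction = 0` the
#' result equals the vanilla single-gradient map.
#'
#' @param model a model with an [input_gradient()] method.
#' @param patch H x W x 3 array in the model's input shape, values in
#'   `[0, 1]` or 0..255.
#' @param target_class integer class index whose score is explained.
#' @param config a [saliency_config()].
#' @return object of class `saliency_map`: `heatmap` (H x W matrix in
#'   `[0, 1)`), `target_class`, `config`.
#' @export
smoothgrad <- function(model, patch, target_class,
                       config = saliency_config()) {
  stopifnot(inherits(config, "saliency_config"), length(dim(patch)) == 3L)
  rng <- if (max(patch) > 1) 255 else 1
  sd <- config$noise_fraction * rng
  acc <- array(0, dim(patch))
  withr::with_seed(config$seed, {
    for (s in seq_len(config$n_samples)) {
      noisy <- if (sd > 0) {
        patch + array(stats::rnorm(length(patch), 0, sd), dim(patch))
      } else patch
      acc <- acc + input_gradient(model, noisy, target_class)
    }
  })
  g <- abs(acc / config$n_samples)
  h <- pmax(g[, , 1], g[, , 2], g[, , 3])     # per-pixel channel max
  lo <- min(h); hi <- max(h)
  heat <- if (hi > lo) (h - lo) / (hi - lo + SALIENCY_EPS) else h * 0
  structure(list(heatmap = heat, target_class = target_class,
                 config = config),
            class = "saliency_map")
}

#' Overlay a saliency heatmap on its patch
#'
#' Alpha-blends a color-mapped heatmap (inferno palette) over the original
#' image and quantizes to 8 bits, so a PNG round trip is lossless. With
#' `opacity = 0` the original image is returned bit-exactly.
#'
#' @param patch H x W x 3 array, values 0..255 (or `[0, 1]`, rescaled).
#' @param map a `saliency_map` with matching spatial shape.
#' @param opacity blend weight of the heatmap in `[0, 1]` (default 0.5).
#' @return H x W x 3 array of 8-bit values (0..255).
#' @export
overlay <- function(patch, map, opacity = 0.5) {
  stopifnot(inherits(map, "saliency_map"), opacity >= 0, opacity <= 1)
  if (max(patch) <= 1) patch <- patch * 255
  patch <- round(clamp(patch, 0, 255))
  h <- map$heatmap
  if (!all(dim(patch)[1:2] == dim(h))) {
    stop("patch and heatmap shapes do not match")
  }
  if (opacity == 0) return(patch)
  pal <- grDevices::hcl.colors(256L, "Inferno")
  cols <- grDevices::col2rgb(pal[pmin(255L, floor(h * 256)) + 1L])
  cmap <- array(NA_real_, dim(patch))
  for (ch in 1:3) cmap[, , ch] <- matrix(cols[ch, ], dim(h)[1], dim(h)[2])
  round((1 - opacity) * patch + opacity * cmap)
}
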