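test_that("patch_side_px converts physical size to pixels with half-away rounding", {
  expect_identical(patch_side_px(100, 100 / 395), 395L)
  expect_identical(patch_side_px(100, 1.0), 100L)
  expect_identical(patch_side_px(100, 0.2528), 396L)  # round(395.57)
  expect_error(patch_side_px(0, 1), "positive")
  expect_error(patch_side_px(100, -0.25), "positive")
})

test_that("an exactly tileable square yields the full non-overlapping grid", {
  poly <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))  # 1000x1000 um at 1 um/px
  tiles <- tile_grid(poly, 100, 1.0, image_bounds = c(2000, 2000))
  expect_equal(nrow(tiles), 100)
  expect_true(all(tiles$side_px == 100L))
  # stride = side: no two tiles overlap
  key <- paste(tiles$x %/% 100, tiles$y %/% 100)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(tiles$x %% 100 == 0 & tiles$y %% 100 == 0))
  # row-major order
  expect_equal(tiles$y, rep(seq(0, 900, 100), each = 10))
})

test_that("a polygon smaller than one tile yields no tiles", {
  poly <- cbind(c(0, 90, 90, 0), c(0, 0, 90, 90))
  expect_equal(nrow(tile_grid(poly, 100, 1.0, c(500, 500))), 0)
})

test_that("degenerate polygons yield an empty grid", {
  expect_equal(nrow(tile_grid(cbind(c(0, 500, 1000), c(0, 0, 0)),
                              100, 1.0, c(2000, 2000))), 0)
})

test_that("circle tile counts match the rasterized containment oracle", {
  for (r_um in c(300, 500, 730)) {
    cx <- r_um + 7.3; cy <- r_um + 11.9
    theta <- seq(0, 2 * pi, length.out = 720)[-720]
    poly <- cbind(cx + r_um * cos(theta), cy + r_um * sin(theta))
    tiles <- tile_grid(poly, 100, 1.0, image_bounds = c(4000, 4000))
    # oracle works on the circle equation itself, not the polygon
    expected <- oracle_tile_count(
      function(x, y) (x - cx)^2 + (y - cy)^2 <= r_um^2,
      c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2])),
      100)
    expect_equal(nrow(tiles), expected, info = paste("radius", r_um))
  }
})

test_that("kept tiles lie fully inside the polygon (rasterized mask check)", {
  withr::with_seed(41, {
    for (trial in 1:5) {
      # random convex-ish blob polygon
      th <- sort(runif(8, 0, 2 * pi))
      rad <- runif(8, 250, 450)
      poly <- cbind(500 + rad * cos(th), 500 + rad * sin(th))
      tiles <- tile_grid(poly, 100, 1.0, image_bounds = c(1000, 1000))
      if (nrow(tiles) == 0) next
      for (i in seq_len(nrow(tiles))) {
        xs <- tiles$x[i] + c(1, tiles$side_px[i]) - 0.5
        ys <- tiles$y[i] + c(1, tiles$side_px[i]) - 0.5
        pts <- expand.grid(x = xs, y = ys)  # interior pixel extremes
        inside <- lymphopatch:::point_in_polygon(pts$x, pts$y, poly)
        expect_true(all(inside))
      }
    }
  })
})

test_that("shrinking a polygon never increases its tile count", {
  withr::with_seed(42, {
    for (trial in 1:10) {
      th <- sort(runif(10, 0, 2 * pi))
      rad <- runif(10, 300, 500)
      big <- cbind(600 + rad * cos(th), 600 + rad * sin(th))
      shrink <- runif(1, 0.5, 0.95)
      small <- cbind(600 + shrink * (big[, 1] - 600),
                     600 + shrink * (big[, 2] - 600))
      n_big <- nrow(tile_grid(big, 100, 1.0, c(1200, 1200)))
      n_small <- nrow(tile_grid(small, 100, 1.0, c(1200, 1200)))
      expect_lte(n_small, n_big)
    }
  })
})

test_that("extract_patches yields one record per kept tile with correct identity", {
  px <- array(128, c(1200, 1200, 3))
  poly <- cbind(c(50, 1050, 1050, 50), c(50, 50, 1050, 1050))
  im <- annotated_image(px, 1.0, list(
    list(polygon = poly, class = "DLBCL", case_id = "caseA")))
  ex <- extract_patches(im, 100)
  expect_length(ex$records, 100)
  expect_true(all(vapply(ex$records, `[[`, "", "case_id") == "caseA"))
  expect_true(all(vapply(ex$records, `[[`, "", "true_class") == "DLBCL"))
  expect_equal(ex$report$n_patches, 100L)
  r <- ex$records[[1]]
  expect_equal(dim(r$tile), c(100, 100, 3))
})

test_that("overlapping annotations of different cases stay independent", {
  px <- array(100, c(500, 500, 3))
  poly <- cbind(c(0, 300, 300, 0), c(0, 0, 300, 300))
  im <- annotated_image(px, 1.0, list(
    list(polygon = poly, class = "DLBCL", case_id = "caseA"),
    list(polygon = poly, class = "SLL_CLL", case_id = "caseB")))
  ex <- extract_patches(im, 100)
  expect_length(ex$records, 18)  # 9 tiles per annotation, not merged
  expect_setequal(unique(vapply(ex$records, `[[`, "", "case_id")),
                  c("caseA", "caseB"))
})

test_that("extraction counts over a synthetic cohort equal per-case tile counts", {
  co <- generate_cohort(synthetic_cohort_config(
    cases_per_class = 1, patches_per_case = c(4, 12), um_per_px = 1,
    classes = c("SLL_CLL", "DLBCL"), seed = 3))
  total <- 0L
  for (cid in names(co$images)) {
    im <- co$images[[cid]]
    a <- im$annotations[[1]]
    total <- total + nrow(tile_grid(a$polygon, 100, im$um_per_px,
                                    c(dim(im$pixels)[2], dim(im$pixels)[1])))
  }
  n_extracted <- sum(vapply(names(co$images), function(cid) {
    length(extract_patches(co$images[[cid]])$records)
  }, 0L))
  expect_equal(n_extracted, total)
})

test_that("out-of-bounds polygons are clipped with a warning", {
  px <- array(0, c(100, 100, 3))
  expect_warning(
    annotated_image(px, 1, list(list(
      polygon = cbind(c(-10, 150, 150, -10), c(0, 0, 90, 90)),
      class = "DLBCL", case_id = "c1"))),
    "clipping")
})

test_that("flag_low_patch_cases applies a strict minimum", {
  rep1 <- data.frame(case_id = c("A", "B"), n_patches = c(10L, 9L))
  expect_equal(flag_low_patch_cases(rep1, 10), "B")
  rep2 <- data.frame(case_id = c("A", "B"), n_patches = c(12L, 10L))
  expect_equal(flag_low_patch_cases(rep2, 10), character(0))
  # Table-1-like counts, sweep of minima, vs direct filter
  counts <- c(4, 7, 33, 4, 2, 231, 278, 238, 222, 245, 146, 108)
  rep3 <- data.frame(case_id = sprintf("c%02d", seq_along(counts)),
                     n_patches = counts)
  for (m in c(2, 5, 10, 100)) {
    expect_equal(flag_low_patch_cases(rep3, m),
                 rep3$case_id[counts < m], info = paste("minimum", m))
  }
})
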