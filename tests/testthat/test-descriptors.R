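# Build a nucleus_region directly from a filled raster shape, bypassing
# image segmentation, so descriptor math is tested in isolation.
region_from_mask <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  px <- which(lab == 1, arr.ind = TRUE)
  ct <- EBImage::ocontour(lab)[[1]] + 1L
  ell <- fit_ellipse_lsq(ct)
  if (is.null(ell)) ell <- wsirisk:::moment_ellipse(px)
  hull_idx <- grDevices::chull(ct[, 1], ct[, 2])
  structure(list(pixels = px, area = nrow(px), contour = ct, ellipse = ell,
                 hull = ct[hull_idx, , drop = FALSE],
                 bbox = c(rmin = min(px[, 1]), rmax = max(px[, 1]),
                          cmin = min(px[, 2]), cmax = max(px[, 2]))),
            class = "nucleus_region")
}

disk_mask <- function(r, n = 2 * r + 11) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

ellipse_mask <- function(a, b, n = 2 * a + 11) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) ((j - ctr) / a)^2 + ((i - ctr) / b)^2 <= 1)
}

test_that("a rasterized disk has circular descriptors", {
  d <- nucleus_descriptors(region_from_mask(disk_mask(20)))
  expect_length(d, 27)
  expect_identical(names(d), shape_descriptor_names())
  expect_lt(abs(d["circularity"] - 1), 0.1)
  expect_gte(d["solidity"], 0.98)
  expect_lt(abs(d["area"] - pi * 400) / (pi * 400), 0.05)
  expect_lt(abs(d["aspect_ratio"] - 1), 0.05)
  expect_lt(abs(d["eccentricity"]), 0.25)
  expect_lt(abs(d["equiv_diameter"] - 40) / 40, 0.05)
  expect_lt(abs(d["feret_max"] - 41) / 41, 0.05)
  expect_true(all(d > 0))
})

test_that("a planted 3:1 ellipse reports the right aspect ratio", {
  d <- nucleus_descriptors(region_from_mask(ellipse_mask(30, 10)))
  expect_lt(abs(d["aspect_ratio"] - 3) / 3, 0.10)
  # raster widening is about half a pixel per side
  expect_lt(abs(d["major_axis"] - 60), 2)
  expect_lt(abs(d["minor_axis"] - 20), 2)
  expect_equal(unname(d["solidity"]), 1)  # convex raster region
})

test_that("descriptors scale correctly with nucleus size", {
  d1 <- nucleus_descriptors(region_from_mask(ellipse_mask(12, 8)))
  d2 <- nucleus_descriptors(region_from_mask(ellipse_mask(24, 16)))
  expect_lt(abs(d2["major_axis"] / d1["major_axis"] - 2), 0.05 * 2)
  expect_lt(abs(d2["minor_axis"] / d1["minor_axis"] - 2), 0.05 * 2)
  expect_lt(abs(d2["area"] / d1["area"] - 4), 0.05 * 4)
  expect_lt(abs(d2["perimeter"] / d1["perimeter"] - 2), 0.05 * 2)
})

test_that("aggregation emits the five summaries with exact arithmetic", {
  tbl <- matrix(c(2, 4, 8), 3, 1, dimnames = list(NULL, "area"))
  agg <- aggregate_shape_features(tbl)
  expect_equal(unname(agg["area_mean"]), 14 / 3)
  expect_equal(unname(agg["area_min"]), 2)
  expect_equal(unname(agg["area_max"]), 8)
  expect_equal(unname(agg["area_mrate"]), 0.25)
  expect_equal(unname(agg["area_sd"]), sd(c(2, 4, 8)))
  # identical rows: every mrate 1, every sd 0
  same <- matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  agg2 <- aggregate_shape_features(same)
  expect_equal(unname(agg2[grepl("_mrate$", names(agg2))]), rep(1, 3))
  expect_equal(unname(agg2[grepl("_sd$", names(agg2))]), rep(0, 3))
  # single nucleus: sd defined as 0, mrate 1
  one <- matrix(1:27, 1, 27, dimnames = list(NULL, shape_descriptor_names()))
  agg3 <- aggregate_shape_features(one)
  expect_length(agg3, 135)
  expect_equal(unname(agg3[grepl("_sd$", names(agg3))]), rep(0, 27))
  expect_error(aggregate_shape_features(same[0, , drop = FALSE]),
               "no nuclei sampled")
})

test_that("mrate is 1 exactly when and only when a descriptor is constant", {
  tbl <- cbind(const = rep(3, 5), varies = c(1, 2, 3, 4, 5))
  agg <- aggregate_shape_features(tbl)
  expect_equal(unname(agg["const_mrate"]), 1)
  expect_lt(agg["varies_mrate"], 1)
})
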