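#' Names of the 27 per-nucleus shape descriptors
#' @return character vector of length 27.
#' @export
shape_descriptor_names <- function() {
  c("area", "perimeter", "perim_area_ratio", "equiv_diameter", "circularity",
    "convex_area", "solidity", "convexity", "extent", "eccentricity",
    "major_axis", "minor_axis", "aspect_ratio", "ellipse_residual",
    "feret_max", "feret_min", "feret_ratio", "bbox_aspect", "compactness",
    "sphericity", paste0("hu", 1:7))
}

polygon_perimeter <- function(pts) {
  p2 <- rbind(pts, pts[1, , drop = FALSE])
  sum(sqrt(rowSums((p2[-1, , drop = FALSE] - p2[-nrow(p2), , drop = FALSE])^2)))
}

polygon_area <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Count pixel centers of the region bounding box inside-or-on the hull
# polygon (crossing-number test with an on-edge tolerance), so a convex
# raster region has convex_area equal to its own pixel count.
hull_pixel_area <- function(hull, bbox) {
  rs <- bbox["rmin"]:bbox["rmax"]; cs <- bbox["cmin"]:bbox["cmax"]
  P <- cbind(rep(rs, times = length(cs)), rep(cs, each = length(rs)))
  hy <- hull[, 1]; hx <- hull[, 2]
  n <- length(hy)
  inside <- rep(FALSE, nrow(P)); onedge <- rep(FALSE, nrow(P))
  py <- P[, 1]; px <- P[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    y1 <- hy[j]; x1 <- hx[j]; y2 <- hy[i]; x2 <- hx[i]
    # on-segment check
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    tpar <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / max(len2, 1e-12)
    onedge <- onedge | (d^2 <= 1e-12 * max(len2, 1) & tpar >= -1e-9 & tpar <= 1 + 1e-9)
    # crossing number (ray to +x)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1 + 1e-300) + x1)
    inside <- xor(inside, crosses)
  }
  sum(inside | onedge)
}

# Max Feret: diameter of the hull point set; min Feret: minimal projection
# width over rotating directions (1-degree resolution).
feret_diameters <- function(hull) {
  d2 <- as.matrix(stats::dist(hull))
  fmax <- max(d2)
  ang <- seq(0, pi, length.out = 181)[-181]
  y <- hull[, 1]; x <- hull[, 2]
  proj <- outer(x, cos(ang + pi / 2)) + outer(y, sin(ang + pi / 2))
  widths <- apply(proj, 2, function(p) diff(range(p)))
  # widths measured between supporting lines through pixel centers; add one
  # pixel so a single-row region has unit, not zero, breadth
  c(fmax = fmax + 1, fmin = min(widths) + 1)
}

# Seven Hu invariant moments of a binary pixel set
hu_moments <- function(px) {
  y <- px[, 1]; x <- px[, 2]
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  xm <- x - cx; ym <- y - cy
  m <- function(p, q) sum(xm^p * ym^q)
  eta <- function(p, q) m(p, q) / n^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

#' The 27 shape descriptors of a segmented nucleus
#'
#' Mask-, hull- and fitted-ellipse-based descriptors. All values are
#' strictly positive by construction so the min-max rate is defined for
#' every descriptor: Hu moments are exported on a signed log scale shifted
#' by a fixed constant, `40 - sign(h) * log10(|h| + 1e-12)`, and the
#' ellipse-fit residual carries a 0.01 px floor.
#'
#' @param region a `nucleus_region` from [segment_nuclei()].
#' @return named numeric vector of length 27 (see
#'   [shape_descriptor_names()]).
#' @export
nucleus_descriptors <- function(region) {
  stopifnot(inherits(region, "nucleus_region"))
  A <- region$area
  P <- polygon_perimeter(region$contour)
  ell <- region$ellipse
  hull <- region$hull
  hullP <- polygon_perimeter(hull)
  convA <- max(hull_pixel_area(hull, region$bbox), A)
  bb <- region$bbox
  bw <- bb["cmax"] - bb["cmin"] + 1; bh <- bb["rmax"] - bb["rmin"] + 1
  fer <- feret_diameters(hull)
  # normalized radius of contour points in the fitted-ellipse frame
  dx <- region$contour[, 2] - ell$cx; dy <- region$contour[, 1] - ell$cy
  u <- dx * cos(ell$theta) + dy * sin(ell$theta)
  v <- -dx * sin(ell$theta) + dy * cos(ell$theta)
  r <- sqrt((u / ell$a)^2 + (v / ell$b)^2)
  resid <- 0.01 + mean(abs(r - 1)) * (ell$a + ell$b) / 2
  hu <- hu_moments(region$pixels)
  out <- c(
    A, P, P / A, 2 * sqrt(A / pi), 4 * pi * A / P^2,
    convA, min(A / convA, 1), min(hullP / P, 1), A / (bw * bh),
    max(sqrt(max(0, 1 - (ell$b / ell$a)^2)), 1e-6),
    2 * ell$a, 2 * ell$b, ell$a / ell$b, resid,
    fer["fmax"], fer["fmin"], fer["fmax"] / fer["fmin"],
    max(bw, bh) / min(bw, bh), P^2 / (4 * pi * A),
    2 * sqrt(pi * A) / P,
    40 - sign(hu) * log10(abs(hu) + 1e-12)
  )
  names(out) <- shape_descriptor_names()
  out
}

#' Aggregate per-nucleus descriptors to slide level
#'
#' For each descriptor column, emits mean, standard deviation (0 for a
#' single nucleus), minimum, maximum, and the min-max rate
#' `mrate = min / max` — the slide-level heterogeneity contrast statistic
#' (values near 1 = homogeneous nuclei, small values = high morphological
#' variation).
#'
#' @param per_nucleus numeric matrix or data.frame, nuclei in rows,
#'   descriptors in columns (strictly positive values expected for a
#'   meaningful mrate).
#' @return named numeric vector of length `5 * ncol(per_nucleus)` with
#'   names `<descriptor>_<mean|sd|min|max|mrate>` (135 for the standard 27
#'   descriptors).
#' @export
aggregate_shape_features <- function(per_nucleus) {
  X <- as.matrix(per_nucleus)
  if (nrow(X) == 0) stop("no nuclei sampled")
  agg <- function(x) {
    c(mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      min = min(x), max = max(x),
      mrate = min(x) / max(x))
  }
  res <- apply(X, 2, agg)
  out <- as.numeric(res)
  names(out) <- as.vector(outer(rownames(res), colnames(res),
                                function(a, d) paste0(d, "_", a)))
  out
}
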