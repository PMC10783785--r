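#' Segmentation parameters for nuclei detection
#'
#' @param min_area minimum component area in pixels.
#' @param adaptive_window side of the Gaussian-weighted local-mean window
#'   used for adaptive threshold refinement (odd).
#' @param adaptive_offset offset (in 0-255 gray levels) added to the local
#'   mean before comparison.
#' @param opening_size diameter of the morphological opening brush.
#' @param exclude_border drop components touching the block border (their
#'   shape is truncated by the crop).
#' @param min_h_od minimum hematoxylin concentration (optical-density
#'   units) a pixel must reach to count as nuclear; guards against Otsu
#'   latching onto sensor noise on tiles with no stained nuclei at all.
#' @param stain_matrix stain matrix for color deconvolution.
#' @return list of class `segment_params`.
#' @export
segment_params <- function(min_area = 40L, adaptive_window = 51L,
                           adaptive_offset = 2, opening_size = 3L,
                           exclude_border = TRUE, min_h_od = 0.15,
                           stain_matrix = he_stain_matrix()) {
  structure(list(min_area = as.integer(min_area),
                 adaptive_window = as.integer(adaptive_window),
                 adaptive_offset = adaptive_offset,
                 opening_size = as.integer(opening_size),
                 exclude_border = isTRUE(exclude_border),
                 min_h_od = min_h_od,
                 stain_matrix = stain_matrix),
            class = "segment_params")
}

# 3x3 Laplacian sharpening of a matrix (edge-replicated boundary)
laplacian_sharpen <- function(x) {
  k <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

# Gaussian-weighted local mean with the given window side
local_gaussian_mean <- function(x, window) {
  sigma <- window / 6
  k <- EBImage::makeBrush(ifelse(window %% 2 == 1, window, window + 1L),
                          shape = "gaussian", sigma = sigma)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

#' Segment nuclei in an H&E RGB block
#'
#' Pipeline: color deconvolution to the hematoxylin concentration channel;
#' 3x3 Laplacian sharpening; Otsu threshold on the sharpened channel
#' (rescaled to 8-bit); adaptive local-mean threshold refinement intersected
#' with the Otsu mask; morphological opening and hole filling; watershed
#' separation of touching nuclei on the distance map; components below
#' `min_area` or with degenerate contours are discarded; each surviving component gets a least-squares ellipse fit to
#' its contour and a convex hull.
#'
#' @param block RGB array in `[0,1]`.
#' @param params a [segment_params()] object.
#' @return list of `nucleus_region` objects, each with `pixels` (n x 2
#'   matrix of 1-based row/col indices), `area`, `contour` (ordered n x 2
#'   row/col boundary coordinates), `ellipse` (list `cx, cy, a, b, theta`),
#'   `hull` (m x 2 row/col vertices), `bbox` (`rmin, rmax, cmin, cmax`).
#'   May be empty.
#' @export
segment_nuclei <- function(block, params = segment_params()) {
  stopifnot(length(dim(block)) == 3)
  H <- color_deconvolution(block, params$stain_matrix)$H
  Hs <- laplacian_sharpen(H)
  rng <- range(Hs)
  if (diff(rng) < 1e-9) return(list())
  H8 <- round((Hs - rng[1]) / diff(rng) * 255)
  t <- tryCatch(otsu_threshold(hist256(H8)), error = function(e) NA_integer_)
  if (is.na(t)) return(list())
  m_otsu <- H8 > t
  loc <- local_gaussian_mean(H8, params$adaptive_window)
  m_adapt <- H8 > loc + params$adaptive_offset
  m <- m_otsu & m_adapt & (H >= params$min_h_od)
  m <- EBImage::fillHull(m * 1)  # adaptive refinement hollows interiors
  m <- EBImage::opening(m, EBImage::makeBrush(params$opening_size, "disc"))
  m <- EBImage::fillHull(m) > 0.5
  # watershed on the distance map separates touching nuclei; the tolerance
  # keeps single wobbly nuclei from over-splitting
  lab <- EBImage::watershed(EBImage::distmap(m * 1), tolerance = 1.5, ext = 1)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  regions <- vector("list", nlab)
  contours <- EBImage::ocontour(lab)
  for (i in seq_len(nlab)) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) < params$min_area) next
    if (params$exclude_border &&
        (min(px) == 1 || max(px[, 1]) == nrow(lab) || max(px[, 2]) == ncol(lab)))
      next  # clipped at the block border: shape would be truncated
    ct <- contours[[i]]
    if (is.null(ct) || nrow(ct) < 5) next
    ct <- ct + 1L  # ocontour is 0-based; columns are (row, col) index order
    ell <- fit_ellipse_lsq(ct)
    if (is.null(ell)) ell <- moment_ellipse(px)  # equivalent ellipse fallback
    if (is.null(ell)) next
    hull_idx <- grDevices::chull(ct[, 1], ct[, 2])
    regions[[i]] <- structure(list(
      pixels = px, area = nrow(px), contour = ct, ellipse = ell,
      hull = ct[hull_idx, , drop = FALSE],
      bbox = c(rmin = min(px[, 1]), rmax = max(px[, 1]),
               cmin = min(px[, 2]), cmax = max(px[, 2]))),
      class = "nucleus_region")
  }
  Filter(Negate(is.null), regions)
}

#' Direct least-squares ellipse fit to contour points
#'
#' Fitzgibbon-style algebraic fit (numerically stabilized Halir-Flusser
#' formulation) of a conic constrained to be an ellipse, converted to
#' geometric parameters. Falls back to the second-moment (equivalent
#' ellipse) fit when the constrained eigenproblem degenerates.
#'
#' @param pts `n x 2` matrix of (row, col) coordinates, `n >= 5`.
#' @return list `cx, cy, a, b, theta` (`a >= b` semi-axes, `theta` the
#'   major-axis angle in radians measured in (col, row) = (x, y) frame), or
#'   `NULL` when no ellipse can be recovered.
#' @export
fit_ellipse_lsq <- function(pts) {
  if (nrow(pts) < 5) return(NULL)
  y <- pts[, 1]; x <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  sol <- tryCatch({
    Tm <- -solve(S3, t(S2))
    M <- S1 + S2 %*% Tm
    M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
    ev <- eigen(M)
    evec <- Re(ev$vectors)
    cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
    ok <- which(cond > 1e-12)
    if (!length(ok)) NULL else {
      a1 <- evec[, ok[1]]
      c(a1, drop(Tm %*% a1))
    }
  }, error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  conic_to_ellipse(sol, mx, my)
}

# Convert conic coefficients (A,B,C,D,E,F) in centered coords back to
# geometric center/axes/angle in original coordinates.
conic_to_ellipse <- function(co, mx, my) {
  if (co[1] + co[3] < 0) co <- -co  # normalize so A + C > 0
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx0 <- (2 * C * D - B * E) / den
  cy0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  a2 <- num * ((A + C) + s) / den^2
  b2 <- num * ((A + C) - s) / den^2
  if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0) return(NULL)
  a <- sqrt(a2); b <- sqrt(b2)
  theta <- (0.5 * atan2(-B, C - A)) %% pi
  # atan2 convention ambiguity: keep whichever of theta, theta + pi/2 puts
  # the point at distance a along the axis on the conic
  on_conic <- function(th) {
    x <- cx0 + a * cos(th); y <- cy0 + a * sin(th)
    abs(A * x^2 + B * x * y + C * y^2 + D * x + E * y + F)
  }
  if (on_conic(theta + pi / 2) < on_conic(theta))
    theta <- (theta + pi / 2) %% pi
  list(cx = cx0 + mx, cy = cy0 + my, a = a, b = b, theta = theta)
}

# Equivalent ellipse from second-order central moments of the points
moment_ellipse <- function(pts) {
  y <- pts[, 1]; x <- pts[, 2]
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  tr <- mxx + myy
  dd <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
  l1 <- (tr + dd) / 2; l2 <- (tr - dd) / 2
  if (l1 <= 0 || l2 <= 0) return(NULL)
  list(cx = cx, cy = cy, a = 2 * sqrt(l1), b = 2 * sqrt(l2),
       theta = (0.5 * atan2(2 * mxy, mxx - myy)) %% pi)
}
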