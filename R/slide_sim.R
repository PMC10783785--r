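#' Parameters for the synthetic H&E slide generator
#'
#' The generator emulates a tile of an H&E-stained section: hematoxylin-toned
#' elliptical nuclei over an eosin-toned background with low-frequency
#' texture and per-pixel sensor noise. Nucleus semi-axes are drawn LogNormal
#' so all shape descriptors remain strictly positive and the min-max rate
#' (mrate) heterogeneity statistic is always well defined.
#'
#' Default stain tones are derived from the standard Ruifrok-Johnston H&E
#' stain vectors (see [he_stain_matrix()]) at fixed optical densities, so
#' color deconvolution of a synthetic slide recovers nuclei cleanly in the
#' hematoxylin channel.
#'
#' @param image_size pixels per side (square tile), at least 64.
#' @param n_nuclei number of nuclei to plant (may be 0).
#' @param axis_mean length-2 numeric, mean (major, minor) semi-axes in pixels.
#' @param heterogeneity nonnegative scalar `h`: the coefficient of variation
#'   of the LogNormal semi-axis distributions. `h = 0` plants identical
#'   ellipses (up to rotation and position).
#' @param stain_params list with `nucleus_rgb`, `background_rgb` (RGB in
#'   `[0,1]`), `noise_sd` (per-pixel Gaussian noise sd on the `[0,1]` scale)
#'   and `texture_sd`, `texture_sigma` (background texture amplitude and
#'   blur radius).
#' @param overlap_allowed if `FALSE`, nuclei are placed by rejection
#'   sampling; placement failing after a bounded number of attempts is an
#'   error ("placement failure").
#' @param seed master seed; substreams `"placement"` and `"stain-noise"`
#'   are derived from it.
#' @return an object of class `slide_sim_params`.
#' @export
slide_sim_params <- function(image_size = 512L,
                             n_nuclei = 80L,
                             axis_mean = c(14, 9),
                             heterogeneity = 0.15,
                             stain_params = NULL,
                             overlap_allowed = FALSE,
                             seed = 1L) {
  stopifnot(image_size >= 64, n_nuclei >= 0, length(axis_mean) == 2,
            all(axis_mean > 0), axis_mean[1] >= axis_mean[2],
            heterogeneity >= 0)
  if (is.null(stain_params)) stain_params <- default_stain_params()
  structure(list(image_size = as.integer(image_size),
                 n_nuclei = as.integer(n_nuclei),
                 axis_mean = as.numeric(axis_mean),
                 heterogeneity = as.numeric(heterogeneity),
                 stain_params = stain_params,
                 overlap_allowed = isTRUE(overlap_allowed),
                 seed = as.integer(seed)),
            class = "slide_sim_params")
}

#' Default synthetic stain tones
#'
#' Nucleus and background RGB are forward-synthesized from the standard H&E
#' stain vectors via the Beer-Lambert relation `I = 256 * 10^(-d * v) - 1`
#' at hematoxylin density 0.9 and eosin density 0.35.
#'
#' @return list with `nucleus_rgb`, `background_rgb`, `noise_sd`,
#'   `texture_sd`, `texture_sigma`.
#' @export
default_stain_params <- function() {
  M <- he_stain_matrix()
  tone <- function(v, d) pmin(pmax((256 * 10^(-d * v) - 1) / 255, 0), 1)
  list(nucleus_rgb    = tone(M[1, ], 0.9),
       background_rgb = tone(M[2, ], 0.35),
       noise_sd = 0.02, texture_sd = 0.05, texture_sigma = 8)
}

#' Generate a synthetic H&E-like slide with ground truth
#'
#' Draws `n_nuclei` rotated ellipses with LogNormal semi-axes
#' (mean = `axis_mean`, coefficient of variation = `heterogeneity`) over a
#' textured eosin background, records every nucleus in a truth table, and
#' rasterizes an integer label mask. Bit-identical output for identical
#' parameters and seed.
#'
#' @param params a [slide_sim_params()] object.
#' @return object of class `synthetic_slide`: list with `image`
#'   (`size x size x 3` array in `[0,1]`), `label_mask` (integer matrix, 0 =
#'   background, nucleus ids consecutive from 1) and `truth_table`
#'   (data.frame: `id, cx, cy, a, b, theta`; coordinates are 0-based
#'   row/col pixel centers, `a >= b` semi-axes in pixels, `theta` radians).
#' @export
generate_slide <- function(params) {
  stopifnot(inherits(params, "slide_sim_params"))
  n <- params$image_size
  k <- params$n_nuclei
  sp <- params$stain_params

  # LogNormal(mean = m, cv = h); h = 0 degenerates to the mean exactly
  draw_axis <- function(m, h, nn) {
    if (h == 0) return(rep(m, nn))
    s2 <- log(1 + h^2)
    stats::rlnorm(nn, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }

  truth <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                      a = numeric(0), b = numeric(0), theta = numeric(0))
  mask <- matrix(0L, n, n)

  if (k > 0) {
    placed <- with_substream(params$seed, "placement", {
      out <- vector("list", k)
      attempts <- 0L
      max_attempts <- 200L * k
      i <- 1L
      while (i <= k) {
        if (attempts >= max_attempts)
          stop("placement failure: could not place ", k,
               " non-overlapping nuclei in ", max_attempts, " attempts")
        attempts <- attempts + 1L
        a <- draw_axis(params$axis_mean[1], params$heterogeneity, 1L)
        b <- draw_axis(params$axis_mean[2], params$heterogeneity, 1L)
        if (b > a) { tmp <- a; a <- b; b <- tmp }
        margin <- a + 2
        if (2 * margin >= n) { next }
        cy <- stats::runif(1, margin, n - 1 - margin)
        cx <- stats::runif(1, margin, n - 1 - margin)
        theta <- stats::runif(1, 0, pi)
        px <- ellipse_pixels(cy, cx, a, b, theta, n)
        if (!params$overlap_allowed && any(mask[px] != 0L)) next
        mask[px] <- i
        out[[i]] <- c(cx = cx, cy = cy, a = a, b = b, theta = theta)
        i <- i + 1L
      }
      out
    })
    truth <- do.call(rbind, lapply(seq_along(placed), function(i)
      data.frame(id = i, cx = placed[[i]]["cx"], cy = placed[[i]]["cy"],
                 a = placed[[i]]["a"], b = placed[[i]]["b"],
                 theta = placed[[i]]["theta"], row.names = NULL)))
  }

  img <- with_substream(params$seed, "stain-noise", {
    # low-frequency eosin texture: Gaussian-blurred white noise
    tex <- matrix(stats::rnorm(n * n), n, n)
    tex <- as.matrix(EBImage::gblur(tex, sigma = sp$texture_sigma))
    tex <- tex / max(stats::sd(tex), 1e-12) * sp$texture_sd
    img <- array(0, c(n, n, 3))
    nuc <- mask > 0L
    for (ch in 1:3) {
      plane <- matrix(sp$background_rgb[ch], n, n) + tex
      plane[nuc] <- sp$nucleus_rgb[ch]
      img[, , ch] <- plane
    }
    img <- img + array(stats::rnorm(length(img), sd = sp$noise_sd), dim(img))
    pmin(pmax(img, 0), 1)
  })

  structure(list(image = img, label_mask = mask, truth_table = truth,
                 params = params),
            class = "synthetic_slide")
}

# Linear indices of pixels whose centers fall inside the rotated ellipse
# centered at (cy, cx) (0-based) with semi-axes a >= b and rotation theta.
ellipse_pixels <- function(cy, cx, a, b, theta, n) {
  r0 <- max(0L, floor(cy - a)); r1 <- min(n - 1L, ceiling(cy + a))
  c0 <- max(0L, floor(cx - a)); c1 <- min(n - 1L, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  (cols[idx[, 2]]) * n + rows[idx[, 1]] + 1L  # column-major linear index
}

#' Analytic shape descriptors of planted nuclei
#'
#' Exact ellipse geometry from the generator truth table: the oracle the
#' image-processing pipeline is tested against. Perimeter uses Ramanujan's
#' approximation.
#'
#' @param slide a `synthetic_slide`.
#' @return data.frame with one row per nucleus: `id, area, perimeter,
#'   major_axis, minor_axis, equiv_diameter, eccentricity, aspect_ratio`.
#' @export
ground_truth_descriptors <- function(slide) {
  stopifnot(inherits(slide, "synthetic_slide"))
  tt <- slide$truth_table
  a <- tt$a; b <- tt$b
  data.frame(
    id = tt$id,
    area = pi * a * b,
    perimeter = pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))),
    major_axis = 2 * a,
    minor_axis = 2 * b,
    equiv_diameter = 2 * sqrt(a * b),
    eccentricity = sqrt(pmax(0, 1 - (b / a)^2)),
    aspect_ratio = a / b
  )
}

#' Write a synthetic slide to disk
#'
#' Image as 8-bit RGB PNG, label mask as single-channel 16-bit PNG, truth
#' table as CSV with header.
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory (created if needed).
#' @param stem file stem, e.g. `"slide01"`.
#' @return invisibly, the paths written.
#' @export
write_slide <- function(slide, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(stem, ".png"))
  p_msk <- file.path(dir, paste0(stem, "_mask.png"))
  p_tt  <- file.path(dir, paste0(stem, "_truth.csv"))
  png::writePNG(slide$image, p_img)
  png::writePNG(slide$label_mask / 65535, p_msk)  # 16-bit gray
  utils::write.csv(slide$truth_table, p_tt, row.names = FALSE)
  invisible(c(image = p_img, mask = p_msk, truth = p_tt))
}

#' Read an RGB image from PNG or TIFF
#'
#' @param path file path; `.png`/`.tif`/`.tiff` supported.
#' @return `h x w x 3` array in `[0,1]`.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    a <- EBImage::imageData(EBImage::readImage(path))
    aperm(a, c(2, 1, 3))  # EBImage stores x-major
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
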