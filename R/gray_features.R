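#' Otsu threshold from a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over all candidate
#' levels `t = 0..254` (class 0 = levels `<= t`, class 1 = levels `> t`).
#' Ties are broken by the lowest level. A histogram with a single nonempty
#' bin (constant image) is degenerate and an error.
#'
#' @param counts integer vector of 256 gray-level counts (levels 0..255).
#' @return the threshold level `t`; pixels with level `> t` are "above".
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256, all(counts >= 0))
  if (sum(counts > 0) < 2) stop("degenerate histogram: constant image")
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                 # class 0 mass up to level t
  s0 <- cumsum(counts * lev)           # class 0 level sum
  tot <- s0[256]
  w0t <- w0[1:255]; s0t <- s0[1:255]
  w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  mu0 <- s0t / pmax(w0t, 1)
  mu1 <- (tot - s0t) / pmax(w1t, 1)
  bcv <- ifelse(valid, (w0t / n) * (w1t / n) * (mu0 - mu1)^2, -Inf)
  which.max(bcv) - 1L                  # which.max returns first (lowest) tie
}

# ITU-R 601 luminance, 8-bit rounded
rgb_to_gray <- function(image) {
  stopifnot(length(dim(image)) == 3)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  round(pmin(pmax(g, 0), 1) * 255)
}

hist256 <- function(gray) tabulate(as.integer(gray) + 1L, nbins = 256L)

#' Tissue mask of an RGB image
#'
#' Luminance conversion, Otsu thresholding keeping the stained (darker)
#' class, and a morphological closing to fill pinholes.
#'
#' @param image RGB array in `[0,1]`.
#' @param brush_size diameter of the closing brush (odd).
#' @return logical matrix, `TRUE` = tissue.
#' @export
tissue_mask <- function(image, brush_size = 5L) {
  g <- rgb_to_gray(image)
  t <- otsu_threshold(hist256(g))
  m <- g <= t
  m <- EBImage::closing(m * 1, EBImage::makeBrush(brush_size, "disc"))
  matrix(as.numeric(m) > 0.5, nrow(g), ncol(g))
}

#' Select the foreground block maximizing tissue coverage
#'
#' Scans candidate block positions on a stride grid in row-major order and
#' returns the first position with maximal tissue-mask coverage. Coordinates
#' are 0-based, half-open.
#'
#' @param mask logical tissue mask.
#' @param block_size block side in pixels, at most `min(dim(mask))`.
#' @param stride scan stride; default `max(1, block_size %/% 4)`.
#' @return list `(row, col, size)`, 0-based top-left corner.
#' @export
select_foreground_block <- function(mask, block_size, stride = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  stopifnot(block_size >= 1, block_size <= nr, block_size <= nc)
  if (is.null(stride)) stride <- max(1L, block_size %/% 4L)
  # integral image for O(1) window sums
  S <- rbind(0, cbind(0, apply(apply(mask * 1, 2, cumsum), 1, cumsum)))
  S <- t(S)  # restore orientation after the double apply
  rs <- unique(c(seq(0L, nr - block_size, by = stride), nr - block_size))
  cs <- unique(c(seq(0L, nc - block_size, by = stride), nc - block_size))
  best <- -1; best_pos <- NULL
  for (r in rs) for (cc in cs) {
    cov <- S[r + block_size + 1, cc + block_size + 1] - S[r + 1, cc + block_size + 1] -
      S[r + block_size + 1, cc + 1] + S[r + 1, cc + 1]
    if (cov > best) { best <- cov; best_pos <- c(r, cc) }
  }
  if (best <= 0) stop("no foreground: tissue mask has zero coverage everywhere")
  list(row = as.integer(best_pos[1]), col = as.integer(best_pos[2]),
       size = as.integer(block_size))
}

#' Area-average downsampling of a matrix
#'
#' Each target pixel is the mean of a contiguous band of source rows and
#' columns (bands partition the source as evenly as possible), i.e. an
#' area-average shrink. Used to reduce the foreground block to the global
#' gray-level ROI.
#'
#' @param x numeric matrix.
#' @param target_rows,target_cols output dimensions (must not exceed input).
#' @return `target_rows x target_cols` matrix.
#' @export
downsample_mean <- function(x, target_rows, target_cols = target_rows) {
  stopifnot(target_rows <= nrow(x), target_cols <= ncol(x))
  rg <- as.integer(cut(seq_len(nrow(x)), target_rows, labels = FALSE))
  cg <- as.integer(cut(seq_len(ncol(x)), target_cols, labels = FALSE))
  rs <- rowsum(x, rg)                       # sum rows into bands
  out <- t(rowsum(t(rs), cg))               # then columns
  out / outer(tabulate(rg, target_rows), tabulate(cg, target_cols))
}

#' Names of the 18 global gray-level features
#' @return character vector of length 18.
#' @export
gray_feature_names <- function() {
  paste0("gray_", c("energy", "total_energy", "entropy", "minimum", "p10",
                    "p90", "maximum", "mean", "median", "iqr", "range",
                    "mad", "rmad", "rms", "skewness", "kurtosis",
                    "variance", "uniformity"))
}

#' The 18 first-order gray-level features of a ROI
#'
#' The standard radiomics first-order panel computed over all ROI pixels:
#' energy, total energy, entropy, minimum, 10th/90th percentile, maximum,
#' mean, median, interquartile range, range, mean absolute deviation, robust
#' mean absolute deviation (within the 10-90 percentile band),
#' root-mean-squared, skewness, (non-excess) kurtosis, population variance
#' and uniformity. Entropy (bits) and uniformity use a fixed histogram bin
#' width of 25 gray levels anchored at multiples of 25.
#'
#' @param roi numeric matrix of gray values in `[0, 255]`.
#' @param bin_width histogram bin width for entropy and uniformity.
#' @return named numeric vector of length 18.
#' @export
global_gray_features <- function(roi, bin_width = 25) {
  x <- as.numeric(roi)
  stopifnot(length(x) > 0, all(is.finite(x)))
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  band <- x[x >= q[1] & x <= q[4]]
  bins <- floor(x / bin_width)
  p <- tabulate(as.integer(bins - min(bins)) + 1L)
  p <- p[p > 0] / n
  out <- c(
    energy = sum(x^2),
    total_energy = sum(x^2),        # unit pixel spacing
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    p10 = q[1], p90 = q[4],
    maximum = max(x),
    mean = mu,
    median = stats::median(x),
    iqr = q[3] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    rmad = if (length(band)) mean(abs(band - mean(band))) else 0,
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2)
  )
  names(out) <- gray_feature_names()
  out
}
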