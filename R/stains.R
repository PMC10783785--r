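#' Standard H&E stain matrix
#'
#' Rows are unit optical-density vectors for hematoxylin and eosin
#' (Ruifrok-Johnston values) plus a residual third row orthogonal to both,
#' so the matrix is invertible and the third concentration channel ("O")
#' captures whatever H and E do not explain.
#'
#' @return `3 x 3` matrix with rows `H`, `E`, `O` and unit row norms.
#' @export
he_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  h <- h / sqrt(sum(h^2)); e <- e / sqrt(sum(e^2))
  o <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  o <- o / sqrt(sum(o^2))
  M <- rbind(H = h, E = e, O = o)
  colnames(M) <- c("R", "G", "B")
  M
}

#' Color deconvolution of an RGB image into stain concentrations
#'
#' Converts pixel intensities to optical density, `OD = -log10((I8 + 1) /
#' 256)` per channel (`I8` the 8-bit intensity), and unmixes with the
#' inverse stain matrix: `conc = OD %*% solve(M)`. Negative concentrations
#' are clipped to zero unless `clip = FALSE` (the unclipped concentrations
#' satisfy the exact linear round trip `OD = conc %*% M`).
#'
#' @param image RGB array in `[0,1]`.
#' @param stain_matrix `3 x 3` matrix with unit-normalized stain rows;
#'   default [he_stain_matrix()].
#' @param clip clip negative concentrations to zero (default `TRUE`).
#' @return list of class `stain_channels` with matrices `H`, `E`, `O`.
#' @export
color_deconvolution <- function(image, stain_matrix = he_stain_matrix(),
                                clip = TRUE) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  M <- stain_matrix
  if (abs(det(M)) < 1e-10) stop("singular stain matrix")
  d <- dim(image)[1:2]
  I8 <- round(pmin(pmax(image[, , 1:3], 0), 1) * 255)  # 8-bit semantics
  od <- -log10((matrix(I8, ncol = 3) + 1) / 256)
  conc <- od %*% solve(M)
  if (clip) conc <- pmax(conc, 0)
  structure(list(H = matrix(conc[, 1], d[1], d[2]),
                 E = matrix(conc[, 2], d[1], d[2]),
                 O = matrix(conc[, 3], d[1], d[2])),
            class = "stain_channels")
}
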