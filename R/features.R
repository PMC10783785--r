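#' Names of the full 153-entry slide feature vector
#'
#' 18 global gray-level features followed by 135 aggregated nucleus-shape
#' features (27 descriptors x 5 aggregations).
#'
#' @return character vector of length 153.
#' @export
slide_feature_names <- function() {
  aggs <- c("mean", "sd", "min", "max", "mrate")
  shape <- as.vector(vapply(shape_descriptor_names(),
                            function(d) paste0(d, "_", aggs),
                            character(5)))
  c(gray_feature_names(), shape)
}

#' Feature-extraction configuration
#'
#' Sizes default to the full-slide protocol (32k foreground block, 1,000 px
#' ROI and sampling blocks, 20 blocks x 20 nuclei) but are capped to the
#' image at run time, so the same extractor runs on synthetic tiles.
#'
#' @param block_size foreground block side (capped at image size).
#' @param roi_size global gray-level ROI side after area-average shrink.
#' @param sample_block_size side of the randomly sampled nuclei blocks.
#' @param n_blocks number of sampled blocks.
#' @param nuclei_per_block nuclei sampled per block (all if fewer).
#' @param seg segmentation parameters ([segment_params()]).
#' @param gray_bin_width histogram bin width for entropy/uniformity.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(block_size = 32000L, roi_size = 1000L,
                           sample_block_size = 1000L, n_blocks = 20L,
                           nuclei_per_block = 20L, seg = segment_params(),
                           gray_bin_width = 25) {
  structure(list(block_size = as.integer(block_size),
                 roi_size = as.integer(roi_size),
                 sample_block_size = as.integer(sample_block_size),
                 n_blocks = as.integer(n_blocks),
                 nuclei_per_block = as.integer(nuclei_per_block),
                 seg = seg, gray_bin_width = gray_bin_width),
            class = "feature_config")
}

#' Extract the 153-entry feature vector from a slide image
#'
#' End-to-end protocol: tissue mask; coverage-maximizing foreground block;
#' area-average shrink to the global ROI and 18 gray-level features; then
#' `n_blocks` randomly positioned blocks within the foreground, nuclei
#' segmentation per block, random sampling of up to `nuclei_per_block`
#' nuclei per block; the pooled nuclei's 27 descriptors aggregated to 135
#' shape features. Deterministic given the seed (block and nucleus sampling
#' draw from the `"wsi-sampling"` substream).
#'
#' @param image RGB array in `[0,1]` (or a `synthetic_slide`).
#' @param config a [feature_config()]; `NULL` for defaults.
#' @param seed integer seed for the sampling substream.
#' @return named numeric vector of length 153 with attributes `seed` and
#'   `n_nuclei_sampled`. Errors "no foreground" / "no nuclei sampled"
#'   propagate when the slide has no tissue or no detectable nuclei.
#' @export
extract_slide_features <- function(image, config = NULL, seed = 1L) {
  if (inherits(image, "synthetic_slide")) image <- image$image
  if (is.null(config)) config <- feature_config()
  n_r <- dim(image)[1]; n_c <- dim(image)[2]
  bs <- min(config$block_size, n_r, n_c)
  mask <- tissue_mask(image)
  blk <- select_foreground_block(mask, bs)
  fg <- image[blk$row + seq_len(bs), blk$col + seq_len(bs), , drop = FALSE]

  roi_size <- min(config$roi_size, bs)
  gray <- rgb_to_gray(fg)
  roi <- round(downsample_mean(gray, roi_size))
  gfeat <- global_gray_features(roi, bin_width = config$gray_bin_width)

  sbs <- min(config$sample_block_size, bs)
  descs <- with_substream(seed, "wsi-sampling", {
    acc <- list()
    for (b in seq_len(config$n_blocks)) {
      r0 <- if (bs > sbs) sample.int(bs - sbs + 1L, 1L) - 1L else 0L
      c0 <- if (bs > sbs) sample.int(bs - sbs + 1L, 1L) - 1L else 0L
      block <- fg[r0 + seq_len(sbs), c0 + seq_len(sbs), , drop = FALSE]
      regions <- segment_nuclei(block, config$seg)
      if (!length(regions)) next
      take <- if (length(regions) > config$nuclei_per_block) {
        sample(seq_along(regions), config$nuclei_per_block)
      } else seq_along(regions)
      for (i in take) acc[[length(acc) + 1L]] <- nucleus_descriptors(regions[[i]])
    }
    acc
  })
  if (!length(descs)) stop("no nuclei sampled")
  shape <- aggregate_shape_features(do.call(rbind, descs))
  out <- c(gfeat, shape)
  stopifnot(length(out) == 153, all(is.finite(out)))
  names(out) <- slide_feature_names()
  attr(out, "seed") <- seed
  attr(out, "n_nuclei_sampled") <- length(descs)
  out
}

#' Extract features for a set of slides into a matrix
#'
#' @param slides list of `synthetic_slide` objects or image file paths.
#' @param config a [feature_config()].
#' @param seed master seed; slide `i` uses substream `"slide-<i>"`.
#' @return `length(slides) x 153` matrix.
#' @export
extract_feature_matrix <- function(slides, config = NULL, seed = 1L) {
  rows <- lapply(seq_along(slides), function(i) {
    s <- slides[[i]]
    img <- if (is.character(s)) read_rgb_image(s) else s
    extract_slide_features(img, config, seed = substream_seed(seed, paste0("slide-", i)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- if (is.character(slides[[1]])) basename(unlist(slides)) else
    sprintf("slide%03d", seq_along(slides))
  out
}
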