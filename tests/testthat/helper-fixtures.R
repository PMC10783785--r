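# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small easy-regime slide: non-overlapping, high-contrast, mild
# heterogeneity.
small_slide <- function(seed = 7) {
  memo(paste0("slide-", seed),
       generate_slide(slide_sim_params(image_size = 320, n_nuclei = 40,
                                       heterogeneity = 0.1, seed = seed)))
}

# Feature-extraction config scaled to the small synthetic tiles.
tile_config <- function(n_blocks = 12L) {
  feature_config(sample_block_size = 160L, n_blocks = n_blocks)
}

# The default-condition simulated cohort (231 patients, informative
# features), shared across survival tests.
default_cohort <- function(seed = 1) {
  memo(paste0("cohort-", seed), generate_cohort(cohort_sim_params(seed = seed)))
}

# Cached integration evaluations on the default cohort (reused by several
# tests; the fits are the expensive part).
cached_eval <- function(mode, domains, seed = 42) {
  key <- paste0("eval-", mode, "-", paste(domains, collapse = "+"), "-", seed)
  memo(key, evaluate_integration(default_cohort(), integration_spec(mode, domains),
                                 n_splits = 20, seed = seed, compute_auc = FALSE))
}

# --- independent oracles ----------------------------------------------------

# Exhaustive between-class-variance search over all 256 candidate levels.
otsu_oracle <- function(counts) {
  n <- sum(counts)
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(counts[(t + 2):256] * ((t + 1):255)) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  best_t
}

# O(n^2) pair-enumeration concordance oracle (explicit double loop).
cindex_oracle <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Greedy IoU >= 0.5 matching of planted nuclei to segmented regions.
segmentation_matches <- function(slide, regions) {
  tt <- slide$truth_table
  n <- nrow(slide$label_mask)
  reg_idx <- lapply(regions, function(r) (r$pixels[, 2] - 1L) * n + r$pixels[, 1])
  out <- data.frame(id = tt$id, iou = 0, region = NA_integer_)
  for (k in seq_len(nrow(tt))) {
    tp <- which(slide$label_mask == tt$id[k])
    for (j in seq_along(reg_idx)) {
      inter <- length(intersect(tp, reg_idx[[j]]))
      iou <- inter / (length(tp) + length(reg_idx[[j]]) - inter)
      if (iou > out$iou[k]) { out$iou[k] <- iou; out$region[k] <- j }
    }
  }
  out
}

# Exhaustive implementation of the final-model selection rule on a table of
# (split_id, cindex, size) rows.
final_model_oracle <- function(tbl) {
  qs <- quantile(tbl$cindex, c(0.5, 0.75), names = FALSE, type = 7)
  elig <- tbl[tbl$cindex >= qs[1] - 1e-12 & tbl$cindex <= qs[2] + 1e-12, ]
  elig <- elig[order(elig$size, -elig$cindex, elig$split_id), ]
  elig$split_id[1]
}

# Build a fake integration_eval from a (split_id, cindex, size) table.
fake_evaluation <- function(tbl) {
  splits <- lapply(seq_len(nrow(tbl)), function(i) {
    list(split_id = tbl$split_id[i], cindex = tbl$cindex[i],
         model = structure(list(n_nonzero = tbl$size[i]),
                           class = "risk_model"))
  })
  structure(list(splits = splits, mean_cindex = mean(tbl$cindex)),
            class = "integration_eval")
}
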