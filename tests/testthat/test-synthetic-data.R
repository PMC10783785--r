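test_that("zero heterogeneity plants identical nuclei with unit mrate", {
  s <- generate_slide(slide_sim_params(image_size = 256, n_nuclei = 20,
                                       heterogeneity = 0, seed = 3))
  tt <- s$truth_table
  expect_equal(nrow(tt), 20)
  expect_true(all(tt$a == tt$a[1]))
  expect_true(all(tt$b == tt$b[1]))
  gt <- ground_truth_descriptors(s)
  agg <- aggregate_shape_features(gt[, -1])
  mrates <- agg[grepl("_mrate$", names(agg))]
  expect_equal(unname(mrates), rep(1, length(mrates)))
  sds <- agg[grepl("_sd$", names(agg))]
  expect_equal(unname(sds), rep(0, length(sds)))
})

test_that("empty and degenerate slide configurations behave", {
  s0 <- generate_slide(slide_sim_params(image_size = 64, n_nuclei = 0, seed = 1))
  expect_equal(nrow(s0$truth_table), 0)
  expect_true(all(s0$label_mask == 0L))
  # too many non-overlapping nuclei in a tiny tile
  expect_error(
    generate_slide(slide_sim_params(image_size = 64, n_nuclei = 60,
                                    axis_mean = c(12, 8), heterogeneity = 0,
                                    seed = 1)),
    "placement failure")
  expect_error(slide_sim_params(image_size = 32), "image_size")
})

test_that("slide generation is bit-deterministic in the seed", {
  p <- slide_sim_params(image_size = 128, n_nuclei = 10, seed = 11)
  s1 <- generate_slide(p)
  s2 <- generate_slide(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$label_mask, s2$label_mask)
  expect_identical(s1$truth_table, s2$truth_table)
  s3 <- generate_slide(slide_sim_params(image_size = 128, n_nuclei = 10,
                                        seed = 12))
  expect_false(identical(s1$image, s3$image))
})

test_that("label mask ids are consecutive and match the truth table", {
  s <- small_slide()
  ids <- sort(unique(as.vector(s$label_mask)))
  expect_equal(ids, 0:nrow(s$truth_table))
  expect_equal(s$truth_table$id, seq_len(nrow(s$truth_table)))
})

test_that("analytic descriptors match closed forms", {
  s <- generate_slide(slide_sim_params(image_size = 128, n_nuclei = 2,
                                       axis_mean = c(10, 10),
                                       heterogeneity = 0, seed = 5))
  gt <- ground_truth_descriptors(s)
  expect_equal(nrow(gt), 2)
  expect_equal(gt$area, rep(100 * pi, 2))
  expect_equal(gt$eccentricity, rep(0, 2))
  expect_equal(gt$perimeter, rep(2 * pi * 10, 2), tolerance = 1e-6)
  # a = 20, b = 10: eccentricity = sqrt(1 - (10/20)^2)
  s2 <- generate_slide(slide_sim_params(image_size = 256, n_nuclei = 1,
                                        axis_mean = c(20, 10),
                                        heterogeneity = 0, seed = 5))
  gt2 <- ground_truth_descriptors(s2)
  expect_equal(gt2$eccentricity, sqrt(1 - 0.25), tolerance = 1e-12)
  expect_equal(gt2$aspect_ratio, 2)
})

test_that("ground-truth area mrate decreases with heterogeneity", {
  mean_mrate <- function(h) {
    mean(vapply(1:8, function(sd) {
      s <- generate_slide(slide_sim_params(image_size = 320, n_nuclei = 25,
                                           heterogeneity = h, seed = sd))
      gt <- ground_truth_descriptors(s)
      min(gt$area) / max(gt$area)
    }, numeric(1)))
  }
  m <- vapply(c(0, 0.15, 0.45), mean_mrate, numeric(1))
  expect_equal(m[1], 1)
  expect_true(m[2] > m[3])
  expect_true(all(diff(m) < 0))
})

test_that("realized event fraction matches the cohort design and is monotone in censoring", {
  ch <- generate_cohort(cohort_sim_params(n_patients = 2000, seed = 21))
  expect_gt(mean(ch$event), 0.532 - 0.03)
  expect_lt(mean(ch$event), 0.532 + 0.03)
  fracs <- vapply(c(0, 1 / 2000, 1 / 800, 1 / 300), function(cr) {
    mean(generate_cohort(cohort_sim_params(n_patients = 2000, censor_rate = cr,
                                           seed = 21))$event)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("null-effect cohort recovers the closed-form Weibull median", {
  p <- cohort_sim_params(n_patients = 5000, censor_rate = 0,
                         admin_censor_time = Inf,
                         true_beta = c(gene01 = 0), seed = 3)
  ch <- generate_cohort(p)
  expect_true(all(ch$event == 1))
  km <- kaplan_meier(ch$time, ch$event)
  med_true <- p$baseline_scale * log(2)^(1 / p$baseline_shape)
  expect_lt(abs(km$median - med_true) / med_true, 0.05)
})

test_that("a univariate Cox fit on the true linear predictor recovers slope 1", {
  ch <- generate_cohort(cohort_sim_params(n_patients = 2000, seed = 5))
  f <- survival::coxph(survival::Surv(ch$time, ch$event) ~ ch$linpred)
  expect_lt(abs(unname(f$coefficients) - 1), 0.10)
})

test_that("cohort generation validates inputs and is deterministic", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  expect_error(cohort_sim_params(n_genes = 2, gene_cov = bad),
               "positive semidefinite")
  expect_error(cohort_sim_params(n_genes = 3, gene_cov = diag(2)), "symmetric|3x3")
  p <- cohort_sim_params(n_patients = 50, seed = 9)
  c1 <- generate_cohort(p); c2 <- generate_cohort(p)
  expect_identical(c1$time, c2$time)
  expect_identical(c1$expression, c2$expression)
})

test_that("cohorts can take image features from real slides", {
  slides <- lapply(1:3, function(sd)
    generate_slide(slide_sim_params(image_size = 256, n_nuclei = 30,
                                    heterogeneity = 0.2, seed = sd)))
  p <- cohort_sim_params(n_patients = 3, seed = 2)
  ch <- generate_cohort(p, slides = slides,
                        feature_config = tile_config(n_blocks = 6L))
  expect_equal(dim(ch$image_features), c(3, 153))
  expect_true(all(is.finite(ch$image_features)))
})

test_that("parameter YAML round trip preserves the configuration", {
  tmp <- tempfile(fileext = ".yaml")
  sp <- slide_sim_params(image_size = 128, n_nuclei = 5, seed = 4)
  write_params_yaml(list(slide = sp), tmp)
  rt <- read_params_yaml(tmp)$slide
  expect_equal(rt$image_size, sp$image_size)
  expect_equal(rt$axis_mean, sp$axis_mean)
  s_rt <- generate_slide(rt); s_sp <- generate_slide(sp)
  expect_identical(s_rt$truth_table, s_sp$truth_table)
  expect_identical(s_rt$label_mask, s_sp$label_mask)
  # stain tones survive the text round trip to printed double precision
  expect_equal(s_rt$image, s_sp$image, tolerance = 1e-12)
})
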