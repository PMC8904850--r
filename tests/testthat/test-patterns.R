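test_that("midpoint-tie ranking matches the worked examples", {
  expect_equal(midpoint_ranks(c(1, 1, 2, 3, 3, 3)),
               c(1.5, 1.5, 3, 5, 5, 5))
  expect_equal(midpoint_ranks(c(0.2, 0.2, 0.9)), c(1.5, 1.5, 3))
  # rank mean is always (n + 1) / 2
  set.seed(1)
  for (k in 1:10) {
    x <- sample(1:6, size = sample(3:40, 1), replace = TRUE)
    expect_equal(mean(midpoint_ranks(x)), (length(x) + 1) / 2)
  }
})

test_that("clinical patterns carry steps and midpoint ranks per sampled ROI", {
  cp <- clinical_pattern(c(10, 3, 7, 21, 30, 15), c(1, 1, 2, 3, 3, 3))
  expect_equal(length(cp$sampled_rois), 6)
  expect_equal(mean(cp$ranks), 3.5)
  # sorted by ROI id; ROI 3 had step 1
  expect_equal(unname(cp$activation_step[as.character(3)]), 1)
  expect_error(clinical_pattern(c(1, 1), c(1, 2)), "duplicated")
  expect_error(clinical_pattern(c(1, 2), c(0, 2)), "positive")
})

test_that("contact points map to the nearest centroid with id tie-break", {
  rois <- roi_table(1:3, x_mm = c(0, 10, 20), y_mm = 0, z_mm = 0)
  expect_equal(nearest_roi_assignment(rbind(c(10, 0, 0)), rois), 2L)
  # equidistant between ROIs 1 and 2: smaller id wins
  expect_equal(nearest_roi_assignment(rbind(c(5, 0, 0)), rois), 1L)
  expect_equal(nearest_roi_assignment(rbind(c(13, 2, 0)), rois), 2L)
  expect_error(nearest_roi_assignment(rbind(c(NA, 0, 0)), rois), "finite")
})

test_that("pattern files merge same-ROI contact points at the earliest step", {
  dir <- withr::local_tempdir()
  rois <- roi_table(1:5, x_mm = c(0, 10, 20, 30, 40), y_mm = 0, z_mm = 0)
  df <- data.frame(cp_id = 1:4, electrode_id = c(1, 1, 1, 2),
                   roi_id = c(2, 2, 4, 5),
                   activation_step = c(4, 2, 1, 3))
  p <- file.path(dir, "pattern.tsv")
  write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  cp <- load_clinical_pattern(p, rois)
  expect_equal(cp$sampled_rois, c(2L, 4L, 5L))
  expect_equal(unname(cp$activation_step), c(2, 1, 3))

  # coordinate columns instead of roi_id
  df2 <- data.frame(cp_id = 1:2, electrode_id = 1,
                    x_mm = c(0.2, 41), y_mm = 0, z_mm = 0,
                    activation_step = c(1, 2))
  p2 <- file.path(dir, "pattern_xyz.tsv")
  write.table(df2, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  cp2 <- load_clinical_pattern(p2, rois)
  expect_equal(cp2$sampled_rois, c(1L, 5L))

  df$activation_step[1] <- 0
  write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_clinical_pattern(p, rois), "positive")
})

test_that("model patterns rank simulated times over the sampled subset", {
  times <- setNames(c(5, 1, 3, 2, 4), 1:5)
  mp <- model_pattern(times, c(1, 3, 5))
  expect_equal(unname(mp$ranks), c(3, 1, 2))
  mp2 <- model_pattern(setNames(c(1, 1, 1), 1:3), 1:3)
  expect_equal(unname(mp2$ranks), c(2, 2, 2))
  expect_equal(unname(model_pattern(setNames(c(.2, .2, .9), 1:3), 1:3)$ranks),
               c(1.5, 1.5, 3))
  expect_error(model_pattern(times, c(1, 9)), "missing")
  expect_error(model_pattern(setNames(c(1, NA, 2), 1:3), 1:3), "unreachable")
})

test_that("rank correlation reproduces the covariance formula exactly", {
  expect_equal(pattern_correlation(c(1, 2, 3), c(1, 2, 3), n_perm = 50,
                                   rng_seed = 1)$C, 1)
  expect_equal(pattern_correlation(c(1, 2, 3), c(3, 2, 1), n_perm = 50,
                                   rng_seed = 1)$C, -1)
  # frozen hand evaluation of the formula with population moments
  expect_equal(pattern_correlation(c(1.5, 1.5, 3), c(1, 2, 3), n_perm = 50,
                                   rng_seed = 1)$C, 0.8660254,
               tolerance = 1e-6)
  # brute-force oracle identity and tie-corrected Spearman identity on
  # random tied rankings
  set.seed(42)
  for (k in 1:10) {
    n <- sample(5:30, 1)
    a <- midpoint_ranks(sample(1:6, n, replace = TRUE))
    b <- midpoint_ranks(sample(1:8, n, replace = TRUE))
    if (sd(a) == 0 || sd(b) == 0) next
    C <- pattern_correlation(a, b, n_perm = 10, rng_seed = k)$C
    expect_equal(C, brute_eq1(a, b))
    expect_equal(C, unname(cor(a, b, method = "spearman")))
  }
  expect_error(pattern_correlation(c(1, 1, 1), c(1, 2, 3), n_perm = 10),
               "constant")
  expect_error(pattern_correlation(c(1, 2), c(1, 2), n_perm = 10), "3")
})

test_that("permutation significance separates real from random rankings", {
  set.seed(7)
  a <- midpoint_ranks(1:12)
  aligned <- pattern_correlation(a, midpoint_ranks(1:12 + rnorm(12, 0, 0.1)),
                                 n_perm = 2000, rng_seed = 1)
  expect_lt(aligned$p, 0.01)
  random_p <- vapply(1:20, function(i) {
    pattern_correlation(a, sample(a), n_perm = 500, rng_seed = i)$p
  }, numeric(1))
  expect_gt(mean(random_p >= 0.05), 0.6)
})

test_that("first-maximum selection prefers the sparsest comparable peak", {
  fm <- epispread:::first_maximum
  # bimodal: low-density peak within the 1% prominence band of the
  # global one is chosen
  C <- c(0.2, 0.608, 0.5, 0.4, 0.61, 0.3)
  p <- rep(0.001, 6)
  expect_equal(fm(C, p)$index, 2)
  # a small early bump far below the best peak is skipped
  C2 <- c(0.45, 0.2, 0.6, 0.9, 0.85, 0.3)
  expect_equal(fm(C2, p)$index, 4)
  # nothing significant: global max with non-significant flag
  sel <- fm(C, rep(0.5, 6))
  expect_false(sel$significant)
  expect_equal(sel$index, 5)
  # significance gates the candidate set
  p3 <- c(0.001, 0.5, 0.001, 0.001, 0.001, 0.001)
  expect_equal(fm(C2, p3)$index, 4)
})

test_that("density fitting recovers a planted threshold on one patient", {
  pat <- generate_patient(synthetic_patient_config(rng_seed = 501))
  fit <- fit_threshold(pat$network, pat$clinical, pat$seed, n_runs = 500,
                       n_perm = 500, rng_seed = 601)
  expect_s3_class(fit, "fit_result")
  expect_equal(fit$curve$theta, default_theta_grid())
  expect_equal(fit$kappa_max, fit$theta_max * 90)
  expect_true(fit$theta_max %in% c(0.08, 0.10, 0.15))
  expect_true(fit$significant)
  expect_gt(fit$c_max, 0.8)
  # deterministic given the master seed
  fit2 <- fit_threshold(pat$network, pat$clinical, pat$seed, n_runs = 500,
                        n_perm = 500, rng_seed = 601)
  expect_identical(fit$curve, fit2$curve)

  dir <- withr::local_tempdir()
  export_fit_result(fit, file.path(dir, "curve.tsv"),
                    file.path(dir, "fit.json"))
  curve <- read.table(file.path(dir, "curve.tsv"), header = TRUE, sep = "\t")
  expect_equal(curve$C, fit$curve$C)
  expect_equal(jsonlite::fromJSON(file.path(dir, "fit.json"))$theta_max,
               fit$theta_max)
})

test_that("median curve can peak where no individual curve does", {
  grid <- c(0.1, 0.2, 0.3)
  mk <- function(C) list(curve = data.frame(theta = grid, kappa = grid * 10,
                                            C = C, p = 0.01))
  # individual argmaxes at positions 1, 3, 1; the median's argmax is at
  # position 2 where no single patient peaks
  fits <- list(mk(c(0.9, 0.85, 0.1)), mk(c(0.1, 0.85, 0.9)),
               mk(c(0.8, 0.75, 0.7)))
  med <- median_correlation_curve(fits)
  expect_equal(med$curve$C_median, c(0.8, 0.85, 0.7))
  expect_equal(med$theta_max, 0.2)
  args <- vapply(fits, function(f) which.max(f$curve$C), integer(1))
  expect_false(which.max(med$curve$C_median) %in% args)

  expect_equal(median_correlation_curve(fits[1])$curve$C_median,
               fits[[1]]$curve$C)
  expect_error(median_correlation_curve(list()), "empty")
  bad <- mk(c(0.1, 0.2, 0.3)); bad$curve$theta <- c(0.1, 0.2, 0.4)
  expect_error(median_correlation_curve(list(mk(c(1, 1, 1)), bad)), "grid")
})

test_that("fully connected baseline degenerates to tied ranks by symmetry", {
  cp <- clinical_pattern(c(10, 11, 12, 13), c(1, 2, 2, 3))
  # seed outside the sampled set: model ranking fully tied
  base <- fully_connected_baseline(cp, seed = 1, n_rois = 20, n_perm = 100)
  expect_true(base$degenerate)
  expect_equal(base$C, 0)
  # multi-node seed: still fully tied outside the seed
  base2 <- fully_connected_baseline(cp, seed = 1:3, n_rois = 20, n_perm = 100)
  expect_true(base2$degenerate)
  # a sampled seed ROI breaks the tie
  base3 <- fully_connected_baseline(cp, seed = 10, n_rois = 20,
                                    n_perm = 2000, rng_seed = 1)
  expect_false(base3$degenerate)
  expect_gt(base3$C, 0)
})
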