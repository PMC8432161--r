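# Feature channels: depth sampling, normalization, asymmetry, the design
# matrix.

test_that("depth sampling: constant, linear ramp, identity cases", {
  # vertical 2 mm cortex above a flat white sheet at z = 0
  white <- grid_surface(5, 5)
  gray <- white
  gray$vertices[, 3] <- 2
  vol_dim <- c(8, 8, 9)
  vox2ras <- rbind(cbind(diag(3), c(-1, -1, -4)), c(0, 0, 0, 1))
  const <- list(data = array(100, vol_dim), vox2ras = vox2ras)
  expect_equal(as.numeric(sample_at_depth(const, white, gray, 0.4)),
               rep(100, 25))
  # ramp I(x, y, z) = z (voxel k at z = k - 4)
  ramp <- list(data = array(rep(0:8 - 4, each = 64), vol_dim),
               vox2ras = vox2ras)
  expect_equal(as.numeric(sample_at_depth(ramp, white, gray, 0.5)),
               rep(1, 25), tolerance = 1e-9)
  expect_equal(as.numeric(sample_at_depth(ramp, white, gray, 0)),
               rep(0, 25), tolerance = 1e-9)
  expect_equal(as.numeric(sample_at_depth(ramp, white, gray,
                                          subcortical_mm = 1)),
               rep(-1, 25), tolerance = 1e-9)
  # out-of-volume points masked with a warning
  far <- white; far$vertices[, 3] <- -50
  expect_warning(out <- sample_at_depth(ramp, far, gray, 0),
                 "outside the volume")
  expect_true(all(is.na(as.numeric(out))))
})

test_that("within-subject z-scoring: closed form, degenerate, idempotent", {
  z <- as.numeric(normalize_within_subject(c(1, 2, 3)))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_warning(zc <- normalize_within_subject(rep(5, 10)),
                 "constant")
  expect_equal(as.numeric(zc), rep(0, 10))
  set.seed(3)
  x <- stats::rnorm(200, 7, 3)
  z1 <- as.numeric(normalize_within_subject(x))
  expect_equal(mean(z1), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z1^2)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(normalize_within_subject(z1)), z1,
               tolerance = 1e-9)
  expect_error(normalize_within_subject(c(1, NA, NA)), ">= 2")
})

test_that("between-subject z-scoring uses control stats with an sd floor", {
  pair <- make_hemisphere_pair(2)
  controls <- lapply(1:6, function(i) generate_control(pair, 100 + i))
  st <- control_stats(controls)
  expect_equal(st$n_controls, 6L)
  # direct arithmetic: mean 2.5, sd 0.25, value 3.0 -> z = 2
  st2 <- st
  st2$mean[, "thickness"] <- 2.5
  st2$sd[, "thickness"] <- 0.25
  x <- rep(3.0, pair$n_vertices)
  expect_equal(as.numeric(normalize_between_subjects(x, st2, "thickness")),
               rep(2, pair$n_vertices))
  # floor rule
  st2$sd[1, "thickness"] <- 0
  z <- as.numeric(normalize_between_subjects(x, st2, "thickness"))
  expect_equal(z[1], 0.5 / st2$sd_floor[["thickness"]])
  expect_error(normalize_between_subjects(x, st, "nope"), "absent")
  # a control from the stats population recentres near 0
  z_self <- as.numeric(normalize_between_subjects(
    controls[[1]]$left[, "thickness"], st, "thickness"))
  expect_lt(abs(mean(z_self)), 0.5)
})

test_that("asymmetry maps are exact antisymmetric differences", {
  a <- interhemispheric_asymmetry(c(1, 2), c(0, 2))
  expect_equal(as.numeric(a$left), c(1, 0))
  expect_equal(as.numeric(a$right), c(-1, 0))
  set.seed(11)
  l <- stats::rnorm(50); r <- stats::rnorm(50)
  a <- interhemispheric_asymmetry(l, r)
  expect_equal(as.numeric(a$left) + as.numeric(a$right), rep(0, 50))
  expect_error(interhemispheric_asymmetry(1:3, 1:4), "length")
  # identical hemispheres give all-zero maps
  a0 <- interhemispheric_asymmetry(l, l)
  expect_equal(as.numeric(a0$left), rep(0, 50))
})

test_that("design matrix has 22 stable, fully named columns", {
  pair <- make_hemisphere_pair(2)
  cohort <- generate_cohort(synthetic_cohort_spec(
    n_patients = 2, n_controls = 3, subdivision = 2), seed = 5L)
  prep <- prepare_cohort_features(cohort)
  m <- prep$subjects[[1]]$matrices$left
  expect_equal(ncol(m), 22L)
  expect_identical(colnames(m),
                   c(FEATURE_CHANNELS, paste0("asym_", FEATURE_CHANNELS)))
  m2 <- build_feature_matrix(prep$subjects[[1]]$features, "left")
  expect_identical(m, m2)  # byte-identical across calls
  fs <- prep$subjects[[1]]$features
  fs$left <- fs$left[, -1]
  expect_error(build_feature_matrix(fs, "left"), "thickness")
  raw <- cohort$patients[[1]]$features
  expect_error(build_feature_matrix(raw, "left"), "asymmetry-augmented")
})

test_that("feature set stages move only forward", {
  pair <- make_hemisphere_pair(2)
  fs <- generate_control(pair, 1)
  expect_equal(fs$stage, "raw")
  expect_error(feature_set(fs$left, fs$right, stage = "raw",
                           asymmetry = list()), "asymmetry")
  surf <- pair$left$mid
  half <- preprocess_features(fs, surf)
  expect_equal(half$stage, "normalized")
  expect_error(preprocess_features(half, surf), "raw-stage")
})
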