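# Synthetic cohort generator.

test_that("icosphere subdivision gives 10*4^n + 2 vertices", {
  for (n in 1:3) {
    ico <- icosphere(n)
    expect_equal(nrow(ico$vertices), 10L * 4L^n + 2L)
    expect_equal(sqrt(rowSums(ico$vertices^2)),
                 rep(1, nrow(ico$vertices)), tolerance = 1e-12)
  }
})

test_that("hemisphere pairs mirror in x and encode the thickness field", {
  pair <- make_hemisphere_pair(2)
  l <- pair$left$white$vertices; r <- pair$right$white$vertices
  expect_equal(l[, 1], -r[, 1], tolerance = 1e-9)
  expect_equal(l[, 2:3], r[, 2:3], tolerance = 1e-9)
  # gray - white offset equals the generating thickness field
  off <- pair$right$gray$vertices - pair$right$white$vertices
  expect_equal(sqrt(rowSums(off^2)), pair$thickness, tolerance = 1e-9)
  off_l <- pair$left$gray$vertices - pair$left$white$vertices
  expect_equal(sqrt(rowSums(off_l^2)), pair$thickness, tolerance = 1e-9)
  # identity template correspondence
  expect_identical(pair$correspondence, seq_len(pair$n_vertices))
})

test_that("controls are seeded and recover the generating fields", {
  pair <- make_hemisphere_pair(2)
  expect_identical(generate_control(pair, 77), generate_control(pair, 77))
  controls <- lapply(1:20, function(i) generate_control(pair, 200 + i))
  model <- lesionplan:::channel_model()
  u <- pair$units
  for (ch in c("thickness", "flair_50")) {
    i <- match(ch, model$channel)
    gen_mean <- model$mean[i] + model$amplitude[i] *
      lesionplan:::smooth_sphere_field(u, model$field[i])
    emp <- rowMeans(vapply(controls, function(fs) fs$left[, ch],
                           numeric(pair$n_vertices)))
    se <- model$sd[i] / sqrt(20)
    expect_lt(mean(abs(emp - gen_mean) > 3 * se), 0.02)
  }
  # a fresh control z-scored against control stats pools to ~N(0,1)
  st <- control_stats(controls)
  fresh <- generate_control(pair, 999)
  z <- as.numeric(normalize_between_subjects(fresh$left[, "thickness"],
                                             st, "thickness"))
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(stats::sd(z) - 1), 0.15)
})

test_that("lesion injection: zero effects, z recovery, mask geometry", {
  pair <- make_hemisphere_pair(4)
  fs <- generate_control(pair, 999)
  zero <- inject_lesion(fs, pair, center_vertex = 10, hemisphere = "left",
                        radius_mm = 12,
                        effects = default_lesion_effects(0))
  expect_identical(zero$features$left, fs$left)
  expect_gt(sum(zero$mask), 0)

  # +2 sd thickness effect recovered in between-subject z within 0.3
  controls <- lapply(1:10, function(i) generate_control(pair, 300 + i))
  st <- control_stats(controls)
  ef <- stats::setNames(numeric(length(FEATURE_CHANNELS)),
                        FEATURE_CHANNELS)
  ef["thickness"] <- 2
  les <- inject_lesion(fs, pair, center_vertex = 10, hemisphere = "left",
                       radius_mm = 15, effects = ef)
  z1 <- as.numeric(normalize_between_subjects(
    les$features$left[, "thickness"], st, "thickness"))
  z0 <- as.numeric(normalize_between_subjects(fs$left[, "thickness"], st,
                                              "thickness"))
  expect_equal(mean((z1 - z0)[les$mask]), 2, tolerance = 0.3)
  # contralateral untouched
  expect_identical(les$features$right, fs$right)

  # mask area close to pi r^2
  for (r in c(12, 15, 20)) {
    l <- inject_lesion(fs, pair, center_vertex = 10, hemisphere = "left",
                       radius_mm = r, effects = ef)
    expect_equal(l$area_mm2, pi * r^2, tolerance = 0.15 * pi * r^2)
  }
  expect_error(inject_lesion(fs, pair, 10, "left", radius_mm = 1000,
                             effects = ef), "extent")
})

test_that("electrode trajectories: spacing, SOZ labelling, laterality", {
  pair <- make_hemisphere_pair(3)
  fs <- generate_control(pair, 5)
  les <- inject_lesion(fs, pair, center_vertex = 50, hemisphere = "left",
                       radius_mm = 12)
  el <- generate_electrodes(pair, targets = 50, target_hemis = "left",
                            mask_vertices = which(les$mask),
                            mask_hemisphere = "left",
                            n_contacts = 8, spacing_mm = 3.5)
  expect_equal(nrow(el), 8L)
  p1 <- as.numeric(el[1, c("x", "y", "z")])
  p8 <- as.numeric(el[8, c("x", "y", "z")])
  expect_equal(sqrt(sum((p8 - p1)^2)), 24.5, tolerance = 1e-9)
  # lesion-targeted electrode has an SOZ contact within 10 mm of mask
  mask_xyz <- pair$left$mid$vertices[which(les$mask), , drop = FALSE]
  soz <- el[el$label == "SOZ", c("x", "y", "z")]
  expect_gt(nrow(soz), 0)
  dmin <- apply(as.matrix(soz), 1, function(p)
    sqrt(min(rowSums(sweep(mask_xyz, 2, p)^2))))
  expect_true(any(dmin < 10))
  # contralateral electrode picks up no SOZ labels
  el_r <- generate_electrodes(pair, targets = 50, target_hemis = "right",
                              mask_vertices = which(les$mask),
                              mask_hemisphere = "left")
  expect_false(any(el_r$label == "SOZ"))
})

test_that("cohorts are reproducible end to end from one seed", {
  spec <- synthetic_cohort_spec(n_patients = 2, n_controls = 2,
                                subdivision = 2)
  c1 <- generate_cohort(spec, seed = 17L)
  c2 <- generate_cohort(spec, seed = 17L)
  expect_identical(c1$patients[[1]]$features, c2$patients[[1]]$features)
  expect_identical(c1$patients[[2]]$electrodes,
                   c2$patients[[2]]$electrodes)
  expect_identical(c1$controls, c2$controls)
  # lesions respect the truncation floor (300 mm^2 equivalent)
  mesh_area <- sum(lesionplan:::triangle_areas(c1$pair$left$mid))
  floor_area <- 300 * mesh_area / spec$reference_hemi_area_mm2
  for (p in c1$patients) expect_gte(p$lesion$area_mm2, floor_area * 0.8)
})

test_that("simulated cohorts write to standard formats on disk", {
  spec <- synthetic_cohort_spec(n_patients = 2, n_controls = 2,
                                subdivision = 2)
  cohort <- generate_cohort(spec, seed = 23L)
  dir <- withr::local_tempdir()
  write_cohort_dir(cohort, dir)
  surf <- read_surface(file.path(dir, "left.white.surf"))
  expect_equal(nrow(surf$vertices), cohort$pair$n_vertices)
  ov <- read_overlay(file.path(dir, "P01_left_thickness.curv"), surf)
  expect_equal(as.numeric(ov),
               cohort$patients[[1]]$features$left[, "thickness"],
               tolerance = 1e-6)
  contacts <- read_contacts(file.path(dir, "P01_contacts.csv"))
  expect_equal(nrow(contacts), spec$n_electrodes * spec$n_contacts)
  aff <- read_affine(file.path(dir, "contacts_to_surface.txt"))
  expect_equal(aff$matrix, diag(4), ignore_attr = TRUE)
})
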