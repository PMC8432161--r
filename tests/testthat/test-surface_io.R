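# File-format readers and writers.

test_that("FreeSurfer surface round-trips and rejects malformed files", {
  ico <- unit_icosahedron()
  path <- withr::local_tempfile(fileext = ".surf")
  write_surface(ico, path)
  back <- read_surface(path, hemisphere = "left", surface_kind = "mid")
  expect_equal(nrow(back$vertices), 12L)
  expect_equal(nrow(back$triangles), 20L)
  expect_equal(back$vertices, ico$vertices, tolerance = 1e-6)
  expect_equal(back$triangles, ico$triangles)

  # truncated file
  raw <- readBin(path, "raw", n = file.size(path))
  trunc <- withr::local_tempfile(fileext = ".surf")
  writeBin(raw[1:40], trunc)
  expect_error(read_surface(trunc), "truncated|malformed")

  # bad magic number
  bad <- withr::local_tempfile(fileext = ".surf")
  writeBin(as.raw(c(0x00, 0x01, 0x02, 0x0A, 0x0A)), bad)
  expect_error(read_surface(bad), "magic")
})

test_that("curv/MGH overlays round-trip and enforce length", {
  ico <- unit_icosahedron()
  vals <- rep(0.5, 12)
  p <- withr::local_tempfile(fileext = ".curv")
  write_curv(vals, p)
  expect_equal(as.numeric(read_overlay(p, ico)), vals)

  mask <- c(rep(1, 5), rep(0, 7))
  write_curv(mask, p)
  expect_identical(as.numeric(read_overlay(p, ico)), mask)

  write_curv(seq_len(11), p)
  expect_error(read_overlay(p, ico), "length 11.*12")

  m <- withr::local_tempfile(fileext = ".mgh")
  x <- stats::rnorm(12)
  write_mgh(x, m)
  expect_equal(as.numeric(read_overlay(m, ico)), x, tolerance = 1e-6)
})

test_that("MGH volumes round-trip with their affine", {
  vol <- array(stats::rnorm(4 * 5 * 6), c(4, 5, 6))
  a <- rbind(cbind(diag(3) * 2, c(-4, -5, -6)), c(0, 0, 0, 1))
  p <- withr::local_tempfile(fileext = ".mgh")
  write_mgh(vol, p, vox2ras = a)
  back <- read_mgh(p)
  expect_equal(back$data[, , , 1], vol, tolerance = 1e-6)
  expect_equal(back$vox2ras, a, tolerance = 1e-5)
})

test_that("contacts parse from CSV and FCSV identically, labels closed", {
  df <- data.frame(electrode = "LA", contact = 1:8,
                   x = seq(0, 24.5, by = 3.5), y = 2, z = 3,
                   label = c("SOZ", "SOZ", "irritative", rep("uninvolved",
                                                             5)))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  from_csv <- read_contacts(csv)
  expect_equal(nrow(from_csv), 8L)
  expect_equal(from_csv$x, df$x)

  fcsv <- withr::local_tempfile(fileext = ".fcsv")
  lines <- c("# Markups fiducial file version = 4.11",
             "# CoordinateSystem = RAS",
             "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
             sprintf("vtkMRMLMarkupsFiducialNode_%d,%g,%g,%g,0,0,0,1,1,1,0,LA-%d,%s,",
                     1:8, df$x, df$y, df$z, 1:8, df$label))
  writeLines(lines, fcsv)
  from_fcsv <- read_contacts(fcsv)
  expect_equal(from_fcsv$x, from_csv$x)
  expect_equal(from_fcsv$label, from_csv$label)
  expect_equal(from_fcsv$contact, from_csv$contact)

  df$label[1] <- "ictal"
  bad <- write_tmp_cohort_csv(df)
  expect_error(read_contacts(bad), "ictal.*SOZ, irritative, uninvolved")
})

test_that("affine io validates, round-trips, applies and inverts", {
  m <- rbind(cbind(diag(3), c(10, 0, 0)), c(0, 0, 0, 1))
  p <- withr::local_tempfile(fileext = ".txt")
  write_affine(m, p)
  aff <- read_affine(p)
  expect_equal(aff$matrix, m, ignore_attr = TRUE)
  pts <- matrix(stats::rnorm(15), ncol = 3)
  moved <- apply_affine(aff, pts)
  expect_equal(moved[, 1], pts[, 1] + 10)
  inv <- affine_transform(solve(m))
  expect_equal(apply_affine(inv, moved), pts, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(affine_transform(matrix(1, 4, 4)), "last row|invertible")
  expect_error(affine_transform(rbind(matrix(0, 3, 4), c(0, 0, 0, 1))),
               "invertible")
})

test_that("cohort table reads the packaged fixture and validates enums", {
  tb <- table1_fixture()
  expect_s3_class(tb, "patient_cohort")
  expect_equal(nrow(tb), 34L)
  p7 <- tb[tb$patient_id == "7", ]
  expect_equal(p7$histology, "FCD IIB")
  expect_equal(p7$concordance, "yes")
  expect_equal(p7$seeg_indication, "discordance")
  p22 <- tb[tb$patient_id == "22", ]
  expect_equal(p22$seeg_outcome, "mTLE")
  expect_equal(p22$n_clusters, 1L)
  expect_equal(p22$concordance, "not-applicable")
  p1 <- tb[tb$patient_id == "1", ]
  expect_equal(p1$surgery, "thermocoagulation+laser")
  expect_equal(p1$seizure_free, "yes")
  expect_equal(p1$followup_months, 4L)
  # missing follow-up is NA, never 0
  expect_true(all(is.na(tb$followup_months[tb$surgery == "no"])))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient,seeg_indication,seeg_outcome,n_clusters,concordance,surgery,histology,outcome,followup_months",
             empty)
  expect_equal(nrow(read_cohort_table(empty)), 0L)

  df <- utils::read.csv(cohort_fixture_path(), check.names = FALSE)
  df$seeg_outcome[3] <- "unknown-outcome"
  expect_error(read_cohort_table(write_tmp_cohort_csv(df)),
               "unknown-outcome.*patient 3")

  # concordance/outcome consistency invariant
  df <- utils::read.csv(cohort_fixture_path(), check.names = FALSE)
  df$concordance[22] <- "Y"  # mTLE patient cannot be concordant
  expect_error(read_cohort_table(write_tmp_cohort_csv(df)),
               "not-applicable")
})

test_that("surface validation catches broken meshes", {
  ico <- unit_icosahedron()
  expect_error(hemi_surface(ico$vertices, rbind(ico$triangles,
                                                c(1, 2, 99))),
               "out of range")
  expect_error(hemi_surface(rbind(ico$vertices, c(9, 9, 9)),
                            ico$triangles), "isolated")
})
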