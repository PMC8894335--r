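# Synthetic cohort generator: counts, determinism, geometry encoding.

test_that("generated cohorts match the configured per-center class counts", {
  co <- generate_cohort(study_center_profiles(), master_seed = 1)
  expect_equal(nrow(co), 180L)
  tab <- table(co$center, co$label)
  expect_equal(unname(tab["VallHebron", c("NOR", "HCM")]), c(21L, 25L))
  expect_equal(unname(tab["SagradaFamilia", c("NOR", "HCM")]), c(33L, 37L))
  expect_equal(unname(tab["SantPau", c("NOR", "HCM")]), c(14L, 10L))
  expect_equal(unname(tab["ACDC", c("NOR", "HCM")]), c(20L, 20L))
  expect_equal(sum(co$label == "NOR"), 88L)
  expect_equal(sum(co$label == "HCM"), 92L)
})

test_that("empty centers yield empty manifests and bad geometry errors", {
  empty <- generate_cohort(list(center_profile("none", 0, 0)), master_seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_error(geometry_config(nor_wall_range = c(6, 18)), "overlap")
})

test_that("cohorts are reproducible under a fixed master seed", {
  profiles <- list(center_profile("X", 2, 3), center_profile("Y", 1, 1))
  a <- generate_cohort(profiles, master_seed = 7)
  b <- generate_cohort(profiles, master_seed = 7)
  expect_identical(a, b)
  c2 <- generate_cohort(profiles, master_seed = 8)
  expect_false(identical(a$wall_ed, c2$wall_ed))
})

test_that("rendered phantoms are reproducible voxel-for-voxel", {
  fx <- tiny_pipeline_fixture()
  subj <- fx$cohort[1, ]
  prof <- fx$profiles[[1]]
  v1 <- render_phantom(subj, "ED", prof)
  v2 <- render_phantom(subj, "ED", prof)
  expect_identical(v1$image, v2$image)
  expect_identical(v1$mask, v2$mask)
})

test_that("uncorrupted phantoms are piecewise constant over mask regions", {
  v <- clean_volume()
  for (lab in 0:3) {
    vals <- v$image[v$mask == lab]
    expect_lt(max(vals) - min(vals), 1e-12)
  }
  # blood pools > myocardium > background contrast ordering
  expect_gt(v$image[v$mask == 1][1], v$image[v$mask == 2][1])
  expect_gt(v$image[v$mask == 3][1], v$image[v$mask == 2][1])
  expect_gt(v$image[v$mask == 2][1], v$image[v$mask == 0][1])
})

test_that("wall thickness oracle recovers an analytic shell", {
  mask <- shell_mask(inner = 25, outer = 35, spacing = c(1, 1, 5))
  t1 <- measure_wall_thickness(mask, c(1, 1, 5))
  expect_lt(abs(t1 - 10), 1.2)  # voxelization tolerance
  # doubling the spacing doubles the measured thickness
  t2 <- measure_wall_thickness(mask, c(2, 2, 10))
  expect_equal(t2, 2 * t1, tolerance = 1e-10)
  empty <- array(0L, dim = c(4, 4, 2))
  expect_error(measure_wall_thickness(empty, c(1, 1, 1)), "myocardium")
})

test_that("HCM and NOR wall-thickness distributions are disjoint", {
  prof <- center_profile("sep", 25, 25, native_spacing = c(1, 1, 5))
  co <- generate_cohort(list(prof), master_seed = 42)
  idx_h <- which(co$label == "HCM")[1:8]
  idx_n <- which(co$label == "NOR")[1:8]
  th_h <- vapply(idx_h, function(i) {
    v <- render_phantom(co[i, ], "ED", prof)
    measure_wall_thickness(v$mask, v$spacing)
  }, 1.0)
  th_n <- vapply(idx_n, function(i) {
    v <- render_phantom(co[i, ], "ED", prof)
    measure_wall_thickness(v$mask, v$spacing)
  }, 1.0)
  expect_gt(min(th_h), 15)   # HCM analogue: wall thickness above 15 mm
  expect_lt(max(th_n), 15)
  expect_gt(min(th_h), max(th_n))
  # manifest geometry itself is strictly separated at any n
  expect_gt(min(co$wall_ed[co$label == "HCM"]),
            max(co$wall_ed[co$label == "NOR"]))
})

test_that("end-systole contracts the blood pools", {
  fx <- tiny_pipeline_fixture()
  subj <- fx$cohort[1, ]
  prof <- fx$profiles[[1]]
  ed <- render_phantom(subj, "ED", prof)
  es <- render_phantom(subj, "ES", prof)
  expect_lt(sum(es$mask == 1L), sum(ed$mask == 1L))
  expect_lt(subj$r_endo_es, subj$r_endo_ed)
  expect_gt(subj$wall_es, subj$wall_ed)
})

test_that("center intensity offsets shift within-mask means accordingly", {
  profiles <- tiny_profiles(noise = 2)
  co <- generate_cohort(profiles, master_seed = 5)
  va <- render_phantom(co[co$center == "A", ][1, ], "ED", profiles[[1]])
  vb <- render_phantom(co[co$center == "B", ][1, ], "ED", profiles[[2]])
  ma <- mean(va$image[va$mask > 0])
  mb <- mean(vb$image[vb$mask > 0])
  offset_diff <- profiles[[2]]$intensity_offset - profiles[[1]]$intensity_offset
  expect_gt(mb - ma, offset_diff - 10)  # scale > 1 adds further shift
})

test_that("all three structures are present in every rendered mask", {
  fx <- tiny_pipeline_fixture()
  for (v in fx$volumes[1:4])
    expect_true(all(1:3 %in% unique(as.vector(v$mask))))
})

test_that("NIfTI export round-trips image, mask, and spacing", {
  prof <- center_profile("io", 1, 1, native_spacing = c(1.3, 1.3, 8),
                         noise_sigma = 1)
  co <- generate_cohort(list(prof), master_seed = 9)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_equal(nrow(manifest), 4L)  # 2 subjects x 2 timepoints
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  v <- read_volume(manifest$image_path[1], manifest$mask_path[1],
                   timepoint = manifest$timepoint[1])
  v0 <- render_phantom(co[1, ], manifest$timepoint[1], prof)
  expect_equal(v$spacing, v0$spacing, tolerance = 1e-6)
  expect_equal(v$image, v0$image, tolerance = 1e-6)
  expect_identical(v$mask, v0$mask)
})
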