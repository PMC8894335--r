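# Preprocessing chain: bias correction, resampling, cropping, curation.

test_that("bias correction reduces within-structure dispersion of a biased
           phantom and leaves clean phantoms nearly unchanged", {
  prof_biased <- center_profile("b", 1, 1, native_spacing = c(1, 1, 5),
                                bias_amplitude = 0.2)
  co <- generate_cohort(list(prof_biased), master_seed = 3)
  v <- render_phantom(co[1, ], "ED", prof_biased)
  cv <- function(x) stats::sd(x) / mean(x)
  corrected <- bias_field_correct(v)
  for (lab in 1:3)
    expect_lt(cv(corrected$image[v$mask == lab]),
              cv(v$image[v$mask == lab]))
  expect_identical(corrected$mask, v$mask)

  clean <- clean_volume()
  out <- bias_field_correct(clean)
  rel <- abs(out$image - clean$image) / (abs(clean$image) + 1e-9)
  expect_lt(stats::median(rel), 0.05)

  flat <- volume_sample(array(7, dim = c(8, 8, 4)),
                        array(1L, dim = c(8, 8, 4)), c(1, 1, 1))
  out_flat <- bias_field_correct(flat)
  expect_lt(max(abs(out_flat$image / out_flat$image[1] - 1)), 1e-6)

  bad <- clean
  bad$image[1] <- NaN
  expect_error(bias_field_correct(bad), "non-finite")
})

test_that("isotropic resampling follows extent arithmetic and preserves
           mask labels", {
  img <- array(stats::rnorm(50 * 50 * 5), dim = c(50, 50, 5))
  mask <- array(0L, dim = c(50, 50, 5))
  mask[20:30, 20:30, 2:4] <- 1L
  mask[31:35, 20:30, 2:4] <- 2L
  mask[36:40, 20:30, 2:4] <- 3L
  v <- volume_sample(img, mask, c(2, 2, 10))
  r <- resample_isotropic(v)
  expect_equal(dim(r$image), c(100L, 100L, 50L))
  expect_equal(r$spacing, c(1, 1, 1))
  expect_setequal(unique(as.vector(r$mask)), unique(as.vector(mask)))
  # physical extent of each structure preserved within a voxel
  expect_equal(sum(r$mask == 1L) * 1, sum(mask == 1L) * 2 * 2 * 10,
               tolerance = 0.12)

  already <- volume_sample(img, mask, c(1, 1, 1))
  expect_identical(resample_isotropic(already)$image, img)
})

test_that("cropping is centered on the mask bounding box and zero-pads", {
  img <- array(1, dim = c(300, 300, 20))
  mask <- array(0L, dim = c(300, 300, 20))
  mask[101:200, 101:200, 6:15] <- 1L  # bbox centered in the grid
  v <- volume_sample(img, mask, c(1, 1, 1))
  cropped <- crop_to_window(v)
  expect_equal(dim(cropped$image), c(150L, 150L, 10L))
  expect_true(all(cropped$image == 1))  # fully interior crop

  corner <- volume_sample(array(2, dim = c(60, 60, 6)),
                          array(0L, dim = c(60, 60, 6)), c(1, 1, 1))
  corner$mask[1:10, 1:10, 1:2] <- 1L
  out <- crop_to_window(corner)
  expect_equal(dim(out$image), c(150L, 150L, 10L))
  expect_true(any(out$image == 0))  # padded overhang
  expect_equal(sum(out$mask == 1L), sum(corner$mask == 1L))

  exact <- volume_sample(array(3, dim = c(150, 150, 10)),
                         array(1L, dim = c(150, 150, 10)), c(1, 1, 1))
  expect_identical(crop_to_window(exact)$image, exact$image)

  nomask <- volume_sample(array(1, dim = c(10, 10, 4)),
                          array(0L, dim = c(10, 10, 4)), c(1, 1, 1),
                          subject_id = "S9")
  expect_error(crop_to_window(nomask), "S9")
})

test_that("curation produces the three shape-prior set-ups correctly", {
  base <- toy_curated("baseline")
  expect_equal(dim(base$channels)[4], 3L)
  expect_identical(base$channels[, , , 1], base$channels[, , , 2])
  expect_identical(base$channels[, , , 1], base$channels[, , , 3])

  masked <- toy_curated("masked")
  expect_identical(masked$channels[, , , 1], masked$channels[, , , 2])

  ps <- toy_curated("per_structure")
  sup <- lapply(1:3, function(i) ps$channels[, , , i] != 0)
  expect_equal(sum(sup[[1]] & sup[[2]]), 0L)
  expect_equal(sum(sup[[1]] & sup[[3]]), 0L)
  expect_equal(sum(sup[[2]] & sup[[3]]), 0L)
  # channel sum identity: per-structure channels add up to the masked image
  expect_equal(ps$channels[, , , 1] + ps$channels[, , , 2] +
                 ps$channels[, , , 3],
               masked$channels[, , , 1])

  # masked with an all-foreground mask equals baseline
  dims <- c(12, 12, 4)
  img <- array(stats::runif(prod(dims)), dim = dims)
  allones <- volume_sample(img, array(1L, dim = dims), c(1, 1, 1))
  expect_identical(curate(allones, "masked")$channels,
                   curate(allones, "baseline")$channels)

  expect_error(curate(allones, "nonsense"))
})

test_that("metadata survives the full preprocessing chain", {
  fx <- tiny_pipeline_fixture()
  v <- fx$volumes[[3]]
  cur <- curate(v, "masked")
  key <- names(fx$volumes)[3]
  expect_equal(paste(cur$subject_id, cur$timepoint, sep = "_"), key)
  expect_equal(cur$label, fx$cohort$label[fx$cohort$subject_id == cur$subject_id])
  expect_equal(cur$center, fx$cohort$center[fx$cohort$subject_id == cur$subject_id])
})

test_that("timepoint extraction yields paired ED/ES samples per subject", {
  prof <- center_profile("tp", 1, 0, native_spacing = c(1.2, 1.2, 8),
                         noise_sigma = 1)
  co <- generate_cohort(list(prof), master_seed = 2)
  vols <- render_subject(co[1, ], prof)
  pair <- extract_timepoint_samples(vols, "masked", bias_correct = FALSE)
  expect_named(pair, c("ED", "ES"))
  expect_equal(pair$ED$subject_id, pair$ES$subject_id)
  expect_equal(pair$ED$label, pair$ES$label)
  expect_equal(pair$ED$center, pair$ES$center)
  expect_equal(dim(pair$ED$channels), c(150L, 150L, 10L, 3L))
  expect_error(extract_timepoint_samples(list(ED = vols$ED), "masked"),
               "ES")
})

test_that("a cohort of n subjects yields 2n training samples", {
  fx <- tiny_pipeline_fixture()
  expect_equal(length(fx$volumes), 2L * nrow(fx$cohort))
})
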