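# Federated histogram harmonization.

make_const_sample <- function(value, n = 6, mask_frac = 0.5) {
  img <- array(value, dim = c(n, n, 2))
  mask <- array(0L, dim = c(n, n, 2))
  mask[seq_len(round(n * mask_frac)), , ] <- 1L
  volume_sample(img, mask, c(1, 1, 1), subject_id = paste0("c", value))
}

test_that("subject histograms count the contributing voxels", {
  edges <- seq(0, 10, length.out = 11)
  s <- make_const_sample(3.5)
  h <- subject_histogram(s, restrict_to_mask = FALSE, edges)
  expect_equal(sum(h), length(s$image))
  expect_equal(h[4], length(s$image))  # all mass in the bin holding 3.5

  hm <- subject_histogram(s, restrict_to_mask = TRUE, edges)
  expect_equal(sum(hm), sum(s$mask > 0))

  # two-region phantom: bimodal counts matching region sizes
  img <- array(2, dim = c(10, 10, 2))
  img[1:4, , ] <- 8
  mask <- array(1L, dim = c(10, 10, 2))
  v <- volume_sample(img, mask, c(1, 1, 1))
  h2 <- subject_histogram(v, TRUE, edges)
  expect_equal(h2[3], sum(img == 2))
  expect_equal(h2[9], sum(img == 8))

  nomask <- volume_sample(img, array(0L, dim = dim(img)), c(1, 1, 1))
  expect_error(subject_histogram(nomask, TRUE, edges), "mask")
})

test_that("the federated average histogram is the per-sample mean", {
  edges <- c(0, 1, 2)
  # center A: one sample with normalized histogram (1, 0)
  a <- histogram_aggregate("A", edges, c(1, 0), 1)
  # center B: three samples, each (0, 1)
  b <- histogram_aggregate("B", edges, c(0, 3), 3)
  ref <- federated_average_histogram(list(a, b))
  expect_equal(ref$mass, c(0.25, 0.75))
  expect_equal(sum(ref$mass), 1)

  # single center: its own mean histogram
  solo <- federated_average_histogram(list(b))
  expect_equal(solo$mass, c(0, 1))

  # identical centers: the common histogram
  sym <- federated_average_histogram(list(a, histogram_aggregate("C", edges, c(2, 0), 2)))
  expect_equal(sym$mass, c(1, 0))

  mismatched <- histogram_aggregate("D", c(0, 0.5, 1), c(1, 0), 1)
  expect_error(federated_average_histogram(list(a, mismatched)), "bin_edges")
})

test_that("aggregation interfaces accept only histogram aggregates", {
  # the privacy contract: voxel data cannot cross the center boundary
  expect_error(federated_average_histogram(list(array(1, dim = c(4, 4, 2)))))
  s <- make_const_sample(2)
  expect_error(federated_average_histogram(list(s)))
})

test_that("standardization recovers a pure intensity shift", {
  set.seed(31)
  dims <- c(20, 20, 4)
  base_vals <- stats::rnorm(prod(dims), 50, 12)
  mask <- array(1L, dim = dims)
  ref_sample <- volume_sample(array(base_vals, dims), mask, c(1, 1, 1))
  shifted <- volume_sample(array(base_vals + 30, dims), mask, c(1, 1, 1))
  edges <- default_bin_edges(list(ref_sample), n_bins = 128)
  agg <- center_histogram_aggregate(list(ref_sample), "R", edges)
  ref <- federated_average_histogram(list(agg))

  map <- fit_standardization(shifted, ref)
  mapped <- apply_standardization(shifted$image, map)
  # inner landmarks should be mapped back by about -30
  mid <- stats::quantile(shifted$image, c(0.3, 0.5, 0.7))
  expect_equal(as.vector(apply_standardization(mid, map)), as.vector(mid) - 30,
               tolerance = 1.5)
  # post-hoc percentile agreement within a bin width
  bw <- diff(edges)[1]
  for (p in c(0.1, 0.5, 0.9))
    expect_lt(abs(stats::quantile(mapped, p) - stats::quantile(base_vals, p)),
              2 * bw)

  # self-matching is close to the identity
  self_map <- fit_standardization(ref_sample, ref)
  probe <- stats::quantile(base_vals, seq(0.05, 0.95, 0.1))
  expect_equal(as.vector(apply_standardization(probe, self_map)),
               as.vector(probe), tolerance = 1.0)
  expect_true(all(diff(self_map$target_landmarks) >= 0))
})

test_that("rescaling lands exactly on [0, 1] and preserves ordering", {
  set.seed(5)
  s <- volume_sample(array(stats::runif(800, 10, 60), c(10, 10, 8)),
                     array(1L, dim = c(10, 10, 8)), c(1, 1, 1))
  edges <- default_bin_edges(list(s))
  ref <- federated_average_histogram(list(
    center_histogram_aggregate(list(s), "A", edges)))
  map <- fit_standardization(s, ref)
  out <- standardize_and_rescale(s, map)
  expect_equal(min(out$image), 0)
  expect_equal(max(out$image), 1)
  ord <- order(s$image[1:50])
  expect_true(all(diff(out$image[1:50][ord]) >= -1e-12))

  # approximate idempotence: re-fitting on the standardized output barely
  # changes it
  edges2 <- default_bin_edges(list(out))
  ref2 <- federated_average_histogram(list(
    center_histogram_aggregate(list(out), "A", edges2)))
  map2 <- fit_standardization(out, ref2)
  out2 <- standardize_and_rescale(out, map2)
  expect_lt(mean(abs(out2$image - out$image)), 0.02)

  const <- volume_sample(array(4, dim = c(6, 6, 2)),
                         array(1L, dim = c(6, 6, 2)), c(1, 1, 1))
  expect_warning(m0 <- fit_standardization(const, ref), "degenerate")
  expect_warning(res <- standardize_and_rescale(const, m0), "zero")
  expect_true(all(res$image == 0.5))
})

test_that("harmonization shrinks inter-center histogram distance", {
  fx <- tiny_pipeline_fixture()
  volumes <- fx$volumes
  centers <- vapply(volumes, `[[`, "", "center")
  edges <- default_bin_edges(volumes)
  aggs <- lapply(unique(centers), function(ctr)
    center_histogram_aggregate(volumes[centers == ctr], ctr, edges))
  before <- mean_pairwise_l1(aggs)
  ref <- federated_average_histogram(aggs)
  std <- harmonize_samples(volumes, ref)
  edges2 <- default_bin_edges(std)
  aggs2 <- lapply(unique(centers), function(ctr)
    center_histogram_aggregate(std[centers == ctr], ctr, edges2))
  after <- mean_pairwise_l1(aggs2)
  expect_lt(after, 0.5 * before)
})

test_that("the LCO reference excludes the held-out center", {
  edges <- c(0, 1, 2, 3)
  aggs <- list(
    histogram_aggregate("A", edges, c(2, 0, 0), 2),
    histogram_aggregate("B", edges, c(0, 3, 0), 3),
    histogram_aggregate("C", edges, c(0, 0, 1), 1))
  lco <- build_reference_for_split(aggs, "LCO", test_center = "C")
  # identical to an average never exposed to C
  expect_equal(lco$mass,
               federated_average_histogram(aggs[1:2])$mass)
  expect_equal(lco$mass[3], 0)
  ccv <- build_reference_for_split(aggs, "CCV")
  expect_false(isTRUE(all.equal(ccv$mass, lco$mass)))
  expect_error(build_reference_for_split(aggs[3], "LCO", test_center = "C"),
               "empty")
  # one-center cohort under CCV: that center's own mean
  solo <- build_reference_for_split(aggs[1], "CCV")
  expect_equal(solo$mass, c(1, 0, 0))
})

test_that("reference histograms round-trip through CSV", {
  ref <- structure(list(bin_edges = c(0, 0.5, 1), mass = c(0.3, 0.7)),
                   class = "reference_histogram")
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_histogram(ref, path)
  back <- read_reference_histogram(path)
  expect_equal(back$bin_edges, ref$bin_edges)
  expect_equal(back$mass, ref$mass)
})
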