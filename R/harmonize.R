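# Privacy-preserving histogram harmonization --------------------------------
#
# Each center reduces its images to one aggregate histogram on a shared bin
# grid; only these aggregates cross center boundaries. The federated average
# histogram (the per-sample mean over all contributing images) serves as the
# Nyul-matching reference, followed by a rescale to [0, 1].

#' Shared histogram bin edges from a set of samples
#'
#' 256 bins over a robust range (0.5th to 99.5th percentile of the pooled
#' contributing intensities); values outside the range are clipped into the
#' outer bins when histograms are computed.
#'
#' @param samples list of `volume_sample`s.
#' @param restrict_to_mask use only voxels inside the segmentation mask.
#' @param n_bins number of bins (default 256).
#' @param probs robust range quantiles.
#' @return numeric vector of `n_bins + 1` strictly increasing bin edges.
#' @export
default_bin_edges <- function(samples, restrict_to_mask = TRUE,
                              n_bins = 256L, probs = c(0.005, 0.995)) {
  vals <- unlist(lapply(samples, function(s) {
    v <- if (restrict_to_mask) s$image[s$mask > 0L] else as.numeric(s$image)
    if (length(v) > 5000L) v[round(seq(1, length(v), length.out = 5000L))] else v
  }))
  r <- stats::quantile(vals, probs, names = FALSE)
  if (diff(r) <= 0) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = n_bins + 1L)
}

#' Histogram of one sample's intensities
#'
#' @param sample a `volume_sample`.
#' @param restrict_to_mask if `TRUE`, only voxels with mask > 0 contribute
#'   (the usual mode when inputs are mask-curated); otherwise all voxels.
#' @param bin_edges shared strictly increasing bin edges; out-of-range
#'   values are clipped into the first/last bin.
#' @return integer vector of per-bin counts; `sum(counts)` equals the number
#'   of contributing voxels.
#' @export
subject_histogram <- function(sample, restrict_to_mask = TRUE, bin_edges) {
  stopifnot(inherits(sample, "volume_sample"))
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  v <- if (restrict_to_mask) {
    if (!any(sample$mask > 0L))
      stop(sprintf("empty mask for subject %s under mask restriction",
                   sample$subject_id))
    sample$image[sample$mask > 0L]
  } else as.numeric(sample$image)
  n_bins <- length(bin_edges) - 1L
  idx <- findInterval(v, bin_edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  tabulate(idx, nbins = n_bins)
}

#' Build one center's aggregate histogram
#'
#' Each subject histogram is normalized to unit mass before summation, so
#' every image contributes equally regardless of its voxel count. The result
#' is the only object that leaves the center during harmonization.
#'
#' @param samples that center's `volume_sample`s.
#' @param center center name.
#' @param bin_edges shared bin edges.
#' @param restrict_to_mask passed to [subject_histogram].
#' @return a `histogram_aggregate`: list with `center`, `bin_edges`,
#'   `counts` (sum of per-sample normalized histograms) and `n_samples`.
#' @export
center_histogram_aggregate <- function(samples, center, bin_edges,
                                       restrict_to_mask = TRUE) {
  if (length(samples) < 1L) stop("a center aggregate needs >= 1 sample")
  counts <- rep(0, length(bin_edges) - 1L)
  for (s in samples) {
    h <- subject_histogram(s, restrict_to_mask, bin_edges)
    counts <- counts + h / sum(h)
  }
  histogram_aggregate(center, bin_edges, counts, length(samples))
}

#' Construct a histogram aggregate
#'
#' @param center center name.
#' @param bin_edges strictly increasing shared intensity grid.
#' @param counts per-bin non-negative summed (normalized) counts.
#' @param n_samples number of samples the counts sum over (N_k >= 1).
#' @return an object of class `histogram_aggregate`.
#' @export
histogram_aggregate <- function(center, bin_edges, counts, n_samples) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (length(counts) != length(bin_edges) - 1L)
    stop("counts length must equal length(bin_edges) - 1")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  structure(list(center = center, bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts),
                 n_samples = as.integer(n_samples)),
            class = "histogram_aggregate")
}

#' Federated average histogram across centers
#'
#' Computes the mean per-sample histogram over all contributing images,
#' `(1/N) * sum_k sum_n H_n^k` with `N = sum_k N_k`, so each center
#' contributes proportionally to its sample count; the result is normalized
#' to unit mass. Only [histogram_aggregate] objects are accepted: no voxel
#' data crosses the center boundary.
#'
#' @param aggregates list of `histogram_aggregate`s sharing one bin grid.
#' @return a `reference_histogram`: list with `bin_edges` and unit-mass
#'   `mass`.
#' @export
federated_average_histogram <- function(aggregates) {
  if (length(aggregates) < 1L) stop("need at least one aggregate")
  stopifnot(all(vapply(aggregates, inherits, TRUE, "histogram_aggregate")))
  edges <- aggregates[[1L]]$bin_edges
  for (a in aggregates)
    if (!isTRUE(all.equal(a$bin_edges, edges)))
      stop("aggregates use mismatched bin_edges")
  total <- Reduce(`+`, lapply(aggregates, `[[`, "counts"))
  n <- sum(vapply(aggregates, `[[`, 1L, "n_samples"))
  mass <- total / n
  mass <- mass / sum(mass)
  structure(list(bin_edges = edges, mass = mass),
            class = "reference_histogram")
}

# Quantiles of a binned histogram, linearly interpolated within bins.
histogram_quantiles <- function(ref, probs) {
  edges <- ref$bin_edges
  cum <- c(0, cumsum(ref$mass) / sum(ref$mass))
  # make strictly increasing for interpolation over empty bins
  keep <- c(TRUE, diff(cum) > 0)
  stats::approx(cum[keep], edges[keep], xout = probs, rule = 2)$y
}

#' Default Nyul landmark percentiles
#'
#' Deciles plus the 1st and 99th percentiles.
#' @return numeric probabilities.
#' @export
nyul_landmarks <- function() c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)

#' Fit a Nyul-style standardization map for one sample
#'
#' Piecewise-linear monotone map sending the sample's landmark percentiles
#' to the matching percentiles of the reference histogram; extrapolation
#' beyond the outer landmarks continues the first/last segment linearly.
#'
#' @param sample a `volume_sample`.
#' @param reference a `reference_histogram` from
#'   [federated_average_histogram].
#' @param percentile_landmarks landmark probabilities (default
#'   [nyul_landmarks]).
#' @param restrict_to_mask compute the sample's landmarks over masked voxels
#'   only.
#' @return a `standardization_map` with `source_landmarks`,
#'   `target_landmarks` and an applicable mapping (see
#'   [apply_standardization]).
#' @export
fit_standardization <- function(sample, reference,
                                percentile_landmarks = nyul_landmarks(),
                                restrict_to_mask = TRUE) {
  stopifnot(inherits(sample, "volume_sample"),
            inherits(reference, "reference_histogram"))
  if (sum(reference$mass) <= 0) stop("reference histogram has no mass")
  v <- if (restrict_to_mask) sample$image[sample$mask > 0L] else
    as.numeric(sample$image)
  src <- stats::quantile(v, percentile_landmarks, names = FALSE, type = 7)
  tgt <- histogram_quantiles(reference, percentile_landmarks)
  tgt <- cummax(tgt)  # enforce monotone targets
  keep <- !duplicated(src)  # collapse duplicated source landmarks
  src <- src[keep]; tgt <- tgt[keep]
  if (length(src) < 2L || max(src) - min(src) < 1e-12) {
    warning("degenerate (constant) sample intensities; using identity map")
    src <- src[1] + c(-0.5, 0.5)
    tgt <- src
  }
  structure(list(source_landmarks = src, target_landmarks = tgt,
                 probs = percentile_landmarks),
            class = "standardization_map")
}

#' Apply a standardization map to intensities
#'
#' Monotone piecewise-linear interpolation between landmarks with linear
#' extrapolation at the tails.
#'
#' @param x numeric vector or array of intensities.
#' @param map a `standardization_map`.
#' @return mapped intensities, same shape as `x`.
#' @export
apply_standardization <- function(x, map) {
  s <- map$source_landmarks; t <- map$target_landmarks
  out <- stats::approx(s, t, xout = as.numeric(x), rule = 2, ties = "ordered")$y
  # linear tail extrapolation (approx rule=2 is constant beyond the range)
  k <- length(s)
  lo_slope <- (t[2] - t[1]) / (s[2] - s[1])
  hi_slope <- (t[k] - t[k - 1]) / (s[k] - s[k - 1])
  below <- as.numeric(x) < s[1]; above <- as.numeric(x) > s[k]
  out[below] <- t[1] + lo_slope * (as.numeric(x)[below] - s[1])
  out[above] <- t[k] + hi_slope * (as.numeric(x)[above] - s[k])
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Standardize a sample and rescale to the unit interval
#'
#' Applies the map, then min-max rescales into [0, 1]. When masking is
#' active the rescaling range is computed over masked voxels and values
#' outside that range are clipped, so the rescaling support attains 0 and 1
#' exactly.
#'
#' @param sample a `volume_sample`.
#' @param map a `standardization_map`.
#' @param restrict_to_mask compute the rescaling range on masked voxels.
#' @return the standardized `volume_sample` with intensities in [0, 1].
#' @export
standardize_and_rescale <- function(sample, map, restrict_to_mask = TRUE) {
  stopifnot(inherits(sample, "volume_sample"),
            inherits(map, "standardization_map"))
  mapped <- apply_standardization(sample$image, map)
  sup <- if (restrict_to_mask) mapped[sample$mask > 0L] else
    as.numeric(mapped)
  lo <- min(sup); hi <- max(sup)
  out <- sample
  if (hi - lo < 1e-12) {
    warning("zero intensity range on the rescaling support; returning 0.5")
    out$image <- array(0.5, dim = dim(mapped))
  } else {
    out$image <- pmin(pmax((mapped - lo) / (hi - lo), 0), 1)
    dim(out$image) <- dim(mapped)
  }
  out
}

#' Build the matching reference for one cross-validation fold
#'
#' Under collaborative cross-validation (CCV) every center's aggregate
#' contributes; under leave-center-out (LCO) the held-out center is
#' excluded, so its test subjects are matched to a reference they did not
#' shape.
#'
#' @param aggregates named list of `histogram_aggregate`s (all centers).
#' @param scheme `"CCV"` or `"LCO"`.
#' @param test_center center name held out (required for LCO).
#' @return a `reference_histogram`.
#' @export
build_reference_for_split <- function(aggregates, scheme = c("CCV", "LCO"),
                                      test_center = NULL) {
  scheme <- match.arg(scheme)
  centers <- vapply(aggregates, `[[`, "", "center")
  use <- if (scheme == "LCO") {
    if (is.null(test_center)) stop("LCO requires a test_center")
    aggregates[centers != test_center]
  } else aggregates
  if (length(use) == 0L) stop("empty training-center set")
  federated_average_histogram(use)
}

#' Mean pairwise L1 distance between per-center mean histograms
#'
#' Quantifies inter-site intensity shift: the average L1 distance between
#' the unit-mass mean histograms of all center pairs. Harmonization should
#' shrink it.
#'
#' @param aggregates list of `histogram_aggregate`s on one bin grid.
#' @return non-negative scalar.
#' @export
mean_pairwise_l1 <- function(aggregates) {
  k <- length(aggregates)
  if (k < 2L) return(0)
  norm <- lapply(aggregates, function(a) a$counts / sum(a$counts))
  tot <- 0; np <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    tot <- tot + sum(abs(norm[[i]] - norm[[j]])); np <- np + 1
  }
  tot / np
}

#' Harmonize a list of samples against a reference
#'
#' Fits and applies a per-sample standardization map, then rescales to
#' [0, 1].
#'
#' @param samples list of `volume_sample`s.
#' @param reference a `reference_histogram`.
#' @param restrict_to_mask masked-value mode (default TRUE).
#' @return list of standardized `volume_sample`s.
#' @export
harmonize_samples <- function(samples, reference, restrict_to_mask = TRUE) {
  lapply(samples, function(s) {
    m <- fit_standardization(s, reference, restrict_to_mask = restrict_to_mask)
    standardize_and_rescale(s, m, restrict_to_mask = restrict_to_mask)
  })
}

#' Serialize a reference histogram to CSV
#' @param reference a `reference_histogram`.
#' @param path output CSV path (columns bin_lo, bin_hi, mass).
#' @export
write_reference_histogram <- function(reference, path) {
  utils::write.csv(data.frame(
    bin_lo = utils::head(reference$bin_edges, -1),
    bin_hi = reference$bin_edges[-1],
    mass = reference$mass), path, row.names = FALSE)
}

#' Read a reference histogram from CSV
#' @param path CSV written by [write_reference_histogram].
#' @return a `reference_histogram`.
#' @export
read_reference_histogram <- function(path) {
  df <- utils::read.csv(path)
  structure(list(bin_edges = c(df$bin_lo, df$bin_hi[nrow(df)]),
                 mass = df$mass), class = "reference_histogram")
}
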