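# Stochastic training-time augmentation -------------------------------------
#
# Four nested set-ups: none; basic (axial rotation, horizontal/vertical
# flip); shape (basic plus low-scale elastic deformation); shape_intensity
# (shape plus k-space spike artifact, multiplicative bias-field artifact,
# Gaussian noise with sigma ~ U(0, 0.25), random gamma). During training one
# transform is sampled uniformly from the pool and applied with probability
# 0.5, identically to all three channels.

#' Build an augmentation set-up
#'
#' @param name one of `"none"`, `"basic"`, `"shape"`, `"shape_intensity"`.
#' @param rotation_degrees maximum axial rotation magnitude (applied angle
#'   is uniform in +/- this range); default 15.
#' @param elastic_sd control-point displacement standard deviation in
#'   voxels (low scale by design); default 2.
#' @param elastic_grid control points per in-plane axis.
#' @param spike_relative_amplitude spike artifact amplitude relative to the
#'   intensity range.
#' @param bias_artifact_amplitude peak relative deviation of the random
#'   multiplicative field.
#' @param noise_sigma_max upper bound of the uniform draw of the Gaussian
#'   noise standard deviation (intensities assumed in [0, 1]).
#' @param gamma_log_range log-gamma uniform range for the random gamma
#'   transform.
#' @param apply_probability probability that a sampled transform is applied
#'   at all (default 0.5).
#' @return an `augmentation_setup` with an ordered transform `pool`.
#' @export
build_pool <- function(name = c("none", "basic", "shape", "shape_intensity"),
                       rotation_degrees = 15,
                       elastic_sd = 2, elastic_grid = 4,
                       spike_relative_amplitude = 0.15,
                       bias_artifact_amplitude = 0.3,
                       noise_sigma_max = 0.25,
                       gamma_log_range = c(-0.3, 0.3),
                       apply_probability = 0.5) {
  name <- match.arg(name)
  basic <- c("rotation", "hflip", "vflip")
  pool <- switch(name,
    none = character(0),
    basic = basic,
    shape = c(basic, "elastic"),
    shape_intensity = c(basic, "elastic", "spike", "bias_field", "noise",
                        "gamma"))
  structure(list(name = name, pool = pool,
                 apply_probability = apply_probability,
                 params = list(rotation_degrees = rotation_degrees,
                               elastic_sd = elastic_sd,
                               elastic_grid = elastic_grid,
                               spike_relative_amplitude = spike_relative_amplitude,
                               bias_artifact_amplitude = bias_artifact_amplitude,
                               noise_sigma_max = noise_sigma_max,
                               gamma_log_range = gamma_log_range)),
            class = "augmentation_setup")
}

#' Stochastically augment one curated sample
#'
#' With probability `apply_probability` (0.5 by default) one transform is
#' drawn uniformly from the set-up's pool and applied identically to all
#' three channels; otherwise the sample passes through unchanged. Labels and
#' metadata are never altered. Spatial transforms use bilinear resampling
#' for baseline/masked curation and nearest-neighbor resampling for
#' per-structure curation, which preserves the channels' disjoint supports.
#' Uses the current global RNG stream; seed it for reproducibility.
#'
#' @param sample a `curated_sample`.
#' @param setup an `augmentation_setup` from [build_pool].
#' @return the (possibly) augmented `curated_sample`.
#' @export
maybe_augment <- function(sample, setup) {
  stopifnot(inherits(sample, "curated_sample"),
            inherits(setup, "augmentation_setup"))
  if (setup$name == "none") return(sample)
  if (length(setup$pool) == 0L)
    stop("non-trivial set-up with an empty transform pool")
  if (stats::runif(1) >= setup$apply_probability) return(sample)
  tf <- setup$pool[sample.int(length(setup$pool), 1L)]
  apply_transform(sample, tf, setup$params)
}

apply_transform <- function(sample, tf, params) {
  ch <- sample$channels
  nn <- identical(sample$curation_type, "per_structure")
  out <- switch(tf,
    hflip = ch[rev(seq_len(dim(ch)[1])), , , , drop = FALSE],
    vflip = ch[, rev(seq_len(dim(ch)[2])), , , drop = FALSE],
    rotation = {
      theta <- stats::runif(1, -params$rotation_degrees,
                            params$rotation_degrees) * pi / 180
      warp_axial(ch, rotation_field(dim(ch)[1:2], theta), nearest = nn)
    },
    elastic = {
      fld <- elastic_field(dim(ch)[1:2], params$elastic_grid,
                           params$elastic_sd)
      warp_axial(ch, fld, nearest = nn)
    },
    spike = {
      rng <- diff(range(ch))
      amp <- params$spike_relative_amplitude * max(rng, 1e-8)
      add_spike(ch, amp)
    },
    bias_field = multiply_bias(ch, params$bias_artifact_amplitude),
    noise = {
      sigma <- stats::runif(1, 0, params$noise_sigma_max)
      ch + array(stats::rnorm(length(ch), 0, sigma), dim = dim(ch))
    },
    gamma = {
      g <- exp(stats::runif(1, params$gamma_log_range[1],
                            params$gamma_log_range[2]))
      lo <- min(ch); hi <- max(ch)
      if (hi - lo < 1e-12) ch else
        ((ch - lo) / (hi - lo))^g * (hi - lo) + lo
    },
    stop(sprintf("unknown transform '%s'", tf)))
  dim(out) <- dim(ch)
  sample$channels <- out
  sample
}

# In-plane coordinate field for a rotation about the slice center.
rotation_field <- function(dims2, theta) {
  cx <- (dims2[1] + 1) / 2; cy <- (dims2[2] + 1) / 2
  gx <- matrix(seq_len(dims2[1]) - cx, dims2[1], dims2[2])
  gy <- matrix(seq_len(dims2[2]) - cy, dims2[1], dims2[2], byrow = TRUE)
  list(x = cos(theta) * gx - sin(theta) * gy + cx,
       y = sin(theta) * gx + cos(theta) * gy + cy)
}

# Smooth random in-plane displacement field from a coarse control grid,
# bilinearly upsampled to the slice resolution.
elastic_field <- function(dims2, grid_n, sd) {
  upsample <- function(coarse) {
    cx <- seq(1, dims2[1], length.out = nrow(coarse))
    cy <- seq(1, dims2[2], length.out = ncol(coarse))
    rows <- apply(coarse, 2, function(col)
      stats::approx(cx, col, xout = seq_len(dims2[1]), rule = 2)$y)
    t(apply(rows, 1, function(row)
      stats::approx(cy, row, xout = seq_len(dims2[2]), rule = 2)$y))
  }
  dx <- upsample(matrix(stats::rnorm(grid_n^2, 0, sd), grid_n, grid_n))
  dy <- upsample(matrix(stats::rnorm(grid_n^2, 0, sd), grid_n, grid_n))
  gx <- matrix(seq_len(dims2[1]), dims2[1], dims2[2])
  gy <- matrix(seq_len(dims2[2]), dims2[1], dims2[2], byrow = TRUE)
  list(x = gx + dx, y = gy + dy)
}

# Apply an in-plane coordinate field to every slice and channel.
warp_axial <- function(ch, field, nearest = FALSE) {
  d <- dim(ch)
  out <- array(0, dim = d)
  nx <- d[1]; ny <- d[2]
  if (nearest) {
    ix <- pmin(pmax(round(field$x), 1), nx)
    iy <- pmin(pmax(round(field$y), 1), ny)
    idx <- cbind(as.vector(ix), as.vector(iy))
    for (k in seq_len(d[3])) for (c in seq_len(d[4]))
      out[, , k, c] <- matrix(ch[, , k, c][idx], nx, ny)
  } else {
    x0 <- floor(field$x); y0 <- floor(field$y)
    fx <- field$x - x0; fy <- field$y - y0
    inb <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
    cl <- function(v, n) pmin(pmax(v, 1), n)
    x0c <- cl(x0, nx); x1c <- cl(x0 + 1, nx)
    y0c <- cl(y0, ny); y1c <- cl(y0 + 1, ny)
    i00 <- cbind(as.vector(x0c), as.vector(y0c))
    i10 <- cbind(as.vector(x1c), as.vector(y0c))
    i01 <- cbind(as.vector(x0c), as.vector(y1c))
    i11 <- cbind(as.vector(x1c), as.vector(y1c))
    w00 <- as.vector((1 - fx) * (1 - fy)); w10 <- as.vector(fx * (1 - fy))
    w01 <- as.vector((1 - fx) * fy); w11 <- as.vector(fx * fy)
    keep <- as.vector(inb)
    for (k in seq_len(d[3])) for (c in seq_len(d[4])) {
      sl <- ch[, , k, c]
      v <- w00 * sl[i00] + w10 * sl[i10] + w01 * sl[i01] + w11 * sl[i11]
      v[!keep] <- 0  # out-of-grid source voxels are padded with zero
      out[, , k, c] <- matrix(v, nx, ny)
    }
  }
  out
}

# k-space spike analogue: an additive in-plane sinusoidal stripe pattern
# with random frequency and phase, shared by all slices and channels.
add_spike <- function(ch, amplitude) {
  d <- dim(ch)
  kx <- stats::runif(1, 0.05, 0.3); ky <- stats::runif(1, 0.05, 0.3)
  phase <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(seq_len(d[1]), d[1], d[2])
  gy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  stripe <- amplitude * cos(2 * pi * (kx * gx + ky * gy) + phase)
  for (k in seq_len(d[3])) for (c in seq_len(d[4]))
    ch[, , k, c] <- ch[, , k, c] + stripe
  ch
}

# Random smooth multiplicative field (single low-frequency cosine bump).
multiply_bias <- function(ch, amplitude) {
  d <- dim(ch)
  a <- stats::runif(1, 0, amplitude)
  px <- stats::runif(1, -0.25, 0.25); py <- stats::runif(1, -0.25, 0.25)
  gx <- matrix(seq_len(d[1]) / d[1] - 0.5, d[1], d[2])
  gy <- matrix(seq_len(d[2]) / d[2] - 0.5, d[1], d[2], byrow = TRUE)
  field <- 1 + a * cos(pi * (gx - px)) * cos(pi * (gy - py))
  for (k in seq_len(d[3])) for (c in seq_len(d[4]))
    ch[, , k, c] <- ch[, , k, c] * field
  ch
}
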