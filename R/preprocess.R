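# Preprocessing: bias correction, isotropic resampling, mask-centered
# cropping, shape-prior curation, ED/ES sample extraction -------------------

#' Correct smooth multiplicative intensity inhomogeneity
#'
#' Targets the artifact N4 addresses: smooth multiplicative non-uniformity
#' of low spatial frequencies. Log intensities of the segmented voxels are
#' modeled as a structure-specific mean plus a low-order polynomial in the
#' voxel coordinates (the segmentation plays the role of N4's mask and tissue
#' model, absorbing anatomical contrast so the polynomial captures only the
#' smooth field); the exponentiated polynomial, normalized to unit mean, is
#' divided out of the whole image. The mask is left untouched.
#'
#' @param volume a `volume_sample`.
#' @param degree polynomial degree of the fitted field (default 2).
#' @param n_fit maximum number of voxels sampled for the fit.
#' @return the corrected `volume_sample`.
#' @export
bias_field_correct <- function(volume, degree = 2L, n_fit = 20000L) {
  stopifnot(inherits(volume, "volume_sample"))
  img <- volume$image
  if (any(!is.finite(img))) stop("image contains non-finite voxels")
  shift <- 0
  mn <- min(img)
  if (mn <= 0) shift <- -mn + 1e-3 * max(abs(img), 1)
  work <- img + shift
  dims <- dim(work)
  fg <- which(volume$mask > 0L)
  if (length(fg) < 50L) fg <- seq_along(work)
  idx <- if (length(fg) > n_fit)
    fg[round(seq(1, length(fg), length.out = n_fit))] else fg
  poly_basis <- function(linear_idx) {
    co <- arrayInd(linear_idx, dims)
    x <- (co[, 1] - (dims[1] + 1) / 2) / dims[1]
    y <- (co[, 2] - (dims[2] + 1) / 2) / dims[2]
    z <- (co[, 3] - (dims[3] + 1) / 2) / dims[3]
    cols <- list()
    for (d in seq_len(degree)) {
      cols[[length(cols) + 1L]] <- x^d
      cols[[length(cols) + 1L]] <- y^d
      if (dims[3] > 2L) cols[[length(cols) + 1L]] <- z^d
    }
    cols[[length(cols) + 1L]] <- x * y
    do.call(cbind, cols)
  }
  P <- poly_basis(idx)
  labs <- volume$mask[idx]
  lev <- sort(unique(labs))
  # per-structure log-mean dummies (built directly: lev may be a single
  # label, which model.matrix on a factor would reject)
  D <- vapply(lev, function(l) as.numeric(labs == l), numeric(length(labs)))
  fit <- stats::lm.fit(cbind(D, P), log(work[idx]))
  beta_poly <- fit$coefficients[(ncol(D) + 1L):(ncol(D) + ncol(P))]
  beta_poly[is.na(beta_poly)] <- 0
  field <- exp(as.vector(poly_basis(seq_along(work)) %*% beta_poly))
  field <- array(field / mean(field), dim = dims)
  out <- volume
  out$image <- work / field - shift
  out
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation for the image, nearest-neighbor for the mask
#' (preserving the label set exactly). The physical extent is preserved to
#' within one voxel; output dimensions are `round(dim * spacing / target)`.
#'
#' @param volume a `volume_sample`.
#' @param target_spacing length-3 target spacing in mm (default 1x1x1).
#' @return the resampled `volume_sample` with `spacing = target_spacing`.
#' @export
resample_isotropic <- function(volume, target_spacing = c(1, 1, 1)) {
  stopifnot(inherits(volume, "volume_sample"))
  sp <- volume$spacing
  if (any(sp <= 0)) stop("input spacing must be positive")
  dims <- dim(volume$image)
  if (any(dims < 1L) || length(volume$image) == 0L)
    stop("degenerate zero-extent volume")
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3L)
  out_dims <- pmax(1L, as.integer(round(dims * sp / target_spacing)))
  if (identical(out_dims, dims) && all(abs(sp - target_spacing) < 1e-12))
    return(volume)
  # output voxel centers expressed in input voxel (1-based) coordinates,
  # aligning the physical centers of the two grids
  coord <- function(ax) {
    out_mm <- (seq_len(out_dims[ax]) - (out_dims[ax] + 1) / 2) * target_spacing[ax]
    out_mm / sp[ax] + (dims[ax] + 1) / 2
  }
  cx <- coord(1); cy <- coord(2); cz <- coord(3)
  img <- trilinear_sample(volume$image, cx, cy, cz)
  msk <- nearest_sample(volume$mask, cx, cy, cz)
  out <- volume
  out$image <- img
  out$mask <- msk
  out$spacing <- target_spacing
  out
}

# Separable grid sampling: coordinates given per-axis (1-based, fractional).
# Linear indexing keeps the gathers fast on large grids.
trilinear_sample <- function(a, cx, cy, cz) {
  dims <- dim(a)
  prep <- function(co, n) {
    co <- pmin(pmax(co, 1), n)
    if (n == 1L) return(list(i0 = rep(1, length(co)),
                             f = rep(0, length(co)), step = 0))
    i0 <- pmin(floor(co), n - 1)
    list(i0 = i0, f = co - i0, step = 1)
  }
  px <- prep(cx, dims[1]); py <- prep(cy, dims[2]); pz <- prep(cz, dims[3])
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  fx <- rep(px$f, times = ny * nz)
  fy <- rep(rep(py$f, each = nx), times = nz)
  fz <- rep(pz$f, each = nx * ny)
  sy <- dims[1]; sz <- dims[1] * dims[2]
  base <- rep(px$i0, times = ny * nz) +
    (rep(rep(py$i0, each = nx), times = nz) - 1) * sy +
    (rep(pz$i0, each = nx * ny) - 1) * sz
  ox <- px$step; oy <- py$step * sy; oz <- pz$step * sz
  out <- (1 - fz) * ((1 - fy) * ((1 - fx) * a[base] + fx * a[base + ox]) +
                     fy * ((1 - fx) * a[base + oy] + fx * a[base + ox + oy])) +
    fz * ((1 - fy) * ((1 - fx) * a[base + oz] + fx * a[base + ox + oz]) +
          fy * ((1 - fx) * a[base + oy + oz] + fx * a[base + ox + oy + oz]))
  array(out, dim = c(nx, ny, nz))
}

nearest_sample <- function(a, cx, cy, cz) {
  dims <- dim(a)
  ix <- pmin(pmax(round(cx), 1), dims[1])
  iy <- pmin(pmax(round(cy), 1), dims[2])
  iz <- pmin(pmax(round(cz), 1), dims[3])
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  lin <- rep(ix, times = ny * nz) +
    (rep(rep(iy, each = nx), times = nz) - 1) * dims[1] +
    (rep(iz, each = nx * ny) - 1) * dims[1] * dims[2]
  array(a[lin], dim = c(nx, ny, nz))
}

#' Crop a volume to a fixed voxel window centered on the mask
#'
#' The window is centered on the center of the bounding box of the mask's
#' non-zero voxels (floor of the midpoint for even extents, 0-based
#' convention); regions falling outside the input grid are zero-padded so
#' the output shape is always exactly `window`.
#'
#' @param volume a `volume_sample` whose mask has non-zero voxels.
#' @param window length-3 output size in voxels (default 150x150x10).
#' @return the cropped `volume_sample`.
#' @export
crop_to_window <- function(volume, window = c(150L, 150L, 10L)) {
  stopifnot(inherits(volume, "volume_sample"))
  window <- as.integer(window)
  nz <- which(volume$mask != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L)
    stop(sprintf("empty mask for subject %s", volume$subject_id))
  lo <- apply(nz, 2, min) - 1L  # 0-based bounding box
  hi <- apply(nz, 2, max) - 1L
  center <- as.integer(floor((lo + hi) / 2))
  # 0-based window start; the floor-midpoint convention makes a crop of an
  # exactly window-sized mask the identity
  start <- center - (window - 1L) %/% 2L
  dims <- dim(volume$image)
  img <- array(0, dim = window)
  msk <- array(0L, dim = window)
  src_lo <- pmax(start, 0L); src_hi <- pmin(start + window - 1L, dims - 1L)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start; dst_hi <- src_hi - start
    img[(dst_lo[1]:dst_hi[1]) + 1, (dst_lo[2]:dst_hi[2]) + 1,
        (dst_lo[3]:dst_hi[3]) + 1] <-
      volume$image[(src_lo[1]:src_hi[1]) + 1, (src_lo[2]:src_hi[2]) + 1,
                   (src_lo[3]:src_hi[3]) + 1]
    msk[(dst_lo[1]:dst_hi[1]) + 1, (dst_lo[2]:dst_hi[2]) + 1,
        (dst_lo[3]:dst_hi[3]) + 1] <-
      volume$mask[(src_lo[1]:src_hi[1]) + 1, (src_lo[2]:src_hi[2]) + 1,
                  (src_lo[3]:src_hi[3]) + 1]
  }
  out <- volume
  out$image <- img
  out$mask <- msk
  out
}

#' Curate a cropped volume into a fixed 3-channel training input
#'
#' Three shape-prior set-ups: `baseline` replicates the image to three
#' identical channels; `masked` multiplies the image by the binary mask
#' before replication; `per_structure` assigns one structure per channel in
#' the order (LV blood pool, RV blood pool, myocardium), giving channels
#' with pairwise disjoint support.
#'
#' @param volume a cropped `volume_sample`.
#' @param curation_type one of `"baseline"`, `"masked"`, `"per_structure"`.
#' @param channel_structures per-structure channel order as mask labels;
#'   default `c(1, 3, 2)` = (LV blood pool, RV blood pool, myocardium).
#' @return a `curated_sample`: list with `channels` (4D array, spatial dims
#'   x 3 channels), `label`, `center`, `subject_id`, `timepoint`,
#'   `curation_type`.
#' @export
curate <- function(volume, curation_type = c("baseline", "masked",
                                             "per_structure"),
                   channel_structures = c(1L, 3L, 2L)) {
  stopifnot(inherits(volume, "volume_sample"))
  curation_type <- match.arg(curation_type)
  dims <- dim(volume$image)
  ch <- array(0, dim = c(dims, 3L))
  if (curation_type == "baseline") {
    for (i in 1:3) ch[, , , i] <- volume$image
  } else if (curation_type == "masked") {
    m <- volume$image * (volume$mask > 0L)
    for (i in 1:3) ch[, , , i] <- m
  } else {
    for (i in 1:3) ch[, , , i] <- volume$image * (volume$mask == channel_structures[i])
  }
  structure(list(channels = ch, label = volume$label, center = volume$center,
                 subject_id = volume$subject_id, timepoint = volume$timepoint,
                 curation_type = curation_type),
            class = "curated_sample")
}

#' @export
print.curated_sample <- function(x, ...) {
  cat(sprintf("<curated_sample> %s %s (%s, %s) curation=%s dims=%s\n",
              x$subject_id, x$timepoint, x$label, x$center, x$curation_type,
              paste(dim(x$channels), collapse = "x")))
  invisible(x)
}

#' Run the full preprocessing chain on one volume
#'
#' Bias correction, isotropic resampling, mask-centered cropping, then
#' curation. Metadata (label, center, subject, timepoint) flows through
#' unchanged.
#'
#' @param volume a raw `volume_sample`.
#' @param curation_type passed to [curate].
#' @param target_spacing passed to [resample_isotropic].
#' @param window passed to [crop_to_window].
#' @param bias_correct logical; skip to save time when the generator adds no
#'   bias field.
#' @return a `curated_sample`.
#' @export
preprocess_volume <- function(volume, curation_type = "masked",
                              target_spacing = c(1, 1, 1),
                              window = c(150L, 150L, 10L),
                              bias_correct = TRUE) {
  v <- volume
  if (bias_correct) v <- bias_field_correct(v)
  v <- resample_isotropic(v, target_spacing)
  v <- crop_to_window(v, window)
  curate(v, curation_type)
}

#' Extract the two timepoint samples of one subject
#'
#' ED and ES are separate training samples that share the subject identity;
#' split plans must keep them in the same partition.
#'
#' @param volumes named list with `volume_sample`s `ED` and `ES` (e.g. from
#'   [render_subject]), already preprocessed or raw.
#' @param curation_type passed to [curate] via [preprocess_volume].
#' @param ... further arguments to [preprocess_volume].
#' @return list of two `curated_sample`s tagged ED and ES.
#' @export
extract_timepoint_samples <- function(volumes, curation_type = "masked", ...) {
  if (is.null(volumes$ED) || is.null(volumes$ES))
    stop("both ED and ES volumes are required")
  out <- list(ED = preprocess_volume(volumes$ED, curation_type, ...),
              ES = preprocess_volume(volumes$ES, curation_type, ...))
  if (out$ED$subject_id != out$ES$subject_id)
    stop("ED and ES volumes belong to different subjects")
  out
}
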