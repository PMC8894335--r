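# Synthetic multi-center cardiac phantom cohort -------------------------------
#
# Four simulated acquisition sites, each with its own class balance, native
# voxel spacing and intensity characteristics (offset, gain, noise, smooth
# multiplicative bias). Subjects carry a sampled cardiac geometry from which
# short-axis-like volumes at end-diastole (ED) and end-systole (ES) are
# rendered together with a three-structure segmentation mask.

#' Describe one simulated acquisition center
#'
#' A center profile bundles the class counts and the acquisition effects that
#' make the center's images look different from other centers: native voxel
#' spacing, an additive intensity offset, a multiplicative gain, Gaussian
#' noise, and the peak amplitude of a smooth multiplicative bias field.
#'
#' @param name center name (unique within a cohort).
#' @param n_nor number of normal (NOR) subjects.
#' @param n_hcm number of hypertrophic-cardiomyopathy (HCM) subjects.
#' @param native_spacing length-3 numeric, voxel spacing in mm
#'   (in-plane x, in-plane y, slice thickness).
#' @param intensity_offset additive intensity offset (arbitrary units).
#' @param intensity_scale multiplicative gain, must be positive.
#' @param noise_sigma standard deviation of additive Gaussian noise (>= 0).
#' @param bias_amplitude peak relative deviation of the multiplicative
#'   low-frequency bias field (>= 0; 0.2 means +/-20 percent).
#' @return an object of class `center_profile`.
#' @export
#' @examples
#' center_profile("siteA", n_nor = 5, n_hcm = 5)
center_profile <- function(name, n_nor, n_hcm,
                           native_spacing = c(1.25, 1.25, 10),
                           intensity_offset = 0,
                           intensity_scale = 1,
                           noise_sigma = 0,
                           bias_amplitude = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (n_nor < 0 || n_hcm < 0) stop("class counts must be >= 0")
  if (length(native_spacing) != 3L || any(native_spacing <= 0))
    stop("native_spacing must be three positive values (mm)")
  if (intensity_scale <= 0) stop("intensity_scale must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (bias_amplitude < 0) stop("bias_amplitude must be >= 0")
  structure(list(
    name = name, n_nor = as.integer(n_nor), n_hcm = as.integer(n_hcm),
    native_spacing = as.numeric(native_spacing),
    intensity_offset = intensity_offset,
    intensity_scale = intensity_scale,
    noise_sigma = noise_sigma,
    bias_amplitude = bias_amplitude
  ), class = "center_profile")
}

#' @export
print.center_profile <- function(x, ...) {
  cat(sprintf("<center_profile> %s: %d NOR / %d HCM, spacing %s mm\n",
              x$name, x$n_nor, x$n_hcm,
              paste(signif(x$native_spacing, 4), collapse = "x")))
  invisible(x)
}

#' Default four-center study configuration
#'
#' The class counts mirror the HCM/NOR subsets of the M&M centers
#' (Vall d'Hebron, Sagrada Familia, SantPau) plus an ACDC-derived fourth
#' center: 21/25, 33/37, 14/10 and 20/20 NOR/HCM subjects, 180 in total.
#' Native spacings sit inside each center's published in-plane resolution and
#' slice-thickness ranges. The intensity parameters are free simulation
#' choices producing a visible inter-site histogram shift.
#'
#' @return a named list of four [center_profile] objects.
#' @export
study_center_profiles <- function() {
  profiles <- list(
    center_profile("VallHebron", 21, 25, native_spacing = c(1.20, 1.20, 10.0),
                   intensity_offset = 0, intensity_scale = 1.00,
                   noise_sigma = 4, bias_amplitude = 0.20),
    center_profile("SagradaFamilia", 33, 37, native_spacing = c(1.30, 1.30, 8.0),
                   intensity_offset = 35, intensity_scale = 1.15,
                   noise_sigma = 5, bias_amplitude = 0.15),
    center_profile("SantPau", 14, 10, native_spacing = c(1.00, 1.00, 10.0),
                   intensity_offset = -20, intensity_scale = 0.85,
                   noise_sigma = 3, bias_amplitude = 0.25),
    center_profile("ACDC", 20, 20, native_spacing = c(1.50, 1.50, 5.0),
                   intensity_offset = 60, intensity_scale = 1.30,
                   noise_sigma = 6, bias_amplitude = 0.10)
  )
  stats::setNames(profiles, vapply(profiles, `[[`, "", "name"))
}

#' Cardiac geometry sampling configuration
#'
#' Per-label distributions of the phantom geometry, in mm. HCM is encoded as
#' end-diastolic myocardial wall thickness above a clinically motivated 15 mm
#' analogue threshold, NOR as normal thickness; the hard truncation bounds
#' keep the two label distributions disjoint by `hcm_wall_range[1] -
#' nor_wall_range[2]` mm. End-systole contracts the blood pools and thickens
#' the wall.
#'
#' @param nor_wall_mean,nor_wall_sd,nor_wall_range NOR end-diastolic wall
#'   thickness distribution (truncated normal), mm.
#' @param hcm_wall_mean,hcm_wall_sd,hcm_wall_range HCM end-diastolic wall
#'   thickness distribution (truncated normal), mm.
#' @param min_separation minimum demanded gap between the NOR upper bound and
#'   HCM lower bound, mm. Set to 0 to allow overlapping regimes.
#' @param nor_endo_mean,hcm_endo_mean mean end-diastolic LV endocardial
#'   (blood-pool) radius per label, mm.
#' @param endo_sd,endo_halfwidth spread and truncation half-width of the
#'   endocardial radius, mm.
#' @param contraction_range uniform range of the ES/ED cavity radius ratio
#'   (< 1: systolic contraction).
#' @param thickening_range uniform range of the ES/ED wall thickness ratio
#'   (> 1: systolic thickening).
#' @param rv_extent_range uniform range of the RV crescent radius, mm.
#' @param z_semi LV long-axis semi-extent, mm.
#' @return an object of class `geometry_config`.
#' @export
geometry_config <- function(nor_wall_mean = 8, nor_wall_sd = 1,
                            nor_wall_range = c(6, 11),
                            hcm_wall_mean = 21, hcm_wall_sd = 2,
                            hcm_wall_range = c(17, 26),
                            min_separation = 2,
                            nor_endo_mean = 24, hcm_endo_mean = 19,
                            endo_sd = 1.5, endo_halfwidth = 4,
                            contraction_range = c(0.60, 0.75),
                            thickening_range = c(1.25, 1.40),
                            rv_extent_range = c(14, 20),
                            z_semi = 60) {
  cfg <- list(
    nor_wall_mean = nor_wall_mean, nor_wall_sd = nor_wall_sd,
    nor_wall_range = nor_wall_range,
    hcm_wall_mean = hcm_wall_mean, hcm_wall_sd = hcm_wall_sd,
    hcm_wall_range = hcm_wall_range,
    min_separation = min_separation,
    nor_endo_mean = nor_endo_mean, hcm_endo_mean = hcm_endo_mean,
    endo_sd = endo_sd, endo_halfwidth = endo_halfwidth,
    contraction_range = contraction_range,
    thickening_range = thickening_range,
    rv_extent_range = rv_extent_range,
    z_semi = z_semi
  )
  gap <- hcm_wall_range[1] - nor_wall_range[2]
  if (min_separation > 0 && gap < min_separation)
    stop(sprintf(paste0("thickness distributions overlap: HCM lower bound %.1f",
                        " minus NOR upper bound %.1f is below the demanded",
                        " separation %.1f mm"),
                 hcm_wall_range[1], nor_wall_range[2], min_separation))
  if (contraction_range[1] <= 0 || contraction_range[2] >= 1)
    stop("contraction_range must lie inside (0, 1)")
  structure(cfg, class = "geometry_config")
}

#' Rendering grid configuration
#'
#' Physical field of view of the native acquisition grid; voxel counts per
#' center follow from the center's native spacing.
#'
#' @param fov length-3 physical extent in mm (x, y, z).
#' @param base_intensity named intensities of background, LV blood pool,
#'   myocardium and RV blood pool before center effects are applied. Blood
#'   pools are brighter than myocardium, which is brighter than background,
#'   mimicking cine contrast.
#' @return an object of class `grid_config`.
#' @export
grid_config <- function(fov = c(160, 160, 40),
                        base_intensity = c(background = 20, lv = 200,
                                           myo = 100, rv = 190)) {
  stopifnot(length(fov) == 3L, all(fov > 0))
  stopifnot(all(c("background", "lv", "myo", "rv") %in% names(base_intensity)))
  structure(list(fov = as.numeric(fov), base_intensity = base_intensity),
            class = "grid_config")
}

#' Generate a synthetic multi-center cohort manifest
#'
#' Samples one geometry per subject under the configured per-label
#' distributions. RNG streams are derived per center and per subject from the
#' master seed, so the manifest (and any volume later rendered from it) is
#' reproducible independently of generation order.
#'
#' @param profiles list of [center_profile] objects.
#' @param geometry a [geometry_config].
#' @param master_seed integer master seed.
#' @return a data.frame of class `fedcmr_cohort` with one row per subject:
#'   `subject_id`, `center`, `label` ("NOR"/"HCM"), per-subject `seed`, and
#'   geometry columns `r_endo_ed`, `wall_ed`, `r_endo_es`, `wall_es`,
#'   `rv_extent`, `z_semi` (mm). The profiles are attached as attribute
#'   `"profiles"`.
#' @export
#' @examples
#' cohort <- generate_cohort(study_center_profiles(), master_seed = 1)
#' table(cohort$center, cohort$label)
generate_cohort <- function(profiles, geometry = geometry_config(),
                            master_seed = 1L) {
  if (length(profiles) == 0) stop("profiles must be non-empty")
  if (inherits(profiles, "center_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "center_profile")))
  stopifnot(inherits(geometry, "geometry_config"))
  rows <- list()
  for (ci in seq_along(profiles)) {
    prof <- profiles[[ci]]
    center_seed <- derive_seed(master_seed, ci)
    labels <- c(rep("NOR", prof$n_nor), rep("HCM", prof$n_hcm))
    for (si in seq_along(labels)) {
      subject_seed <- derive_seed(center_seed, si)
      geo <- with_seed(subject_seed, sample_geometry(labels[si], geometry))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%03d", prof$name, si),
        center = prof$name, label = labels[si], seed = subject_seed,
        r_endo_ed = geo$r_endo_ed, wall_ed = geo$wall_ed,
        r_endo_es = geo$r_endo_es, wall_es = geo$wall_es,
        rv_extent = geo$rv_extent, z_semi = geo$z_semi,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), center = character(),
               label = character(), seed = integer(),
               r_endo_ed = numeric(), wall_ed = numeric(),
               r_endo_es = numeric(), wall_es = numeric(),
               rv_extent = numeric(), z_semi = numeric())
  rownames(manifest) <- NULL
  attr(manifest, "profiles") <- stats::setNames(
    profiles, vapply(profiles, `[[`, "", "name"))
  attr(manifest, "master_seed") <- master_seed
  class(manifest) <- c("fedcmr_cohort", "data.frame")
  manifest
}

# One subject's geometry draw; assumes the RNG is already seeded.
sample_geometry <- function(label, g) {
  if (label == "HCM") {
    wall <- rtruncnorm1(1, g$hcm_wall_mean, g$hcm_wall_sd,
                        g$hcm_wall_range[1], g$hcm_wall_range[2])
    endo_mean <- g$hcm_endo_mean
  } else {
    wall <- rtruncnorm1(1, g$nor_wall_mean, g$nor_wall_sd,
                        g$nor_wall_range[1], g$nor_wall_range[2])
    endo_mean <- g$nor_endo_mean
  }
  r_endo <- rtruncnorm1(1, endo_mean, g$endo_sd,
                        endo_mean - g$endo_halfwidth,
                        endo_mean + g$endo_halfwidth)
  contraction <- stats::runif(1, g$contraction_range[1], g$contraction_range[2])
  thickening <- stats::runif(1, g$thickening_range[1], g$thickening_range[2])
  list(
    r_endo_ed = r_endo, wall_ed = wall,
    r_endo_es = r_endo * contraction, wall_es = wall * thickening,
    rv_extent = stats::runif(1, g$rv_extent_range[1], g$rv_extent_range[2]),
    z_semi = g$z_semi
  )
}

#' Render one phantom volume at a center's native grid
#'
#' Builds the image/mask pair for one subject and timepoint: an axis-aligned
#' concentric-ellipsoid LV blood pool and myocardial shell plus a crescent RV
#' blood pool, voxelized at the center's native spacing. The image is
#' `base_intensity[structure] * (1 + bias field) * intensity_scale +
#' intensity_offset + N(0, noise_sigma)`; the mask is noise-free with labels
#' 0 background, 1 LV blood pool, 2 myocardium, 3 RV blood pool.
#'
#' @param subject one row of a [generate_cohort] manifest (data.frame row).
#' @param timepoint `"ED"` or `"ES"`.
#' @param profile the subject's [center_profile].
#' @param grid a [grid_config].
#' @return a `volume_sample`: list with `image` and `mask` (3D arrays of
#'   identical dimensions), `spacing` (mm), `timepoint`, `subject_id`,
#'   `center`, `label`.
#' @export
render_phantom <- function(subject, timepoint = c("ED", "ES"), profile,
                           grid = grid_config()) {
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(profile, "center_profile"), inherits(grid, "grid_config"))
  if (nrow(as.data.frame(subject)) != 1L)
    stop("subject must be a single manifest row")
  sp <- profile$native_spacing
  dims <- pmax(1L, as.integer(round(grid$fov / sp)))
  if (timepoint == "ED") {
    r_endo <- subject$r_endo_ed; wall <- subject$wall_ed
  } else {
    r_endo <- subject$r_endo_es; wall <- subject$wall_es
  }
  r_epi <- r_endo + wall
  rv_extent <- if (timepoint == "ED") subject$rv_extent else
    subject$rv_extent * (subject$r_endo_es / subject$r_endo_ed)
  if (2 * (r_epi + 1.6 * rv_extent) > max(grid$fov[1:2]) ||
      2 * r_epi > min(grid$fov[1:2]))
    stop(sprintf("geometry of subject %s exceeds the rendering grid",
                 subject$subject_id))

  # voxel-center coordinates in mm, origin at the grid center
  x <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp[1]
  y <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp[2]
  z <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * sp[3]
  X <- array(rep(x, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(y, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dim = dims)

  zs <- subject$z_semi
  lv_in <- (X / r_endo)^2 + (Y / r_endo)^2 + (Z / zs)^2 <= 1
  epi <- (X / r_epi)^2 + (Y / r_epi)^2 + (Z / (zs + wall))^2 <= 1
  rv_cx <- -(r_epi + 0.35 * rv_extent)
  rv <- ((X - rv_cx) / rv_extent)^2 + (Y / (1.5 * rv_extent))^2 +
    (Z / zs)^2 <= 1
  mask <- array(0L, dim = dims)
  mask[rv & !epi] <- 3L
  mask[epi] <- 2L
  mask[lv_in] <- 1L

  base <- grid$base_intensity
  image <- array(base[["background"]], dim = dims)
  image[mask == 1L] <- base[["lv"]]
  image[mask == 2L] <- base[["myo"]]
  image[mask == 3L] <- base[["rv"]]

  noise_seed <- derive_seed(subject$seed, if (timepoint == "ED") 1L else 2L)
  image <- with_seed(noise_seed, {
    if (profile$bias_amplitude > 0) {
      px <- stats::runif(1, -0.25, 0.25) * grid$fov[1]
      py <- stats::runif(1, -0.25, 0.25) * grid$fov[2]
      bias <- profile$bias_amplitude *
        cos(pi * (X - px) / grid$fov[1]) * cos(pi * (Y - py) / grid$fov[2])
      image <- image * (1 + bias)
    }
    image <- image * profile$intensity_scale + profile$intensity_offset
    if (profile$noise_sigma > 0)
      image <- image + stats::rnorm(length(image), 0, profile$noise_sigma)
    image
  })

  for (lab in 1:3) if (!any(mask == lab))
    stop(sprintf("structure label %d empty for subject %s", lab,
                 subject$subject_id))
  volume_sample(image, mask, sp, timepoint,
                subject_id = subject$subject_id,
                center = subject$center, label = subject$label)
}

#' Construct a volume sample
#'
#' @param image 3D numeric array.
#' @param mask 3D integer array over labels 0 (background), 1 (LV blood
#'   pool), 2 (myocardium), 3 (RV blood pool); same dimensions as `image`.
#' @param spacing voxel spacing in mm.
#' @param timepoint `"ED"` or `"ES"`.
#' @param subject_id,center,label subject metadata carried through the
#'   pipeline.
#' @return an object of class `volume_sample`.
#' @export
volume_sample <- function(image, mask, spacing, timepoint = "ED",
                          subject_id = "", center = "", label = "") {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  if (length(dim(image)) != 3L) stop("image must be a 3D array")
  bad <- setdiff(unique(as.integer(mask)), 0:3)
  if (length(bad)) stop("mask labels must be within {0,1,2,3}")
  structure(list(image = image, mask = mask, spacing = as.numeric(spacing),
                 timepoint = timepoint, subject_id = subject_id,
                 center = center, label = label),
            class = "volume_sample")
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf("<volume_sample> %s %s (%s, %s): %s voxels @ %s mm\n",
              x$subject_id, x$timepoint, x$label, x$center,
              paste(dim(x$image), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Measure myocardial wall thickness from a segmentation mask
#'
#' Estimates the median shell thickness of the myocardium (label 2) from a
#' per-slice exact Euclidean distance transform: for each myocardial voxel
#' the in-plane distance to the nearest non-myocardial voxel is computed; for
#' a uniform shell these distances are uniform on (0, thickness/2), so the
#' thickness is recovered as four times their median after a half-voxel
#' boundary correction.
#'
#' @param mask 3D integer mask containing myocardium label 2.
#' @param spacing voxel spacing in mm (in-plane spacing is used).
#' @return estimated median wall thickness in mm.
#' @export
measure_wall_thickness <- function(mask, spacing) {
  if (!any(mask == 2L)) stop("mask contains no myocardium (label 2)")
  h <- mean(spacing[1:2])
  d_all <- numeric(0)
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k] == 2L
    if (!any(sl)) next
    d_all <- c(d_all, slice_boundary_distances(sl, spacing[1], spacing[2]))
  }
  4 * (stats::median(d_all) - h / 2)
}

# In-plane distances (mm) from TRUE pixels to the nearest FALSE pixel,
# computed against the FALSE pixels 4-adjacent to the region (the nearest
# complement pixel always lies on that boundary).
slice_boundary_distances <- function(sl, sx, sy) {
  nx <- nrow(sl); ny <- ncol(sl)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- sl
  nb <- pad[1:nx, 2:(ny + 1)] | pad[3:(nx + 2), 2:(ny + 1)] |
    pad[2:(nx + 1), 1:ny] | pad[2:(nx + 1), 3:(ny + 2)]
  boundary <- nb & !sl
  idx_in <- which(sl); idx_b <- which(boundary)
  if (!length(idx_b)) return(rep(Inf, length(idx_in)))
  bx <- ((idx_b - 1) %% nx + 1) * sx
  by <- ((idx_b - 1) %/% nx + 1) * sy
  ix <- ((idx_in - 1) %% nx + 1) * sx
  iy <- ((idx_in - 1) %/% nx + 1) * sy
  # chunk to bound memory on large regions
  out <- numeric(length(idx_in))
  step <- max(1L, as.integer(2e6 / length(idx_b)))
  for (s in seq(1L, length(idx_in), by = step)) {
    e <- min(s + step - 1L, length(idx_in))
    dx <- outer(ix[s:e], bx, "-"); dy <- outer(iy[s:e], by, "-")
    out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

#' Render both timepoints of one subject
#'
#' @inheritParams render_phantom
#' @return named list with elements `ED` and `ES`, each a `volume_sample`.
#' @export
render_subject <- function(subject, profile, grid = grid_config()) {
  list(ED = render_phantom(subject, "ED", profile, grid),
       ES = render_phantom(subject, "ES", profile, grid))
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' Renders every subject at both timepoints and writes compressed NIfTI image
#' and mask files with the native spacing in the header, plus a manifest CSV
#' with columns subject_id, center, label, timepoint, image_path, mask_path.
#'
#' @param cohort a [generate_cohort] manifest.
#' @param dir output directory (created if missing).
#' @param grid a [grid_config].
#' @return invisibly, the manifest data.frame (also written to
#'   `manifest.csv`).
#' @export
write_cohort <- function(cohort, dir, grid = grid_config()) {
  profiles <- attr(cohort, "profiles")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    prof <- profiles[[subj$center]]
    for (tp in c("ED", "ES")) {
      vol <- render_phantom(subj, tp, prof, grid)
      img_path <- file.path(dir, sprintf("%s_%s_img.nii.gz", subj$subject_id, tp))
      msk_path <- file.path(dir, sprintf("%s_%s_msk.nii.gz", subj$subject_id, tp))
      hdr <- list(pixdim = c(-1, vol$spacing, 1, 1, 1, 1))
      RNifti::writeNifti(RNifti::asNifti(vol$image, reference = hdr),
                         img_path)
      RNifti::writeNifti(RNifti::asNifti(vol$mask, reference = hdr,
                                         datatype = "int16"), msk_path)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, center = subj$center,
        label = subj$label, timepoint = tp,
        image_path = img_path, mask_path = msk_path,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a NIfTI image/mask pair back into a volume sample
#'
#' @param image_path,mask_path NIfTI files written by [write_cohort].
#' @param timepoint,subject_id,center,label metadata to attach.
#' @return a `volume_sample`.
#' @export
read_volume <- function(image_path, mask_path, timepoint = "ED",
                        subject_id = "", center = "", label = "") {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  volume_sample(array(as.numeric(img), dim = dim(img)[1:3]),
                array(as.integer(msk), dim = dim(msk)[1:3]),
                spacing, timepoint, subject_id, center, label)
}
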