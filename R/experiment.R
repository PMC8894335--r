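# Experiment driver ----------------------------------------------------------
#
# Reproducible end-to-end runs: generate -> preprocess -> harmonize ->
# train/evaluate -> report. A run is fully determined by its configuration
# and seeds; every artifact can be regenerated from (config, seed) alone.

#' Build and validate a run configuration
#'
#' @param curation_type `"baseline"`, `"masked"` or `"per_structure"`.
#' @param augmentation `"none"`, `"basic"`, `"shape"` or
#'   `"shape_intensity"`.
#' @param frameworks subset of `c("CDS", "FL", "FL_EV")`.
#' @param scheme `"CCV"` or `"LCO"`.
#' @param seeds integer vector of network-initialization seeds (the study
#'   repeats each experiment five times; default `0:4`).
#' @param cohort_seed master seed of the synthetic cohort.
#' @param profiles list of [center_profile]s (default
#'   [study_center_profiles]).
#' @param geometry a [geometry_config].
#' @param grid a [grid_config].
#' @param harmonize apply federated histogram standardization (default
#'   TRUE).
#' @param bias_correct apply bias-field correction during preprocessing.
#' @param architecture classifier architecture (default `"small3d"`; the
#'   full `"resnet3d_18"` is impractical to train without accelerators).
#' @param rounds maximum communication rounds.
#' @param patience early-stopping patience in rounds.
#' @param ccv_folds CCV fold count (default 5).
#' @param window crop window in voxels.
#' @param target_spacing resampling target in mm.
#' @param output_dir optional directory for result CSVs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(curation_type = "per_structure",
                       augmentation = "none",
                       frameworks = c("CDS", "FL", "FL_EV"),
                       scheme = "CCV",
                       seeds = 0:4,
                       cohort_seed = 1L,
                       profiles = study_center_profiles(),
                       geometry = geometry_config(),
                       grid = grid_config(),
                       harmonize = TRUE,
                       bias_correct = TRUE,
                       architecture = "small3d",
                       rounds = 100L,
                       patience = 10L,
                       ccv_folds = 5L,
                       window = c(150L, 150L, 10L),
                       target_spacing = c(1, 1, 1),
                       output_dir = NULL) {
  curation_type <- match.arg(curation_type,
                             c("baseline", "masked", "per_structure"))
  augmentation <- match.arg(augmentation,
                            c("none", "basic", "shape", "shape_intensity"))
  frameworks <- match.arg(frameworks, c("CDS", "FL", "FL_EV"),
                          several.ok = TRUE)
  scheme <- match.arg(scheme, c("CCV", "LCO"))
  architecture <- match.arg(architecture, c("small3d", "resnet3d_18"))
  structure(list(curation_type = curation_type, augmentation = augmentation,
                 frameworks = frameworks, scheme = scheme,
                 seeds = as.integer(seeds),
                 cohort_seed = as.integer(cohort_seed),
                 profiles = profiles, geometry = geometry, grid = grid,
                 harmonize = harmonize, bias_correct = bias_correct,
                 architecture = architecture, rounds = as.integer(rounds),
                 patience = as.integer(patience),
                 ccv_folds = as.integer(ccv_folds),
                 window = as.integer(window),
                 target_spacing = as.numeric(target_spacing),
                 output_dir = output_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Round-trips all scalar and profile fields losslessly.
#'
#' @param config a [run_config].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  ser$profiles <- lapply(config$profiles, unclass)
  ser$geometry <- unclass(config$geometry)
  ser$grid <- unclass(config$grid)
  ser$grid$base_intensity <- as.list(ser$grid$base_intensity)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config` returns the reconstructed `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profiles <- lapply(raw$profiles, function(p)
    do.call(center_profile, p[c("name", "n_nor", "n_hcm", "native_spacing",
                                "intensity_offset", "intensity_scale",
                                "noise_sigma", "bias_amplitude")]))
  geometry <- do.call(geometry_config,
                      raw$geometry[names(raw$geometry) %in%
                                     names(formals(geometry_config))])
  grid <- grid_config(fov = unlist(raw$grid$fov),
                      base_intensity = unlist(raw$grid$base_intensity))
  run_config(curation_type = raw$curation_type,
             augmentation = raw$augmentation,
             frameworks = raw$frameworks, scheme = raw$scheme,
             seeds = raw$seeds, cohort_seed = raw$cohort_seed,
             profiles = profiles, geometry = geometry, grid = grid,
             harmonize = raw$harmonize, bias_correct = raw$bias_correct,
             architecture = raw$architecture, rounds = raw$rounds,
             patience = raw$patience, ccv_folds = raw$ccv_folds,
             window = raw$window, target_spacing = raw$target_spacing,
             output_dir = raw$output_dir)
}

# Render and preprocess every subject-timepoint up to the cropped window
# (curation happens after harmonization). Returns a list keyed
# "<subject>_<tp>" of cropped volume_samples.
prepare_volumes <- function(cohort, config) {
  profiles <- attr(cohort, "profiles")
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    prof <- profiles[[subj$center]]
    for (tp in c("ED", "ES")) {
      v <- render_phantom(subj, tp, prof, config$grid)
      if (config$bias_correct) v <- bias_field_correct(v)
      v <- resample_isotropic(v, config$target_spacing)
      v <- crop_to_window(v, config$window)
      out[[paste(subj$subject_id, tp, sep = "_")]] <- v
    }
  }
  out
}

# Standardize a set of cropped volumes against a reference built from the
# given training centers, then curate. Returns curated samples (same keys).
curate_fold_samples <- function(volumes, config, train_centers) {
  restrict <- config$curation_type != "baseline"
  if (config$harmonize) {
    edges <- default_bin_edges(volumes, restrict_to_mask = restrict)
    centers <- vapply(volumes, `[[`, "", "center")
    aggs <- lapply(intersect(unique(centers), train_centers), function(ctr)
      center_histogram_aggregate(volumes[centers == ctr], ctr, edges,
                                 restrict_to_mask = restrict))
    reference <- federated_average_histogram(aggs)
    volumes <- harmonize_samples(volumes, reference,
                                 restrict_to_mask = restrict)
  }
  lapply(volumes, curate, curation_type = config$curation_type)
}

#' Run a full experiment
#'
#' Executes the pipeline for one configuration: cohort generation,
#' preprocessing, per-fold federated harmonization (the reference excludes
#' the held-out center under LCO), training of every requested framework
#' with early stopping, and repeated-seed AUC aggregation.
#'
#' @param config a [run_config].
#' @param verbose print per-fold progress.
#' @return a list with `results` (one row per framework: per-center and
#'   Total AUC mean/sd over seeds), `predictions` (per-prediction
#'   data.frame) and `config`. When `config$output_dir` is set, both tables
#'   are also written as CSV.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$profiles, config$geometry,
                            config$cohort_seed)
  volumes <- prepare_volumes(cohort, config)
  vol_center <- vapply(volumes, `[[`, "", "center")
  vol_subject <- vapply(volumes, `[[`, "", "subject_id")
  vol_label <- vapply(volumes, `[[`, "", "label")
  vol_tp <- vapply(volumes, `[[`, "", "timepoint")

  plan <- if (config$scheme == "CCV")
    make_ccv_splits(cohort, k = config$ccv_folds, seed = config$cohort_seed)
  else make_lco_splits(cohort, seed = config$cohort_seed)
  validate_split_plan(plan, cohort)

  # curated inputs per fold context: CCV shares one all-center reference;
  # LCO rebuilds the reference without the held-out center
  fold_samples <- if (config$scheme == "CCV") {
    shared <- curate_fold_samples(volumes, config, unique(cohort$center))
    lapply(plan$folds, function(f) shared)
  } else {
    lapply(plan$folds, function(f)
      curate_fold_samples(volumes, config,
                          setdiff(unique(cohort$center), f$test_center)))
  }

  setup <- build_pool(config$augmentation)
  predictions <- list()
  for (seed in config$seeds) {
    spec <- classifier_spec(architecture = config$architecture,
                            input_shape = config$window,
                            max_epochs = config$rounds,
                            patience = config$patience)
    handle <- build_classifier(spec, seed = seed)
    feats_shared <- NULL  # CCV folds share one curated set; cache features
    for (fi in seq_along(plan$folds)) {
      f <- plan$folds[[fi]]
      samples <- fold_samples[[fi]]
      if (config$scheme == "CCV") {
        if (is.null(feats_shared)) {
          feats_shared <- compute_features(handle, samples)
          rownames(feats_shared) <- names(samples)
        }
        feats <- feats_shared
      } else {
        feats <- compute_features(handle, samples)
        rownames(feats) <- names(samples)
      }
      y <- as.integer(vol_label == "HCM")

      sel_center_data <- function(ids) {
        keys <- names(samples)[vol_subject %in% ids]
        ctrs <- vol_center[keys]
        stats::setNames(lapply(unique(ctrs), function(ctr) {
          k <- keys[ctrs == ctr]
          list(features = feats[k, , drop = FALSE],
               labels = y[match(k, names(samples))], keys = k)
        }), unique(ctrs))
      }
      train_cd <- sel_center_data(f$train)
      val_cd <- sel_center_data(f$validation)
      center_arg <- if (config$augmentation == "none") train_cd else {
        aug_seed <- derive_seed(seed, fi)
        function(r) with_seed(derive_seed(aug_seed, r), {
          lapply(train_cd, function(cd) {
            aug <- lapply(cd$keys, function(k)
              maybe_augment(samples[[k]], setup))
            list(features = compute_features(handle, aug),
                 labels = cd$labels)
          })
        })
      }
      fedcfg <- federation_config("FL", rounds = config$rounds,
                                  patience = config$patience)
      for (fw in config$frameworks) {
        fedcfg$framework <- fw
        fit <- train_federated(handle, center_arg, val_cd, fedcfg)
        h <- set_model_weights(handle, fit$weights)
        test_keys <- names(samples)[vol_subject %in% f$test]
        probs <- predict_proba(h, feats[test_keys, , drop = FALSE])
        predictions[[length(predictions) + 1L]] <- data.frame(
          framework = fw, seed = seed, fold = fi,
          center = vol_center[test_keys], subject_id = vol_subject[test_keys],
          timepoint = vol_tp[test_keys], label = vol_label[test_keys],
          prob = probs, stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf("seed %d fold %d %s: stopped at round %d (best %d)",
                          seed, fi, fw, fit$rounds_run, fit$best_round))
      }
    }
  }
  predictions <- do.call(rbind, predictions)
  rownames(predictions) <- NULL
  results <- do.call(rbind, lapply(config$frameworks, function(fw)
    aggregate_results(predictions[predictions$framework == fw, , drop = FALSE],
                      row_id = list(augmentation = config$augmentation,
                                    curation = config$curation_type,
                                    framework = fw))))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions,
                     file.path(config$output_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  list(results = results, predictions = predictions, config = config)
}
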