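# Cross-validation geometries and AUC reporting ------------------------------
#
# Two split schemes over subjects (never over subject-timepoints, so ED and
# ES of one subject always share a partition): collaborative
# cross-validation (CCV), where every center contributes a label-stratified
# 20% of its subjects to each fold's test set, and leave-center-out
# cross-validation (LCO), with one whole center held out per fold. Of the
# remaining subjects, 90% train and 10% validate, per center.

#' Build a collaborative cross-validation split plan
#'
#' Per center and label, subjects are shuffled and allocated to `k` test
#' folds with largest-remainder rounding, so each fold's test set holds
#' about 20% of every center. The non-test subjects of each fold are split
#' per center into 90% training and 10% validation.
#'
#' @param cohort a [generate_cohort] manifest (or any data.frame with
#'   `subject_id`, `center`, `label`).
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param val_fraction validation share of the non-test subjects.
#' @return a `split_plan`: list with `scheme`, `seed` and `folds`, each fold
#'   holding `train`, `validation`, `test` subject-id vectors and
#'   `test_center = NA`.
#' @export
make_ccv_splits <- function(cohort, k = 5L, seed = 0L, val_fraction = 0.1) {
  centers <- unique(cohort$center)
  for (ctr in centers)
    if (sum(cohort$center == ctr) < k)
      stop(sprintf("center %s has fewer than %d subjects", ctr, k))
  assignment <- with_seed(seed, {
    out <- stats::setNames(integer(nrow(cohort)), cohort$subject_id)
    for (ctr in centers) for (lab in unique(cohort$label)) {
      ids <- cohort$subject_id[cohort$center == ctr & cohort$label == lab]
      if (!length(ids)) next
      ids <- sample(ids)
      # largest-remainder allocation of length(ids) subjects over k folds,
      # rotated so small remainders do not always favor fold 1
      base <- length(ids) %/% k; rem <- length(ids) %% k
      sizes <- rep(base, k)
      if (rem > 0) {
        first <- sample.int(k, 1L)
        sizes[(first + seq_len(rem) - 2L) %% k + 1L] <- base + 1L
      }
      out[ids] <- rep(seq_len(k), times = sizes)
    }
    out
  })
  folds <- lapply(seq_len(k), function(f) {
    test <- names(assignment)[assignment == f]
    rest <- cohort[!(cohort$subject_id %in% test), , drop = FALSE]
    tv <- with_seed(derive_seed(seed, f), split_train_val(rest, val_fraction))
    list(train = tv$train, validation = tv$validation, test = test,
         test_center = NA_character_)
  })
  structure(list(scheme = "CCV", seed = seed, folds = folds),
            class = "split_plan")
}

#' Build a leave-center-out split plan
#'
#' One fold per center; fold k's test set is exactly all subjects of center
#' k, with train/validation drawn 90/10 per remaining center.
#'
#' @inheritParams make_ccv_splits
#' @return a `split_plan` with one fold per center; each fold records its
#'   `test_center`.
#' @export
make_lco_splits <- function(cohort, seed = 0L, val_fraction = 0.1) {
  centers <- unique(cohort$center)
  if (length(centers) < 2L) stop("LCO requires at least two centers")
  folds <- lapply(seq_along(centers), function(ci) {
    ctr <- centers[ci]
    test <- cohort$subject_id[cohort$center == ctr]
    rest <- cohort[cohort$center != ctr, , drop = FALSE]
    tv <- with_seed(derive_seed(seed, ci), split_train_val(rest, val_fraction))
    list(train = tv$train, validation = tv$validation, test = test,
         test_center = ctr)
  })
  structure(list(scheme = "LCO", seed = seed, folds = folds),
            class = "split_plan")
}

# Per-center 90/10 train/validation split of the non-test subjects; every
# center keeps at least one validation subject when it has >= 2.
split_train_val <- function(rest, val_fraction) {
  train <- character(0); validation <- character(0)
  for (ctr in unique(rest$center)) {
    ids <- sample(rest$subject_id[rest$center == ctr])
    n_val <- if (length(ids) >= 2L)
      max(1L, round(val_fraction * length(ids))) else 0L
    validation <- c(validation, ids[seq_len(n_val)])
    train <- c(train, ids[setdiff(seq_along(ids), seq_len(n_val))])
  }
  list(train = train, validation = validation)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, %d folds, seed %d\n", x$scheme,
              length(x$folds), x$seed))
  invisible(x)
}

#' Check the structural invariants of a split plan
#'
#' Verifies disjointness of train/validation/test within every fold, full
#' cohort coverage, and (for LCO) that the test center is entirely excluded
#' from training and validation.
#'
#' @param plan a `split_plan`.
#' @param cohort the manifest the plan was built from.
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_split_plan <- function(plan, cohort) {
  all_ids <- cohort$subject_id
  for (f in plan$folds) {
    sets <- list(f$train, f$validation, f$test)
    if (anyDuplicated(unlist(sets)))
      stop("train/validation/test overlap within a fold")
    if (!setequal(unlist(sets), all_ids))
      stop("fold does not cover the cohort")
    if (!is.na(f$test_center)) {
      tc_ids <- cohort$subject_id[cohort$center == f$test_center]
      if (!setequal(f$test, tc_ids))
        stop("LCO test set is not exactly the held-out center")
      if (any(c(f$train, f$validation) %in% tc_ids))
        stop("held-out center leaks into train/validation")
    }
  }
  if (plan$scheme == "CCV") {
    tests <- lapply(plan$folds, `[[`, "test")
    if (anyDuplicated(unlist(tests)))
      stop("CCV test folds overlap")
    if (!setequal(unlist(tests), all_ids))
      stop("CCV test folds do not partition the cohort")
  }
  invisible(TRUE)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks (equivalent to the
#' Mann-Whitney statistic); tied scores contribute 1/2.
#'
#' @param probabilities predicted scores.
#' @param labels 0/1 (or "NOR"/"HCM") true labels; both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(probabilities, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "HCM")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Trace the early-stopping rule over a score sequence
#'
#' Pure helper mirroring the rule used during training: keep the best score
#' seen so far, stop after `patience` consecutive non-improving rounds.
#'
#' @param scores per-round validation scores (higher is better).
#' @param patience non-improvement tolerance in rounds.
#' @return list with `best_round` and `stop_round`.
#' @export
early_stop_trace <- function(scores, patience) {
  best <- -Inf; best_round <- 0L; stale <- 0L; stop_round <- length(scores)
  for (r in seq_along(scores)) {
    if (scores[r] > best) {
      best <- scores[r]; best_round <- r; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) { stop_round <- r; break }
    }
  }
  list(best_round = best_round, stop_round = stop_round)
}

#' Aggregate fold/seed predictions into a results table
#'
#' Per seed, the total AUC is computed on the predictions pooled across all
#' folds (not by averaging per-fold AUCs), and per-center AUCs on each
#' center's pooled test predictions; cells report mean and population
#' standard deviation over the seeds.
#'
#' @param predictions data.frame with columns `seed`, `fold`, `center`,
#'   `subject_id`, `timepoint`, `label`, `prob` (one row per test
#'   prediction).
#' @param row_id optional named list of identifiers (e.g. augmentation,
#'   framework) prepended to the output row.
#' @return a one-row data.frame with `<center>_mean`/`<center>_sd` columns
#'   and `Total_mean`/`Total_sd`, plus attribute `"per_seed"` holding the
#'   seed-wise AUCs.
#' @export
aggregate_results <- function(predictions, row_id = list()) {
  needed <- c("seed", "center", "label", "prob")
  if (!all(needed %in% names(predictions)))
    stop("predictions must have columns seed, center, label, prob")
  seeds <- sort(unique(predictions$seed))
  centers <- unique(predictions$center)
  per_seed <- do.call(rbind, lapply(seeds, function(s) {
    ps <- predictions[predictions$seed == s, , drop = FALSE]
    row <- c(vapply(centers, function(ctr) {
      pc <- ps[ps$center == ctr, , drop = FALSE]
      if (length(unique(pc$label)) < 2L) NA_real_
      else compute_auc(pc$prob, pc$label)
    }, 1.0), Total = compute_auc(ps$prob, ps$label))
    row
  }))
  rownames(per_seed) <- seeds
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  }
  cells <- lapply(colnames(per_seed), function(cn) {
    v <- per_seed[, cn]
    stats::setNames(list(mean(v, na.rm = TRUE), pop_sd(v)),
                    paste0(cn, c("_mean", "_sd")))
  })
  out <- as.data.frame(c(row_id, unlist(cells, recursive = FALSE)),
                       stringsAsFactors = FALSE)
  attr(out, "per_seed") <- per_seed
  out
}
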