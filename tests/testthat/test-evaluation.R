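# Split geometry, AUC, early-stopping trace, results aggregation.

test_that("CCV folds partition every center at about 20% per fold", {
  co <- generate_cohort(study_center_profiles(), master_seed = 1)
  plan <- make_ccv_splits(co, k = 5, seed = 3)
  expect_length(plan$folds, 5L)
  validate_split_plan(plan, co)
  test_sizes <- vapply(plan$folds, function(f) length(f$test), 1L)
  expect_true(all(abs(test_sizes - 36) <= 4))  # 20% of 180, rounding slack
  expect_equal(sum(test_sizes), 180L)
  # per-center contribution of each fold close to a fifth
  for (f in plan$folds) {
    per_center <- table(co$center[co$subject_id %in% f$test])
    totals <- table(co$center)
    expect_true(all(abs(per_center - totals / 5) <= 1))
  }
  expect_error(make_ccv_splits(co[co$center == "SantPau", ][1:4, ], k = 5),
               "fewer than")
})

test_that("LCO plans hold out exactly one full center per fold", {
  co <- generate_cohort(study_center_profiles(), master_seed = 1)
  plan <- make_lco_splits(co, seed = 2)
  expect_length(plan$folds, 4L)  # one fold per center
  validate_split_plan(plan, co)
  held <- vapply(plan$folds, `[[`, "", "test_center")
  expect_setequal(held, unique(co$center))
  acdc <- plan$folds[[which(held == "ACDC")]]
  acdc_ids <- co$subject_id[co$center == "ACDC"]
  expect_setequal(acdc$test, acdc_ids)
  expect_false(any(c(acdc$train, acdc$validation) %in% acdc_ids))
  # every subject appears in exactly one test fold
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")), co$subject_id)
  one_center <- co[co$center == "ACDC", ]
  expect_error(make_lco_splits(one_center), "two centers")
})

test_that("both timepoints of a subject always share a partition", {
  # splits operate on subjects; expanding to subject-timepoints keeps pairs
  co <- generate_cohort(tiny_profiles(), master_seed = 4)
  plan <- make_ccv_splits(co, k = 3, seed = 1)
  expanded <- expand.grid(subject_id = co$subject_id,
                          timepoint = c("ED", "ES"),
                          stringsAsFactors = FALSE)
  for (f in plan$folds) {
    part <- ifelse(expanded$subject_id %in% f$test, "test",
                   ifelse(expanded$subject_id %in% f$validation,
                          "validation", "train"))
    by_subj <- tapply(part, expanded$subject_id,
                      function(p) length(unique(p)))
    expect_true(all(by_subj == 1L))
  }
})

test_that("rank-based AUC handles the worked example and ties", {
  expect_equal(compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(compute_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(compute_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(compute_auc(c(0.2, 0.8), c(1, 1)), "both classes")
  # labels may arrive as NOR/HCM strings
  expect_equal(compute_auc(c(0.1, 0.9), c("NOR", "HCM")), 1.0)
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:10) {
    n <- 40
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- stats::rnorm(n) + y
    s[sample(n, 5)] <- 0.5  # inject ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("the early stopping rule traces injected score sequences", {
  tr <- early_stop_trace(c(0.6, rep(0.7, 11)), patience = 10)
  expect_equal(tr$best_round, 2L)
  expect_equal(tr$stop_round, 12L)
  # patience 0: stop at the first non-improving round
  tr0 <- early_stop_trace(c(0.6, 0.6), patience = 0)
  expect_equal(tr0$stop_round, 2L)
  expect_equal(tr0$best_round, 1L)
  # monotone improvement: runs to the end of the budget
  trm <- early_stop_trace(seq(0.1, 0.9, by = 0.1), patience = 3)
  expect_equal(trm$stop_round, 9L)
  expect_equal(trm$best_round, 9L)
})

test_that("results aggregate over seeds with population std", {
  aucs <- c(0.8, 0.8, 0.9, 0.9, 1.0)
  # construct predictions whose per-seed pooled AUC is exactly controlled:
  # seed s gets 10 points; AUC target reached by ordering scores
  rows <- list()
  for (s in seq_along(aucs)) {
    y <- rep(c(0, 1), each = 5)
    n_concordant <- round(aucs[s] * 25)
    scores <- c(seq(0.1, 0.5, length.out = 5), seq(0.6, 1.0, length.out = 5))
    # flip pairs by moving negatives up until the pair count matches
    flips <- 25 - n_concordant
    if (flips > 0) scores[5] <- scores[5] + 0.12 * flips  # overtakes positives
    rows[[s]] <- data.frame(seed = s, fold = 1, center = "A",
                            subject_id = paste0("s", 1:10),
                            timepoint = "ED", label = y, prob = scores)
  }
  preds <- do.call(rbind, rows)
  per_seed <- attr(aggregate_results(preds), "per_seed")
  got <- aggregate_results(preds)
  expect_equal(got$Total_mean, mean(per_seed[, "Total"]))
  # the documented convention: population standard deviation over seeds
  v <- per_seed[, "Total"]
  expect_equal(got$Total_sd, sqrt(mean((v - mean(v))^2)))
  # and the arithmetic for the intended AUC sequence
  expect_equal(mean(aucs), 0.88)
  expect_equal(sqrt(mean((aucs - mean(aucs))^2)), 0.07483315, tolerance = 1e-6)
})

test_that("the Total column pools predictions rather than averaging centers", {
  # two centers with opposite difficulty: pooled AUC differs from the mean
  # of per-center AUCs because cross-center pairs count too
  preds <- data.frame(
    seed = 0, fold = 1,
    center = rep(c("A", "B"), each = 4),
    subject_id = paste0("s", 1:8), timepoint = "ED",
    label = c(0, 0, 1, 1, 0, 0, 1, 1),
    prob = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9))
  res <- aggregate_results(preds)
  per_center_mean <- mean(c(res$A_mean, res$B_mean))
  expect_equal(res$A_mean, 1.0)
  expect_equal(res$B_mean, 1.0)
  pooled <- compute_auc(preds$prob, preds$label)
  expect_equal(res$Total_mean, pooled)
  expect_false(isTRUE(all.equal(res$Total_mean, per_center_mean)))
})
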