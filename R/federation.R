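# Collaborative learning frameworks -----------------------------------------
#
# Three frameworks over identical data and models: CDS (pooled centralized
# training), FL (FederatedAveraging: per-center local rounds aggregated with
# coefficients n_k / n) and FL-EV (equal voting: uniform coefficients 1/K).
# One communication round equals seven local gradient iterations per center.
# Only model weights ever cross a center boundary.

#' FederatedAveraging aggregation
#'
#' Elementwise convex combination of per-center weight sets with
#' coefficients `n_k / n`, so larger centers carry proportionally more of
#' the global model.
#'
#' @param weights_list list of K `model_weights` (identical shape
#'   signatures).
#' @param n_k per-center sample sizes (length K, all >= 1).
#' @return the aggregated `model_weights`.
#' @export
aggregate_fedavg <- function(weights_list, n_k) {
  if (length(weights_list) < 1L) stop("no weight sets to aggregate")
  if (length(n_k) != length(weights_list))
    stop("n_k must have one entry per weight set")
  if (sum(n_k) <= 0) stop("total sample size must be positive")
  aggregate_weighted(weights_list, n_k / sum(n_k))
}

#' Equal-voting aggregation
#'
#' Unweighted elementwise mean: every center receives coefficient 1/K
#' regardless of its sample size.
#'
#' @param weights_list list of K `model_weights`.
#' @return the aggregated `model_weights`.
#' @export
aggregate_equal <- function(weights_list) {
  if (length(weights_list) < 1L) stop("no weight sets to aggregate")
  k <- length(weights_list)
  aggregate_weighted(weights_list, rep(1 / k, k))
}

aggregate_weighted <- function(weights_list, coef) {
  coef <- unname(coef)
  ref <- weights_list[[1L]]
  for (wl in weights_list[-1L]) check_same_signature(ref, wl)
  out <- lapply(names(ref), function(nm) {
    acc <- coef[1L] * ref[[nm]]
    for (i in seq_along(weights_list)[-1L])
      acc <- acc + coef[i] * weights_list[[i]][[nm]]
    acc
  })
  structure(stats::setNames(out, names(ref)), class = "model_weights")
}

#' Federation configuration
#'
#' @param framework `"CDS"`, `"FL"` or `"FL_EV"`.
#' @param iterations_per_round local gradient iterations per communication
#'   round (default 7).
#' @param rounds maximum communication rounds (default 100).
#' @param patience early-stopping patience in rounds (default 10).
#' @param lr_head head learning rate override (NULL = classifier spec).
#' @return an object of class `federation_config`.
#' @export
federation_config <- function(framework = c("CDS", "FL", "FL_EV"),
                              iterations_per_round = 7L, rounds = 100L,
                              patience = 10L, lr_head = NULL) {
  framework <- match.arg(framework)
  structure(list(framework = framework,
                 iterations_per_round = as.integer(iterations_per_round),
                 rounds = as.integer(rounds), patience = as.integer(patience),
                 lr_head = lr_head),
            class = "federation_config")
}

#' Run one communication round
#'
#' FL/FL-EV: the identical global weights are distributed to every center,
#' each center runs one local round of `iterations_per_round` gradient
#' steps, and the local weight sets are aggregated
#' ([aggregate_fedavg] for FL, [aggregate_equal] for FL-EV). CDS instead
#' trains a single model for one epoch over the pooled stream, with the
#' batch count chosen as `iterations_per_round * K` so one CDS epoch takes
#' the same number of gradient steps as one federated round across all
#' centers.
#'
#' @param global a `model_weights` object (the current global model).
#' @param handle a built classifier used as the computation template.
#' @param center_data named list (one entry per center) of lists with
#'   `features` (matrix) and `labels` (0/1 vector).
#' @param config a [federation_config].
#' @return the updated global `model_weights`.
#' @export
run_round <- function(global, handle, center_data, config) {
  stopifnot(inherits(config, "federation_config"))
  if (length(center_data) < 1L) stop("no centers provided")
  lr <- config$lr_head %||% handle$spec$lr_head
  it <- config$iterations_per_round
  if (config$framework == "CDS") {
    feats <- do.call(rbind, lapply(center_data, `[[`, "features"))
    labs <- unlist(lapply(center_data, `[[`, "labels"), use.names = FALSE)
    h <- set_model_weights(handle, global)
    h <- train_local_round(h, feats, labs,
                           n_iterations = it * length(center_data), lr = lr)
    return(model_weights(h))
  }
  locals <- lapply(center_data, function(cd) {
    h <- set_model_weights(handle, global)
    h <- train_local_round(h, cd$features, cd$labels, n_iterations = it,
                           lr = lr)
    model_weights(h)
  })
  n_k <- vapply(center_data, function(cd) nrow(cd$features), 1L)
  if (config$framework == "FL") aggregate_fedavg(locals, n_k)
  else aggregate_equal(locals)
}

#' Train under a collaborative framework with early stopping
#'
#' Runs communication rounds until the validation score (the negative
#' n_k-weighted mean of per-center validation cross-entropy, evaluated
#' locally at each center) stops improving for `patience` rounds or the
#' round budget is exhausted; the best-scoring weights are restored.
#'
#' @param handle a built classifier (its weights are the identical
#'   initialization distributed to all centers).
#' @param center_data named list of per-center `features`/`labels` for
#'   training, or a function of the round index returning such a list (used
#'   when stochastic augmentation regenerates features every round).
#' @param val_data named list of per-center `features`/`labels` for
#'   validation; centers with no validation samples are skipped.
#' @param config a [federation_config].
#' @return list with `weights` (best `model_weights`), `best_round`,
#'   `rounds_run` and the per-round `score` trace.
#' @export
train_federated <- function(handle, center_data, val_data, config) {
  global <- model_weights(handle)
  score_fn <- function(w) {
    h <- set_model_weights(handle, w)
    tot <- 0; wsum <- 0
    for (cd in val_data) {
      n <- nrow(cd$features)
      if (is.null(n) || n == 0L) next
      tot <- tot + n * bce_loss(h, cd$features, cd$labels)
      wsum <- wsum + n
    }
    if (wsum == 0L) stop("no validation samples available")
    -tot / wsum
  }
  best <- global; best_score <- -Inf; best_round <- 0L; stale <- 0L
  trace <- numeric(0)
  for (r in seq_len(config$rounds)) {
    cd <- if (is.function(center_data)) center_data(r) else center_data
    global <- run_round(global, handle, cd, config)
    sc <- score_fn(global)
    if (!is.finite(sc)) stop("validation score is non-finite")
    trace <- c(trace, sc)
    if (sc > best_score) {
      best_score <- sc; best <- global; best_round <- r; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  list(weights = best, best_round = best_round, rounds_run = length(trace),
       score = trace)
}
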