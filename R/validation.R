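#' Invariant accuracy of prediction (IAP / ROC AUC)
#'
#' The probability that a randomly chosen active outscores a randomly
#' chosen inactive, with half credit for ties — the Mann-Whitney statistic
#' scaled to [0, 1], numerically equal to the area under the ROC curve.
#' Computed in O(n log n) via mid-ranks, so it is invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores_active,scores_inactive numeric score vectors, both
#'   non-empty.
#' @return IAP in [0, 1].
#' @examples
#' iap(c(0.9, 0.8), c(0.1, 0.2))   # 1: complete separation
#' iap(c(1, 1), c(1, 1))           # 0.5: all ties
#' @export
iap <- function(scores_active, scores_inactive) {
  n1 <- length(scores_active)
  n0 <- length(scores_inactive)
  if (n1 == 0L || n0 == 0L)
    stop("both score classes must be non-empty", call. = FALSE)
  r <- rank(c(scores_active, scores_inactive))  # mid-ranks on ties
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Label-stratified fold assignment, deterministic given seed. Classes are
# shuffled and dealt round-robin with a counter running across classes, so
# global fold sizes stay balanced and k = n yields singleton folds.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    pos <- 0L
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) > 1L) idx <- sample(idx)
      if (length(idx) < k)
        warning(sprintf(
          "class '%s' has %d members for %d folds; stratification degrades",
          cls, length(idx), k), call. = FALSE)
      fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  fold
}

#' Pooled k-fold cross-validated IAP for one activity
#'
#' Compounds are split into `k` seeded, label-stratified folds; each fold
#' is scored by a model trained on the remaining folds, and one IAP is
#' computed over the pooled out-of-fold scores (stable for activities with
#' few actives, unlike averaging per-fold AUCs). With `k` equal to the
#' number of compounds this is exactly leave-one-out. A training fold left
#' without actives is skipped with a warning.
#'
#' @param labeled a `labeled_set`.
#' @param features named list of descriptor sets covering its compounds.
#' @param k number of folds (>= 2), default 20.
#' @param seed integer seed; the same seed always reproduces the same
#'   folds and result.
#' @param regularization,min_actives passed to [sar_train()];
#'   `min_actives` is relaxed to 1 inside folds so a small activity can
#'   still be fit on its training portion.
#' @return Pooled IAP (single double).
#' @export
kfold_iap <- function(labeled, features, k = 20L, seed = 1L,
                      regularization = 1, min_actives = 1L) {
  stopifnot(inherits(labeled, "labeled_set"))
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- length(labeled$compound_id)
  if (k > n) stop("k exceeds the number of compounds", call. = FALSE)
  fold <- stratified_folds(labeled$label, k, seed)
  scores <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- fold == f
    train_ids <- labeled$compound_id[!test]
    train_lab <- labeled$label[!test]
    if (!any(train_lab == "active")) {
      warning(sprintf("fold %d skipped: training portion has no actives", f),
              call. = FALSE)
      next
    }
    ls <- labeled_set(labeled$activity_id, train_ids, train_lab)
    m <- suppressMessages(
      sar_train(ls, features, regularization = regularization,
                min_actives = min_actives))
    a <- labeled$activity_id
    for (i in which(test))
      scores[i] <- sar_score(m, features[[labeled$compound_id[i]]], a)
  }
  ok <- !is.na(scores)
  iap(scores[ok & labeled$label == "active"],
      scores[ok & labeled$label == "inactive"])
}

#' Cross-validated accuracy report over all activities
#'
#' Trains one model on all labeled sets, reads off the analytic
#' leave-one-out IAP per activity from its calibration arrays, adds the
#' seeded k-fold IAP, and flags the activities whose LOO accuracy is
#' strictly above the selection threshold — the reliability filter applied
#' before a model is put to predictive use.
#'
#' @param labeled list of `labeled_set` objects.
#' @param features named list of descriptor sets.
#' @param k folds for [kfold_iap()] (default 20).
#' @param seed fold seed.
#' @param auc_threshold strict selection threshold on LOO IAP
#'   (default 0.8).
#' @param regularization,min_actives passed to [sar_train()].
#' @return A `sar_validation`: data.frame with columns `activity_id`,
#'   `n_active`, `n_inactive`, `iap_loo`, `iap_kfold`, `selected`, with
#'   the run parameters in `attr(, "metadata")`.
#' @export
validate_sar <- function(labeled, features, k = 20L, seed = 1L,
                         auc_threshold = 0.8, regularization = 1,
                         min_actives = 3L) {
  if (inherits(labeled, "labeled_set")) labeled <- list(labeled)
  model <- sar_train(labeled, features, regularization = regularization,
                     min_actives = min_actives)
  names(labeled) <- vapply(labeled, `[[`, character(1), "activity_id")
  rows <- lapply(names(model$activities), function(a) {
    act <- model$activities[[a]]
    # the k-fold set is the model's full pool labeled for this activity
    pool <- labeled_set(a, model$compound_ids,
                        ifelse(model$compound_ids %in% act$active_ids,
                               "active", "inactive"))
    kf <- kfold_iap(pool, model$features, k = min(k, model$n_compounds),
                    seed = seed, regularization = regularization)
    data.frame(activity_id = a, n_active = act$n_active,
               n_inactive = model$n_compounds - act$n_active,
               iap_loo = iap(act$cal_active, act$cal_inactive),
               iap_kfold = kf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$iap_loo > auc_threshold
  rownames(out) <- NULL
  attr(out, "metadata") <- list(k = as.integer(k), seed = as.integer(seed),
                                auc_threshold = auc_threshold,
                                min_actives = as.integer(min_actives),
                                regularization = regularization)
  class(out) <- c("sar_validation", "data.frame")
  out
}

#' @export
print.sar_validation <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("cross-validated accuracy report (k = %d, seed = %d, %s)\n",
              md$k, md$seed,
              sprintf("selection: LOO IAP > %g", md$auc_threshold)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("mean LOO IAP, all activities:      %.4f\n", mean(x$iap_loo)))
  if (any(x$selected))
    cat(sprintf("mean LOO IAP, selected activities: %.4f\n",
                mean(x$iap_loo[x$selected])))
  invisible(x)
}

#' Select activities above the accuracy threshold
#'
#' Strictly-greater-than filter on the leave-one-out IAP: an activity
#' predicted with AUC exactly at the threshold is not selected.
#'
#' @param report a `sar_validation` report.
#' @param auc_threshold threshold, default 0.8.
#' @return Character vector of selected activity ids.
#' @export
select_activities <- function(report, auc_threshold = 0.8) {
  report$activity_id[report$iap_loo > auc_threshold]
}
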