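#' Train the Bayesian descriptor-activity model
#'
#' The predictor is a regularized naive-Bayes scorer over presence/absence
#' MNA descriptors. With `N` training compounds, `n_d` compounds carrying
#' descriptor `d`, and for activity `a` with `n_a` actives of which `n_da`
#' carry `d`, the conditional activity estimate is
#' \deqn{p_{da} = (n_{da} + c \, p_a) / (n_d + c), \qquad p_a = n_a / N,}
#' with regularization constant `c` (default 1) pulling rare descriptors
#' toward the prior. A compound with descriptor set `D(x)` scores
#' \deqn{s(x, a) = \mathrm{mean}_{d \in D(x) \cap V} \arcsin(2 p_{da} - 1),}
#' the arcsine stabilizing the variance of the per-descriptor estimates;
#' when the query shares no descriptor with the vocabulary `V` the score
#' falls back to the prior term \eqn{\arcsin(2 p_a - 1)}.
#'
#' Every compound in any labeled set joins one training pool; compounds not
#' labeled active for an activity count as its inactives (inactivity is the
#' absence of evidence of activity). For each activity the model stores the
#' leave-one-out scores of all training compounds (computed analytically,
#' see [loo_scores()]); these empirical score distributions calibrate the
#' Pa/Pi output of [predict.sar_model()].
#'
#' @param labeled a `labeled_set` or list of them (one per activity).
#' @param features named list mapping `compound_id` to its descriptor set
#'   (character vector), e.g. from [featurize_structures()].
#' @param regularization the constant `c` above; must be > 0 so that
#'   `p_da` never saturates the arcsine at exactly 0 or 1.
#' @param min_actives activities with fewer actives (or with no inactive)
#'   are excluded with a message; all excluded is an error.
#' @param max_level descriptor depth recorded as provenance in the model
#'   (the features are supplied already computed).
#' @param ruleset provenance string recorded in the model config.
#' @return An object of class `sar_model`.
#' @examples
#' feats <- list(c1 = c("A", "B"), c2 = c("A", "C"), c3 = c("B", "D"),
#'               c4 = c("C", "D"))
#' ls <- labeled_set("tox", paste0("c", 1:4),
#'                   c("active", "active", "inactive", "inactive"))
#' m <- sar_train(ls, feats, min_actives = 2)
#' predict(m, c("A", "B"))
#' @seealso [predict.sar_model()], [loo_scores()], [iap()]
#' @export
sar_train <- function(labeled, features, regularization = 1,
                      min_actives = 3L, max_level = 2L, ruleset = "") {
  if (inherits(labeled, "labeled_set")) labeled <- list(labeled)
  if (!length(labeled)) stop("no labeled sets supplied", call. = FALSE)
  if (regularization <= 0) stop("regularization must be > 0", call. = FALSE)
  all_ids <- sort(unique(unlist(lapply(labeled, `[[`, "compound_id"))))
  missing <- setdiff(all_ids, names(features))
  if (length(missing))
    stop("no descriptor set for compounds: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  feats <- features[all_ids]
  N <- length(all_ids)

  vocab <- sort(unique(unlist(feats, use.names = FALSE)))
  n_d <- tabulate_descriptors(feats, vocab)

  activities <- list()
  for (ls in labeled) {
    a <- ls$activity_id
    act_ids <- ls$compound_id[ls$label == "active"]
    n_a <- length(act_ids)
    if (n_a < min_actives || n_a >= N) {
      message(sprintf(
        "activity '%s' excluded: %d actives, %d inactives (min_actives = %d)",
        a, n_a, N - n_a, min_actives))
      next
    }
    n_da <- tabulate_descriptors(feats[act_ids], vocab)
    activities[[a]] <- list(activity_id = a, n_active = n_a,
                            active_ids = act_ids, n_da = n_da)
  }
  if (!length(activities))
    stop("all activities excluded during training", call. = FALSE)

  model <- structure(list(
    vocabulary = vocab,
    n_compounds = N,
    compound_ids = all_ids,
    n_d = n_d,
    activities = activities,
    config = list(regularization = regularization,
                  min_actives = as.integer(min_actives),
                  max_level = as.integer(max_level), ruleset = ruleset)
  ), class = "sar_model")

  # analytic-LOO calibration: per activity, the LOO score of every training
  # compound, kept with ids for reporting and sorted per class for Pa/Pi
  for (a in names(model$activities)) {
    loo <- loo_scores(model, a, feats)
    is_act <- names(loo) %in% model$activities[[a]]$active_ids
    model$activities[[a]]$loo <- loo
    model$activities[[a]]$cal_active <- sort(unname(loo[is_act]))
    model$activities[[a]]$cal_inactive <- sort(unname(loo[!is_act]))
  }
  model$features <- feats
  model
}

# count, per vocabulary item, the compounds whose set contains it
tabulate_descriptors <- function(feats, vocab) {
  idx <- match(unlist(feats, use.names = FALSE), vocab)
  counts <- tabulate(idx[!is.na(idx)], nbins = length(vocab))
  stats::setNames(as.integer(counts), vocab)
}

#' Score a descriptor set against one activity
#'
#' Deterministic evaluation of the model's evidence statistic; descriptors
#' absent from the training vocabulary are ignored, and a query sharing no
#' descriptor with the vocabulary receives the prior fallback
#' `asin(2 * p_a - 1)` rather than an error.
#'
#' @param model a [sar_train()] fit.
#' @param descriptors character vector: the query's descriptor set.
#' @param activity_id activity present in the model.
#' @return The score (a single double).
#' @export
sar_score <- function(model, descriptors, activity_id) {
  act <- model$activities[[activity_id]]
  if (is.null(act))
    stop("unknown activity: ", activity_id, call. = FALSE)
  score_one(descriptors, model$vocabulary, model$n_d, act$n_da,
            act$n_active, model$n_compounds, model$config$regularization)
}

score_one <- function(descriptors, vocab, n_d, n_da, n_a, N, c0) {
  p_a <- n_a / N
  idx <- match(descriptors, vocab)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(asin(2 * p_a - 1))
  p_da <- (n_da[idx] + c0 * p_a) / (n_d[idx] + c0)
  mean(asin(2 * p_da - 1))
}

#' Analytic leave-one-out scores of the training compounds
#'
#' For each training compound its score is recomputed with its own
#' contributions removed from all count statistics: `N - 1` compounds,
#' `n_d` reduced by the compound's descriptor membership, and `n_a`,
#' `n_da` reduced iff the compound is active for the activity. Descriptors
#' that occur in no other training compound drop out of the score, exactly
#' as they would be absent from the vocabulary of a model retrained without
#' the compound; the result equals explicit retraining without the compound
#' to within floating-point noise. Removing the only active leaves a
#' degenerate prior (`p_a = 0`), against which the score is still computed
#' (and flagged by a message).
#'
#' @param model a [sar_train()] fit (or the partial model during training).
#' @param activity_id activity present in the model.
#' @param feats optional features map override (used internally during
#'   training, before the map is attached to the model).
#' @return Named numeric vector of LOO scores, one per training compound.
#' @export
loo_scores <- function(model, activity_id, feats = NULL) {
  act <- model$activities[[activity_id]]
  if (is.null(act))
    stop("unknown activity: ", activity_id, call. = FALSE)
  if (is.null(feats)) feats <- model$features
  vocab <- model$vocabulary
  n_d <- model$n_d
  n_da <- act$n_da
  N <- model$n_compounds
  n_a <- act$n_active
  c0 <- model$config$regularization
  ids <- model$compound_ids
  is_act <- ids %in% act$active_ids
  if (n_a == 1L)
    message(sprintf(
      "activity '%s': single active; its LOO score uses a degenerate prior",
      activity_id))
  out <- numeric(length(ids))
  for (k in seq_along(ids)) {
    d <- feats[[ids[k]]]
    idx <- match(d, vocab)
    idx <- idx[!is.na(idx)]
    a_k <- is_act[k]
    n_a1 <- n_a - as.integer(a_k)
    p_a1 <- n_a1 / (N - 1L)
    if (length(idx)) {
      n_d1 <- n_d[idx] - 1L
      keep <- n_d1 >= 1L          # descriptor unique to this compound:
      idx <- idx[keep]            # absent from the retrained vocabulary
      n_d1 <- n_d1[keep]
    }
    if (!length(idx)) {
      out[k] <- asin(2 * p_a1 - 1)
    } else {
      n_da1 <- n_da[idx] - as.integer(a_k)
      p_da1 <- (n_da1 + c0 * p_a1) / (n_d1 + c0)
      out[k] <- mean(asin(2 * p_da1 - 1))
    }
  }
  stats::setNames(out, ids)
}

# rank position of s within a sorted calibration array, half credit on ties
rank_position <- function(s, sorted_scores, direction = c("below", "above")) {
  direction <- match.arg(direction)
  n <- length(sorted_scores)
  if (direction == "below")
    (sum(sorted_scores < s) + 0.5 * sum(sorted_scores == s)) / n
  else
    (sum(sorted_scores > s) + 0.5 * sum(sorted_scores == s)) / n
}

#' Predict Pa/Pi probability pairs for new structures
#'
#' For each activity the query's score is placed within the stored
#' leave-one-out score distributions of the training compounds:
#' `Pa` is the fraction of training actives scoring below the query (ties
#' half credit) — the probability estimate "to be active" — and `Pi` the
#' fraction of training inactives scoring above it. Rows are sorted by
#' `Pa - Pi` descending, so the more probable activities top the list.
#' Descriptors never seen in training are ignored and cannot change any
#' prediction.
#'
#' @param object a `sar_model`.
#' @param newdata one descriptor set (character vector) or a named list of
#'   them (one element per compound).
#' @param activities optional character vector restricting the activities
#'   scored.
#' @param ... unused.
#' @return data.frame with columns `compound_id`, `activity_id`, `score`,
#'   `Pa`, `Pi`, sorted by `Pa - Pi` descending within compound.
#' @export
predict.sar_model <- function(object, newdata, activities = NULL, ...) {
  if (is.character(newdata)) newdata <- list(query = newdata)
  if (!length(newdata)) stop("no query compounds", call. = FALSE)
  if (is.null(names(newdata)))
    names(newdata) <- paste0("query", seq_along(newdata))
  acts <- names(object$activities)
  if (!is.null(activities)) {
    bad <- setdiff(activities, acts)
    if (length(bad))
      stop("unknown activities: ", paste(bad, collapse = ", "),
           call. = FALSE)
    acts <- activities
  }
  rows <- vector("list", length(newdata))
  for (q in seq_along(newdata)) {
    d <- newdata[[q]]
    if (!length(d))
      stop("empty descriptor set for compound '", names(newdata)[q], "'",
           call. = FALSE)
    sc <- vapply(acts, function(a) sar_score(object, d, a), numeric(1))
    pa <- pi_ <- numeric(length(acts))
    for (j in seq_along(acts)) {
      act <- object$activities[[acts[j]]]
      pa[j] <- rank_position(sc[j], act$cal_active, "below")
      pi_[j] <- rank_position(sc[j], act$cal_inactive, "above")
    }
    df <- data.frame(compound_id = names(newdata)[q], activity_id = acts,
                     score = unname(sc), Pa = pa, Pi = pi_,
                     stringsAsFactors = FALSE)
    df <- df[order(-(df$Pa - df$Pi), df$activity_id), , drop = FALSE]
    rows[[q]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out predictions for the training compounds
#'
#' The per-compound analytic LOO scores of one activity together with their
#' Pa/Pi placement in the calibration distributions (which contain these
#' same scores, so each compound's own score counts as a self-tie). On a
#' well-trained activity the Pa values of the actives are approximately
#' uniform on [0, 1]: a `Pa > t` selection filter loses about a fraction
#' `t` of the true actives.
#'
#' @param model a `sar_model`.
#' @param activity_id activity present in the model.
#' @return data.frame with `compound_id`, `label`, `score`, `Pa`, `Pi`.
#' @export
training_loo <- function(model, activity_id) {
  act <- model$activities[[activity_id]]
  if (is.null(act))
    stop("unknown activity: ", activity_id, call. = FALSE)
  loo <- act$loo
  is_act <- names(loo) %in% act$active_ids
  pa <- vapply(loo, rank_position, numeric(1),
               sorted_scores = act$cal_active, direction = "below")
  pi_ <- vapply(loo, rank_position, numeric(1),
                sorted_scores = act$cal_inactive, direction = "above")
  data.frame(compound_id = names(loo),
             label = ifelse(is_act, "active", "inactive"),
             score = unname(loo), Pa = unname(pa), Pi = unname(pi_),
             stringsAsFactors = FALSE)
}

#' @export
print.sar_model <- function(x, ...) {
  cat(sprintf(
    "sar_model: %d training compounds, %d descriptors, %d activities\n",
    x$n_compounds, length(x$vocabulary), length(x$activities)))
  cat(sprintf("  regularization c = %g, MNA max level = %d\n",
              x$config$regularization, x$config$max_level))
  invisible(x)
}

#' @export
summary.sar_model <- function(object, ...) {
  rows <- lapply(object$activities, function(a) data.frame(
    activity_id = a$activity_id, n_active = a$n_active,
    n_inactive = object$n_compounds - a$n_active,
    iap_loo = iap(a$cal_active, a$cal_inactive),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(model = object, table = out), class = "summary.sar_model")
}

#' @export
print.summary.sar_model <- function(x, ...) {
  print(x$model)
  cat("per-activity leave-one-out accuracy (IAP = ROC AUC):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

MODEL_FORMAT <- "mnasar-model"
MODEL_VERSION <- 1L

#' Save / load a trained model
#'
#' The model file is a versioned, self-describing JSON document: a format
#' magic and version, the training configuration, the descriptor
#' vocabulary with its compound counts, per-activity active counts and
#' descriptor-in-active counts, the calibration (leave-one-out) score
#' arrays at full double precision, and the per-compound descriptor sets.
#' A saved model reloads to identical predictions bit for bit.
#'
#' @param model a `sar_model`.
#' @param path file path (`.json`).
#' @return `write_sar_model` returns `path` invisibly; `read_sar_model`
#'   returns the `sar_model`.
#' @export
write_sar_model <- function(model, path) {
  acts <- lapply(model$activities, function(a) list(
    activity_id = a$activity_id,
    n_active = a$n_active,
    active_ids = a$active_ids,
    n_da = as.list(stats::setNames(as.integer(a$n_da[a$n_da > 0L]),
                                   names(a$n_da)[a$n_da > 0L])),
    loo = as.list(a$loo),
    cal_active = a$cal_active,
    cal_inactive = a$cal_inactive))
  doc <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
              config = model$config,
              n_compounds = model$n_compounds,
              compound_ids = model$compound_ids,
              vocabulary = model$vocabulary,
              n_d = as.integer(model$n_d),
              activities = acts,
              features = model$features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_sar_model
#' @export
read_sar_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, MODEL_FORMAT))
    stop("not a ", MODEL_FORMAT, " file: ", path, call. = FALSE)
  if (doc$version > MODEL_VERSION)
    stop("model file version ", doc$version, " is newer than supported (",
         MODEL_VERSION, ")", call. = FALSE)
  vocab <- doc$vocabulary
  activities <- lapply(doc$activities, function(a) {
    n_da <- stats::setNames(integer(length(vocab)), vocab)
    if (length(a$n_da))
      n_da[names(a$n_da)] <- as.integer(unlist(a$n_da))
    loo <- unlist(a$loo)
    list(activity_id = a$activity_id, n_active = as.integer(a$n_active),
         active_ids = as.character(a$active_ids), n_da = n_da,
         loo = loo,
         cal_active = as.numeric(a$cal_active),
         cal_inactive = as.numeric(a$cal_inactive))
  })
  names(activities) <- vapply(activities, `[[`, character(1), "activity_id")
  model <- structure(list(
    vocabulary = vocab,
    n_compounds = as.integer(doc$n_compounds),
    compound_ids = as.character(doc$compound_ids),
    n_d = stats::setNames(as.integer(doc$n_d), vocab),
    activities = activities,
    config = doc$config,
    features = lapply(doc$features, as.character)
  ), class = "sar_model")
  # the stored calibration arrays describe the model to independent
  # readers; here they are recomputed from the exact integer counts so a
  # reloaded model predicts bit-for-bit identically however many decimal
  # digits the serialization carried
  for (a in names(model$activities)) {
    loo <- suppressMessages(loo_scores(model, a))
    is_act <- names(loo) %in% model$activities[[a]]$active_ids
    model$activities[[a]]$loo <- loo
    model$activities[[a]]$cal_active <- sort(unname(loo[is_act]))
    model$activities[[a]]$cal_inactive <- sort(unname(loo[!is_act]))
  }
  model
}
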