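test_that("training counts and scores match the from-scratch oracle", {
  fx <- toy_fixture(n = 12, vocab = 10, seed = 3)
  fit <- sar_train(fx$labeled, fx$features, min_actives = 1)
  active_ids <- fx$labeled$compound_id[fx$labeled$label == "active"]
  a <- fx$labeled$activity_id[1]
  for (q in list(fx$features[[1]], c("V1", "V2"), "unseen-descriptor")) {
    expect_equal(sar_score(fit, q, a),
                 oracle_score(fx$features, active_ids, q), tolerance = 1e-14)
  }
  # invariant bounds on the counts
  act <- fit$activities[[a]]
  expect_true(all(act$n_da <= pmin(fit$n_d, act$n_active)))
  expect_true(all(fit$n_d <= fit$n_compounds))
})

test_that("an all-active descriptor is enriched above the prior", {
  feats <- list(a1 = c("X", "B1"), a2 = c("X", "B2"), a3 = c("X", "B3"),
                i1 = c("B1", "B2"), i2 = c("B2", "B3"), i3 = c("B3", "B1"))
  ls <- labeled_set("act", names(feats), rep(c("active", "inactive"),
                                             each = 3))
  fit <- sar_train(ls, feats)
  p_a <- 0.5
  prior_score <- asin(2 * p_a - 1)
  expect_gt(sar_score(fit, "X", "act"), prior_score)
  # zero vocabulary overlap falls back to exactly the prior score
  expect_equal(sar_score(fit, "nothing-known", "act"), prior_score)
})

test_that("analytic LOO equals explicit retrain-without-one", {
  for (seed in 1:4) {
    n <- sample(8:20, 1)
    fx <- toy_fixture(n = n, vocab = 7, seed = seed)
    fit <- sar_train(fx$labeled, fx$features, min_actives = 1)
    a <- fx$labeled$activity_id[1]
    loo <- fit$activities[[a]]$loo
    for (k in seq_len(n)) {
      id <- fx$labeled$compound_id[k]
      ls_k <- labeled_set(a, fx$labeled$compound_id[-k],
                          fx$labeled$label[-k])
      refit <- suppressMessages(
        sar_train(ls_k, fx$features, min_actives = 1))
      expect_equal(loo[[id]], sar_score(refit, fx$features[[id]], a),
                   tolerance = 1e-12)
    }
  }
})

test_that("LOO bookkeeping: inactives leave n_da untouched, actives not", {
  fx <- toy_fixture(n = 10, vocab = 6, seed = 9)
  fit <- sar_train(fx$labeled, fx$features, min_actives = 1)
  a <- fx$labeled$activity_id[1]
  loo <- fit$activities[[a]]$loo
  plain <- vapply(fx$labeled$compound_id, function(id)
    sar_score(fit, fx$features[[id]], a), numeric(1))
  # any compound carrying a vocabulary descriptor shifts under LOO
  for (id in fx$labeled$compound_id)
    expect_false(isTRUE(all.equal(loo[[id]], plain[[id]])))
  # a duplicate of a training compound scores identically to it (non-LOO)
  expect_equal(sar_score(fit, fx$features[[1]], a), plain[[1]])
})

test_that("Pa and Pi are monotone in the score with rank-extreme limits", {
  fx <- toy_fixture(n = 14, vocab = 8, seed = 5)
  fit <- sar_train(fx$labeled, fx$features, min_actives = 1)
  a <- fx$labeled$activity_id[1]
  act <- fit$activities[[a]]
  probe <- sort(c(act$cal_active, act$cal_inactive,
                  seq(-1.5, 1.5, length.out = 21)))
  pa <- vapply(probe, function(s)
    mnasar:::rank_position(s, act$cal_active, "below"), numeric(1))
  pi_ <- vapply(probe, function(s)
    mnasar:::rank_position(s, act$cal_inactive, "above"), numeric(1))
  expect_true(all(diff(pa) >= 0))
  expect_true(all(diff(pi_) <= 0))
  # a score above every calibration score
  expect_equal(mnasar:::rank_position(10, act$cal_active, "below"), 1)
  expect_equal(mnasar:::rank_position(10, act$cal_inactive, "above"), 0)
  # below every calibration score
  expect_equal(mnasar:::rank_position(-10, act$cal_active, "below"), 0)
  expect_equal(mnasar:::rank_position(-10, act$cal_inactive, "above"), 1)
  # degenerate all-ties calibration gives half credit
  expect_equal(mnasar:::rank_position(0.3, rep(0.3, 5), "below"), 0.5)
  expect_equal(mnasar:::rank_position(0.3, rep(0.3, 5), "above"), 0.5)
})

test_that("descriptors unseen in training never change a prediction", {
  fx <- toy_fixture(n = 12, vocab = 8, seed = 11)
  fit <- sar_train(fx$labeled, fx$features, min_actives = 1)
  q <- fx$features[[3]]
  p1 <- predict(fit, q)
  p2 <- predict(fit, c(q, "never-seen-anywhere"))
  expect_equal(p1[, c("score", "Pa", "Pi")], p2[, c("score", "Pa", "Pi")])
  expect_error(predict(fit, character(0)), "empty descriptor set")
  expect_error(sar_score(fit, q, "no-such-activity"), "unknown activity")
})

test_that("prediction lists sort by Pa - Pi descending", {
  ds <- make_descriptor_dataset(synth_config(n_active = 20,
                                             n_inactive = 40, seed = 2))
  null_ls <- labeled_set("null", ds$labeled$compound_id,
                         sample(ds$labeled$label))
  fit <- suppressMessages(sar_train(list(ds$labeled, null_ls),
                                    ds$features, min_actives = 1))
  p <- predict(fit, ds$features[[1]])
  expect_equal(order(-(p$Pa - p$Pi)), seq_len(nrow(p)))
  expect_true(all(p$Pa >= 0 & p$Pa <= 1 & p$Pi >= 0 & p$Pi <= 1))
})

test_that("model serialization round trips to identical predictions", {
  fx <- toy_fixture(n = 15, vocab = 9, seed = 13)
  fit <- sar_train(fx$labeled, fx$features, min_actives = 1,
                   regularization = 0.5, ruleset = "chembl_pubchem")
  tf <- withr::local_tempfile(fileext = ".json")
  write_sar_model(fit, tf)
  fit2 <- read_sar_model(tf)
  expect_identical(fit2$config$regularization, 0.5)
  queries <- c(fx$features[1:5],
               list(novel = c("V1", "V3", "zzz"), fallback = "zzz"))
  expect_identical(predict(fit, queries), predict(fit2, queries))
  expect_identical(fit$activities$toy$cal_active,
                   fit2$activities$toy$cal_active)
  # corrupted magic is refused
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), tf2, auto_unbox = TRUE)
  expect_error(read_sar_model(tf2), "not a mnasar-model")
})

test_that("degenerate activities are excluded or flagged", {
  feats <- list(a = "X", b = "Y", c = "Z")
  all_active <- labeled_set("all", names(feats), rep("active", 3))
  expect_error(suppressMessages(sar_train(all_active, feats,
                                          min_actives = 1)),
               "all activities excluded")
  one_active <- labeled_set("one", names(feats),
                            c("active", "inactive", "inactive"))
  expect_message(fit <- sar_train(one_active, feats, min_actives = 1),
                 "degenerate prior")
  expect_true(is.finite(fit$activities$one$loo[["a"]]))
  expect_error(sar_train(one_active, list(a = "X"), min_actives = 1),
               "no descriptor set")
})
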