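# Small forests (n_trees = 60) keep the unit tests quick; the ensemble's
# statistical behaviour at full depth is exercised in the acceptance tests.
fast_cfg <- function(seed = 1L, ...) {
  predictor_config(n_trees = 60L, tune_points = 2L, seed = seed, ...)
}

# Cleanly separable feature set: one informative column + noise.
sep_features <- function(n_escape = 30L, n_subject = 90L, seed = 1L,
                         signal = 5) {
  set.seed(seed)
  n <- n_escape + n_subject
  x <- matrix(rnorm(n * 14), n, 14,
              dimnames = list(sprintf("tx%03d", 1:n),
                              c(paste0("f_", 1:7), paste0("m_", 1:7))))
  lab <- c(rep("escape", n_escape), rep("subject", n_subject))
  x[, 1] <- x[, 1] + ifelse(lab == "escape", signal, 0)
  list(features = x, labels = stats::setNames(lab, rownames(x)))
}

test_that("vote calls enumerate identically to the oracle", {
  cfg <- predictor_config()
  got <- vote_call(0:20, cfg)
  want <- vapply(0:20, vote_oracle, "")
  expect_equal(got, want)
  expect_equal(vote_call(17, cfg), "escape")
  expect_equal(vote_call(13, cfg), "leaning_escape")
  expect_equal(vote_call(10, cfg), "uninformative")
  expect_equal(vote_call(11, cfg), "uninformative")
})

test_that("sample aggregation follows firm-then-leaning rules", {
  cfg <- predictor_config()
  expect_equal(aggregate_samples(c(rep("escape", 8),
                                   rep("uninformative", 2)), cfg),
               "escape")
  expect_equal(aggregate_samples(c(rep("escape", 4), rep("subject", 4),
                                   rep("uninformative", 2)), cfg),
               "variable")
  expect_equal(aggregate_samples(c(rep("escape", 6), "leaning_escape",
                                   rep("uninformative", 3)), cfg),
               "leaning_escape")
})

test_that("k-means pairing matches females with same-cluster males", {
  # two well-separated blobs, each holding males
  auto <- rbind(
    matrix(rnorm(8, 0, 0.01), 4, 2),
    matrix(rnorm(8, 10, 0.01), 4, 2)
  )
  rownames(auto) <- c("f1", "f2", "m1", "m2", "f3", "f4", "m3", "m4")
  sex <- stats::setNames(rep(c("female", "female", "male", "male"), 2),
                         rownames(auto))
  p <- pair_female_male(auto, sex, k = 2L, seed = 5)
  expect_setequal(p$males[[which(p$sample_id == "f1")]], c("m1", "m2"))
  expect_setequal(p$males[[which(p$sample_id == "f3")]], c("m3", "m4"))
  expect_false(any(p$fallback))
  p2 <- pair_female_male(auto, sex, k = 2L, seed = 5)
  expect_identical(p, p2)   # seeded start
  expect_error(pair_female_male(auto[1:2, ], sex[1:2]), "no male")
})

test_that("training draws floor(0.75) escape genes and twice as many
           subject genes", {
  sf <- sep_features(n_escape = 46L, n_subject = 120L)
  ens <- train_ensemble(sf$features, sf$labels, fast_cfg())
  # 46 escape - 3 holdout = 43; floor(0.75*43) = 32; subject = 64
  expect_equal(ens$n_escape_draw, 32L)
  expect_equal(ens$n_subject_draw, 64L)
  expect_length(ens$models, 20L)
  expect_length(ens$holdout, 6L)
})

test_that("separable features give perfect per-model holdout accuracy", {
  sf <- sep_features(signal = 8)
  ens <- train_ensemble(sf$features, sf$labels, fast_cfg(seed = 2))
  expect_true(all(ens$accuracy$acc_escape == 1))
  expect_true(all(ens$accuracy$acc_subject == 1))
  pr <- predict_ensemble(ens, sf$features)
  expect_true(all(pr$status[sf$labels[pr$transcript_id] == "escape"] ==
                    "escape"))
})

test_that("label-shuffled features stay within the chance band", {
  sf <- sep_features(signal = 0, seed = 3)   # pure noise
  ens <- train_ensemble(sf$features, sf$labels, fast_cfg(seed = 3))
  # per-model escape accuracy is binomial around chance on the small
  # escape holdout; the mean across 20 models must be far from 1
  expect_lt(mean(ens$accuracy$acc_escape), 0.9)
  expect_gt(mean(ens$accuracy$acc_subject), 0.5) # majority class
})

test_that("training is deterministic and errors on deficient labels", {
  sf <- sep_features()
  e1 <- train_ensemble(sf$features, sf$labels, fast_cfg(seed = 7))
  e2 <- train_ensemble(sf$features, sf$labels, fast_cfg(seed = 7))
  expect_identical(predict_ensemble(e1, sf$features),
                   predict_ensemble(e2, sf$features))
  few <- sf$labels[c(which(sf$labels == "escape")[1:5],
                     which(sf$labels == "subject"))]
  expect_error(train_ensemble(sf$features, few, fast_cfg()),
               "too few labeled escape")
})

test_that("a perfectly predictive feature ranks 14", {
  sf <- sep_features(signal = 10)
  ens <- train_ensemble(sf$features, sf$labels, fast_cfg(seed = 4))
  imp <- feature_importance_ranks(ens)
  expect_equal(imp$feature[1], "f_1")
  expect_equal(imp$mean_rank[1], 14)
})

test_that("cross-sample application reproduces within-sample calls", {
  sf <- sep_features()
  ens <- train_ensemble(sf$features, sf$labels, fast_cfg(seed = 9))
  own <- predict_ensemble(ens, sf$features)
  cross <- cross_sample_apply(ens, sf$features, sf$labels)
  expect_identical(cross$calls, own)
  # inverted effects tank accuracy
  inv <- sf$features
  inv[, 1] <- -inv[, 1]
  bad <- cross_sample_apply(ens, inv, sf$labels)
  expect_lt(bad$acc_escape, cross$acc_escape)
})

test_that("the 2-SD simple classifier uses bands then the midpoint", {
  tr_v <- c(rnorm(50, 0, 1), rnorm(50, 10, 1))
  tr_l <- rep(c("escape", "subject"), each = 50)
  out <- simple_threshold_classifier(tr_v, tr_l, c(9.5, 0.2, 5))
  if (out$rule$kind == "bands") {
    expect_equal(out$calls[1:2], c("subject", "escape"))
    expect_true(is.na(out$calls[3]))   # mid-gap: no call
  }
  # overlapping bands: midpoint threshold
  ov <- simple_threshold_classifier(c(0, 2, 1, 3), c("a", "a", "b", "b"),
                                    c(0.9, 1.9, 1.5))
  expect_equal(ov$rule$kind, "midpoint")
  expect_equal(ov$rule$threshold, 1.5)
  expect_equal(ov$calls, c("a", "b", "a"))   # tie goes to the lower class
})

test_that("variable-gene counts are monotone in the sweep threshold", {
  set.seed(12)
  calls <- dplyr::bind_rows(lapply(1:40, function(g) {
    st <- sample(c("escape", "subject"), 10, replace = TRUE,
                 prob = c(runif(1), 1))
    tibble::tibble(id = paste0("g", g), status = st)
  }))
  sw <- variable_threshold_sweep(calls, c(0.05, 0.1, 0.25, 1 / 3, 0.51))
  expect_true(all(diff(sw$n_variable[order(sw$fraction)]) <= 0))
  expect_equal(sw$n_variable[sw$fraction == 0.51], 0L)  # pigeonhole
  even <- tibble::tibble(id = "g", status = rep(c("escape", "subject"), 5))
  expect_equal(variable_threshold_sweep(even, 0.5)$n_variable, 1L)
})
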