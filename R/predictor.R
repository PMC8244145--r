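# The ensemble XCI-status predictor: k-means pairing of female samples with
# male reference means, 20 bagged-tree models per sample trained on
# stratified draws of meta-labeled genes, vote-based per-sample calls,
# cross-sample aggregation, importance ranking, and the simple 2-SD
# threshold baseline.

#' Configuration for the ensemble predictor
#'
#' @param n_models Models per sample (20).
#' @param n_trees Trees per model (1500).
#' @param escape_train_frac Fraction of (post-holdout) escape genes drawn
#'   per model (0.75, floored).
#' @param subject_multiplier Subject genes drawn = multiplier x drawn escape
#'   count (2).
#' @param holdout_per_class Genes per class withheld globally before any
#'   draw (3).
#' @param vote_call_min Votes for a firm call (15 of 20).
#' @param vote_lean_min Lower edge of the leaning band (12; 12-14 votes
#'   lean).
#' @param agg_constitutive_frac Fraction of samples agreeing for a
#'   constitutive overall call (0.66).
#' @param agg_variable_frac Fraction of samples per status for a variable
#'   overall call (1/3).
#' @param k_clusters k for the autosomal k-means pairing (3).
#' @param tune_points mtry grid size (5 values evenly spaced over the
#'   feature count, chosen by out-of-bag AUC).
#' @param seed Seed for sampling and tree construction.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(n_models = 20L, n_trees = 1500L,
                             escape_train_frac = 0.75,
                             subject_multiplier = 2L,
                             holdout_per_class = 3L,
                             vote_call_min = 15L, vote_lean_min = 12L,
                             agg_constitutive_frac = 0.66,
                             agg_variable_frac = 1 / 3,
                             k_clusters = 3L, tune_points = 5L,
                             seed = 1L) {
  stopifnot(vote_lean_min < vote_call_min, vote_call_min <= n_models,
            escape_train_frac > 0, escape_train_frac < 1,
            agg_constitutive_frac > 0, agg_constitutive_frac < 1,
            agg_variable_frac > 0, agg_variable_frac < 1)
  structure(as.list(environment()), class = "predictor_config")
}

#' Pair each female sample with a male reference group
#'
#' k-means on standardized per-sample autosomal mark means; each female is
#' paired with the males sharing her cluster. A cluster without males falls
#' back to all males (flagged in `fallback`).
#'
#' @param autosomal Sample x mark matrix of autosomal mark means.
#' @param sex Named character vector sample_id -> female/male.
#' @param k Number of clusters (3).
#' @param seed Seed for the k-means start.
#' @return Tibble `sample_id` (females), `cluster`, `males` (list-column of
#'   male sample ids), `fallback`.
#' @export
pair_female_male <- function(autosomal, sex, k = 3L, seed = 1L) {
  sex <- sex[rownames(autosomal)]
  if (!any(sex == "male")) stop("no male samples to pair with")
  z <- scale(autosomal)
  z[, apply(autosomal, 2L, stats::sd) == 0] <- 0
  km <- with_seed_(seed, stats::kmeans(z, centers = min(k, nrow(z)),
                                       nstart = 10L))
  cl <- km$cluster
  females <- names(sex)[sex == "female"]
  males <- names(sex)[sex == "male"]
  out <- lapply(females, function(f) {
    same <- males[cl[males] == cl[f]]
    fb <- length(same) == 0L
    tibble::tibble(sample_id = f, cluster = cl[[f]],
                   males = list(if (fb) males else same), fallback = fb)
  })
  dplyr::bind_rows(out)
}

#' Build the 14-feature matrix for one female sample
#'
#' Seven marks for the female sample plus the mean of the same seven marks
#' over her paired male group. Missing values are imputed with the
#' sample-wide median of the feature and flagged.
#'
#' @param marks Long mark tibble (`transcript_id`, `sample_id`, `mark`,
#'   `value`).
#' @param female_id The female sample.
#' @param male_ids Her paired male group.
#' @return List: `features` (transcript x 14 matrix, columns `f_<mark>`,
#'   `m_<mark>`), `imputed` (logical matrix of the same shape).
#' @export
build_features <- function(marks, female_id, male_ids) {
  mk <- sort(unique(marks$mark))
  f <- marks[marks$sample_id == female_id, ]
  fw <- tapply(f$value, list(f$transcript_id, f$mark), mean)
  m <- marks[marks$sample_id %in% male_ids, ]
  mw <- tapply(m$value, list(m$transcript_id, m$mark), mean, na.rm = TRUE)
  tx <- sort(unique(rownames(fw)))
  x <- cbind(fw[tx, mk, drop = FALSE], mw[tx, mk, drop = FALSE])
  colnames(x) <- c(paste0("f_", mk), paste0("m_", mk))
  imput <- is.na(x)
  for (j in seq_len(ncol(x))) {
    if (any(imput[, j])) {
      x[imput[, j], j] <- stats::median(x[, j], na.rm = TRUE)
    }
  }
  list(features = x, imputed = imput)
}

# Mann-Whitney AUC of score for positive class.
auc_ <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

fit_rf_ <- function(x, y, cfg, seed) {
  p <- ncol(x)
  grid <- unique(round(seq(1, p, length.out = cfg$tune_points)))
  d <- data.frame(x, check.names = FALSE)
  d$.y <- factor(y, levels = c("escape", "subject"))
  fits <- lapply(grid, function(mt) {
    ranger::ranger(
      dependent.variable.name = ".y", data = d, num.trees = cfg$n_trees,
      mtry = mt, probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1L
    )
  })
  oob_auc <- vapply(fits, function(f) {
    auc_(f$predictions[, "escape"], d$.y == "escape")
  }, 0)
  fits[[which.max(oob_auc)]]
}

#' Train the 20-model ensemble for one sample
#'
#' A global holdout of `holdout_per_class` genes per class is removed first;
#' each model then draws (fresh, without replacement) `floor(0.75 x)` of the
#' remaining escape genes and twice that many subject genes, and fits a
#' bagged-tree classifier (1500 trees, mtry tuned over a 5-point grid by
#' out-of-bag AUC). Per-model accuracy is recorded on the labeled genes the
#' model did not draw.
#'
#' @param features Transcript x feature matrix ([build_features()]).
#' @param labels Named character vector transcript -> escape/subject (the
#'   meta-status training labels).
#' @param cfg A [predictor_config()].
#' @return An `xci_ensemble`: `models`, `holdout` (ids), `accuracy`
#'   (per-model escape/subject accuracy tibble), `labels`, `cfg`.
#' @export
train_ensemble <- function(features, labels, cfg = predictor_config()) {
  labels <- labels[labels %in% c("escape", "subject")]
  labels <- labels[names(labels) %in% rownames(features)]
  esc <- names(labels)[labels == "escape"]
  sub <- names(labels)[labels == "subject"]
  need <- cfg$holdout_per_class + 4L
  if (length(esc) < need) {
    stop("too few labeled escape genes: have ", length(esc),
         ", need at least ", need)
  }
  if (length(sub) < cfg$holdout_per_class + 4L) {
    stop("too few labeled subject genes: have ", length(sub))
  }
  with_seed_(cfg$seed, {
    holdout <- c(sample(esc, cfg$holdout_per_class),
                 sample(sub, cfg$holdout_per_class))
    esc_pool <- setdiff(esc, holdout)
    sub_pool <- setdiff(sub, holdout)
    n_esc_draw <- floor(cfg$escape_train_frac * length(esc_pool))
    n_sub_draw <- min(cfg$subject_multiplier * n_esc_draw,
                      length(sub_pool))
    models <- vector("list", cfg$n_models)
    acc <- vector("list", cfg$n_models)
    for (b in seq_len(cfg$n_models)) {
      tr <- c(sample(esc_pool, n_esc_draw), sample(sub_pool, n_sub_draw))
      fit <- fit_rf_(features[tr, , drop = FALSE], labels[tr], cfg,
                     seed = cfg$seed + b)
      rest <- setdiff(names(labels), tr)
      pr <- stats::predict(fit,
                           data.frame(features[rest, , drop = FALSE],
                                      check.names = FALSE))$predictions
      call <- ifelse(pr[, "escape"] >= 0.5, "escape", "subject")
      acc[[b]] <- tibble::tibble(
        model = b,
        acc_escape = mean(call[labels[rest] == "escape"] == "escape"),
        acc_subject = mean(call[labels[rest] == "subject"] == "subject")
      )
      models[[b]] <- fit
    }
    structure(list(models = models, holdout = holdout,
                   accuracy = dplyr::bind_rows(acc), labels = labels,
                   n_escape_draw = n_esc_draw, n_subject_draw = n_sub_draw,
                   feature_names = colnames(features), cfg = cfg),
              class = "xci_ensemble")
  })
}

#' Status from the number of escape votes
#'
#' 15+ of 20 on one side is a firm call; 12-14 on the larger side is a
#' leaning call; anything else is inconsistent (uninformative). Vectorized.
#'
#' @param votes_escape Integer escape votes (0..n_models).
#' @param cfg A [predictor_config()].
#' @return Character vector of statuses.
#' @export
vote_call <- function(votes_escape, cfg = predictor_config()) {
  vs <- cfg$n_models - votes_escape
  ifelse(votes_escape >= cfg$vote_call_min, "escape",
         ifelse(vs >= cfg$vote_call_min, "subject",
                ifelse(votes_escape >= cfg$vote_lean_min, "leaning_escape",
                       ifelse(vs >= cfg$vote_lean_min, "leaning_subject",
                              "uninformative"))))
}

#' Apply an ensemble to a feature matrix
#'
#' The identical vote machinery works within-sample or across samples
#' (foreign features from another sample or dataset).
#'
#' @param ensemble An `xci_ensemble`.
#' @param features Transcript x feature matrix with the ensemble's feature
#'   columns.
#' @return Tibble `transcript_id`, `votes_escape`, `status`.
#' @export
predict_ensemble <- function(ensemble, features) {
  stopifnot(identical(colnames(features), ensemble$feature_names))
  d <- data.frame(features, check.names = FALSE)
  votes <- rowSums(vapply(ensemble$models, function(m) {
    stats::predict(m, d)$predictions[, "escape"] >= 0.5
  }, logical(nrow(d))))
  tibble::tibble(transcript_id = rownames(features),
                 votes_escape = as.integer(votes),
                 status = vote_call(votes, ensemble$cfg))
}

#' Apply one sample's ensemble to another sample's features
#'
#' @param ensemble Ensemble trained on sample A.
#' @param features Feature matrix of sample B.
#' @param labels Optional named truth labels of B for accuracy evaluation.
#' @return List: `calls` (as [predict_ensemble()]), `acc_escape`,
#'   `acc_subject` (NA without labels).
#' @export
cross_sample_apply <- function(ensemble, features, labels = NULL) {
  calls <- predict_ensemble(ensemble, features)
  acc_e <- acc_s <- NA_real_
  if (!is.null(labels)) {
    st <- calls$status
    lb <- unname(labels[calls$transcript_id])
    firm <- st %in% c("escape", "subject") & lb %in% c("escape", "subject")
    acc_e <- mean(st[firm & lb == "escape"] == "escape")
    acc_s <- mean(st[firm & lb == "subject"] == "subject")
  }
  list(calls = calls, acc_escape = acc_e, acc_subject = acc_s)
}

#' Aggregate per-sample predictor statuses into an overall call
#'
#' Firm fractions are tested first over all samples with a vote result:
#' one status at `agg_constitutive_frac` or more is constitutive; both firm
#' statuses at `agg_variable_frac` or more is variable. Failing both, the
#' leaning votes join their side and the constitutive rule is retried,
#' yielding a leaning overall call; otherwise uninformative.
#'
#' @param statuses Character vector of per-sample statuses (escape, subject,
#'   leaning_escape, leaning_subject, uninformative).
#' @param cfg A [predictor_config()].
#' @return A single status string.
#' @export
aggregate_samples <- function(statuses, cfg = predictor_config()) {
  n <- length(statuses)
  if (n == 0L) return("uninformative")
  fe <- sum(statuses == "escape") / n
  fs <- sum(statuses == "subject") / n
  if (fe >= cfg$agg_constitutive_frac) return("escape")
  if (fs >= cfg$agg_constitutive_frac) return("subject")
  if (fe >= cfg$agg_variable_frac && fs >= cfg$agg_variable_frac) {
    return("variable")
  }
  fe2 <- fe + sum(statuses == "leaning_escape") / n
  fs2 <- fs + sum(statuses == "leaning_subject") / n
  if (fe2 >= cfg$agg_constitutive_frac) return("leaning_escape")
  if (fs2 >= cfg$agg_constitutive_frac) return("leaning_subject")
  "uninformative"
}

#' Aggregate a per-sample call table by transcript
#'
#' @param calls Tibble `id`, `sample_id`, `status`.
#' @param cfg A [predictor_config()].
#' @return Tibble `id`, `status` (overall).
#' @export
aggregate_call_table <- function(calls, cfg = predictor_config()) {
  sp <- split(calls$status, calls$id)
  tibble::tibble(id = names(sp),
                 status = vapply(sp, aggregate_samples, "", cfg = cfg))
}

#' Mean importance rank per feature across an ensemble
#'
#' Within each model the features are ranked by impurity importance, the
#' most important receiving the highest rank (14 for the full feature set)
#' and the least important rank 1; ties break by feature order. Ranks are
#' averaged across models.
#'
#' @param ensemble An `xci_ensemble` (or list of them, pooled).
#' @return Tibble `feature`, `mean_rank`, sorted descending.
#' @export
feature_importance_ranks <- function(ensemble) {
  ensembles <- if (inherits(ensemble, "xci_ensemble")) list(ensemble)
  else ensemble
  ranks <- lapply(ensembles, function(e) {
    vapply(e$models, function(m) {
      imp <- ranger::importance(m)[e$feature_names]
      rank(imp, ties.method = "first")
    }, numeric(length(e$feature_names)))
  })
  all_r <- do.call(cbind, ranks)
  mr <- unname(rowMeans(all_r))
  tibble::tibble(feature = rownames(all_r), mean_rank = mr)[order(-mr), ]
}

#' Simple two-standard-deviation threshold classifier
#'
#' Class bands are mean +/- 2 SD of the training values per class. When the
#' bands overlap, the midpoint of the class means becomes a single
#' threshold (sides by class-mean order; a value exactly at the midpoint
#' goes to the lower-mean class). When they do not overlap, values inside
#' exactly one band take that class and values in neither get no call.
#'
#' @param train_values Numeric training values.
#' @param train_labels Two-class character labels aligned with
#'   `train_values`.
#' @param values Values to classify.
#' @return List: `rule` (list describing bands/threshold), `calls`
#'   (character vector, NA = no call).
#' @export
simple_threshold_classifier <- function(train_values, train_labels,
                                        values) {
  cls <- sort(unique(train_labels))
  stopifnot(length(cls) == 2L)
  m <- vapply(cls, function(c) mean(train_values[train_labels == c]), 0)
  s <- vapply(cls, function(c) stats::sd(train_values[train_labels == c]),
              0)
  s[is.na(s)] <- 0   # single-observation class: degenerate band
  lo <- m - 2 * s; hi <- m + 2 * s
  overlap <- max(lo) <= min(hi)
  low_class <- cls[which.min(m)]; high_class <- cls[which.max(m)]
  if (overlap) {
    thr <- mean(m)
    calls <- ifelse(values <= thr, low_class, high_class)
    rule <- list(kind = "midpoint", threshold = thr,
                 low_class = low_class, high_class = high_class)
  } else {
    calls <- rep(NA_character_, length(values))
    for (c in cls) {
      inside <- values >= lo[c] & values <= hi[c]
      calls[inside] <- c
    }
    rule <- list(kind = "bands", lower = lo, upper = hi)
  }
  list(rule = rule, calls = calls)
}

#' Variable-gene counts over a sweep of variable-escape thresholds
#'
#' Re-runs the variable rule (both firm statuses at >= the fraction) at each
#' threshold; counts are monotone non-increasing in the fraction.
#'
#' @param calls Per-sample call table (`id`, `status`).
#' @param fractions Thresholds to sweep (default `c(1/3, .25, .10, .05)`).
#' @return Tibble `fraction`, `n_variable`.
#' @export
variable_threshold_sweep <- function(calls,
                                     fractions = c(1 / 3, 0.25, 0.10,
                                                   0.05)) {
  sp <- split(calls$status, calls$id)
  n_var <- vapply(fractions, function(f) {
    sum(vapply(sp, function(st) {
      n <- length(st)
      sum(st == "escape") / n >= f && sum(st == "subject") / n >= f
    }, TRUE))
  }, 0L)
  tibble::tibble(fraction = fractions, n_variable = as.integer(n_var))
}
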