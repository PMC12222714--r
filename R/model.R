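# Co-complex interaction classifier. The backend is pluggable behind a
# minimal fit / predict-score / save / load contract; the default is
# ridge-regularized logistic regression (glmnet). Features arrive as a pair
# table (id_a, id_b, numeric columns); missingness is explicit and imputed as
# zero with companion observed-indicator columns, since absence of evidence
# is itself informative in pulldown-derived features.

feature_columns <- function(features) {
  setdiff(names(features), c("id_a", "id_b", "label"))
}

#' Zero-fill missing features, adding observed-indicator columns
#'
#' @param features Pair feature table with possible `NA`s.
#' @param add_indicators Add an `obs_<column>` 0/1 column per feature column.
#' @return Feature table with no non-finite values.
#' @export
impute_missing <- function(features, add_indicators = TRUE) {
  cols <- feature_columns(features)
  for (cl in cols) {
    v <- features[[cl]]
    miss <- !is.finite(v)
    if (add_indicators) features[[paste0("obs_", cl)]] <- as.numeric(!miss)
    v[miss] <- 0
    features[[cl]] <- v
  }
  features
}

#' Assemble a labeled training table
#'
#' Keeps every positive gold pair and subsamples at most `n_negatives`
#' negative pairs without replacement (the published negative-balancing
#' rule). Gold pairs absent from the feature table get all-missing rows,
#' which imputation turns into zeros plus observed = 0 indicators.
#'
#' @param features Pair feature table.
#' @param gold A list with `positives` and `negatives` pair data frames (one
#'   side of a [split_benchmark()] result).
#' @param n_negatives Negative subsample size.
#' @param seed Integer seed for the subsample.
#' @return Labeled, imputed feature table with a `label` column.
#' @export
assemble_training <- function(features, gold, n_negatives = 10000L, seed = 1L) {
  assert_that(nrow(gold$positives) > 0L, "no positive pairs in gold standard")
  neg <- gold$negatives
  with_seed(seed, {
    if (nrow(neg) > n_negatives) {
      neg <- neg[sample.int(nrow(neg), n_negatives), , drop = FALSE]
    } else if (nrow(neg) < n_negatives) {
      warning(sprintf("only %d negatives available (requested %d); using all",
                      nrow(neg), n_negatives), call. = FALSE)
    }
    lab <- rbind(data.frame(gold$positives[c("id_a", "id_b")], label = 1),
                 data.frame(neg[c("id_a", "id_b")], label = 0))
    out <- merge(lab, features, by = c("id_a", "id_b"), all.x = TRUE, sort = TRUE)
    out <- out[order(out$id_a, out$id_b), , drop = FALSE]
    rownames(out) <- NULL
    impute_missing(out)
  })
}

#' Train a co-complex classifier
#'
#' @param labeled Labeled feature table from [assemble_training()].
#' @param backend `"glmnet"` (ridge logistic regression, default) or `"glm"`
#'   (unpenalized logistic regression).
#' @param seed Integer seed (recorded; both backends are deterministic).
#' @param lambda Ridge penalty for the glmnet backend.
#' @return A `cf_model`: frozen fit plus the feature-name schema it will
#'   enforce at prediction time.
#' @export
train_classifier <- function(labeled, backend = c("glmnet", "glm"), seed = 1L,
                             lambda = 1e-3) {
  backend <- match.arg(backend)
  assert_that("label" %in% names(labeled), "`labeled` needs a label column")
  y <- labeled$label
  assert_that(length(unique(y)) >= 2L,
              "training data must contain both classes")
  cols <- feature_columns(labeled)
  assert_that(length(cols) >= 1L, "no feature columns")
  x <- as.matrix(labeled[cols])
  assert_that(all(is.finite(x)), "non-finite feature values; impute first")
  fit <- with_seed(seed, {
    if (backend == "glmnet") {
      # a full decreasing path keeps the coordinate descent warm-started;
      # jumping straight to a small ridge penalty can stall on separable data
      path <- exp(seq(log(10), log(lambda), length.out = 40))
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = path, standardize = TRUE, maxit = 1e6)
    } else {
      df <- as.data.frame(x)
      df$.label <- y
      suppressWarnings(stats::glm(.label ~ ., data = df, family = stats::binomial()))
    }
  })
  structure(list(backend = backend, fit = fit, feature_names = cols,
                 lambda = lambda, seed = seed),
            class = "cf_model")
}

#' @export
print.cf_model <- function(x, ...) {
  cat(sprintf("<cf_model> backend=%s, %d features\n",
              x$backend, length(x$feature_names)))
  invisible(x)
}

check_schema <- function(model, features) {
  cols <- feature_columns(features)
  missing <- setdiff(model$feature_names, cols)
  extra <- setdiff(cols, model$feature_names)
  if (length(missing) > 0L || length(extra) > 0L)
    stop(sprintf("feature schema mismatch; missing: [%s], extra: [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

predict_scores <- function(model, features) {
  x <- as.matrix(features[model$feature_names])
  s <- if (model$backend == "glmnet") {
    as.numeric(predict(model$fit, newx = x, s = model$lambda, type = "response"))
  } else {
    as.numeric(predict(model$fit, newdata = as.data.frame(x), type = "response"))
  }
  pmin(1, pmax(0, s))
}

#' Score all pairs of a feature table
#'
#' Streams over chunks so memory stays bounded on large pair tables.
#'
#' @param model A `cf_model`.
#' @param features Imputed pair feature table.
#' @param chunk_size Rows scored per chunk.
#' @return Scored network data frame `id_a`, `id_b`, `score`.
#' @export
score_all_pairs <- function(model, features, chunk_size = 200000L) {
  check_schema(model, features)
  n <- nrow(features)
  starts <- seq.int(1L, n, by = chunk_size)
  score <- numeric(n)
  for (st in starts) {
    en <- min(st + chunk_size - 1L, n)
    score[st:en] <- predict_scores(model, features[st:en, , drop = FALSE])
  }
  data.frame(id_a = features$id_a, id_b = features$id_b, score = score,
             stringsAsFactors = FALSE)
}

#' Save / load a frozen model
#'
#' The model directory holds the fitted backend object plus a JSON sidecar
#' with the feature-name schema and backend identity.
#'
#' @param model A `cf_model`.
#' @param dir Model directory.
#' @return `dir` / the reloaded `cf_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$fit, file.path(dir, "fit.rds"))
  jsonlite::write_json(list(backend = model$backend,
                            feature_names = model$feature_names,
                            lambda = model$lambda, seed = model$seed),
                       file.path(dir, "schema.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "schema.json"), simplifyVector = TRUE)
  structure(list(backend = meta$backend, fit = readRDS(file.path(dir, "fit.rds")),
                 feature_names = meta$feature_names, lambda = meta$lambda,
                 seed = meta$seed),
            class = "cf_model")
}

truth_labels_for <- function(scores, truth) {
  keys <- pair_key(scores$id_a, scores$id_b)
  pos <- if (nrow(truth$positives)) pair_key(truth$positives$id_a, truth$positives$id_b) else character(0)
  neg <- if (nrow(truth$negatives)) pair_key(truth$negatives$id_a, truth$negatives$id_b) else character(0)
  # unscored truth pairs enter at score 0: the classifier saw no evidence
  unscored_pos <- setdiff(pos, keys)
  unscored_neg <- setdiff(neg, keys)
  lab <- rep(NA_real_, length(keys))
  lab[keys %in% pos] <- 1
  lab[keys %in% neg] <- 0
  df <- data.frame(score = scores$score, label = lab)
  df <- df[!is.na(df$label), , drop = FALSE]
  if (length(unscored_pos) + length(unscored_neg) > 0L) {
    df <- rbind(df, data.frame(
      score = 0,
      label = c(rep(1, length(unscored_pos)), rep(0, length(unscored_neg)))))
  }
  attr(df, "n_unscored") <- length(unscored_pos) + length(unscored_neg)
  df
}

# Average-precision style step integration over distinct descending
# thresholds: AUPRC = sum over recall increments of the precision at that
# threshold.
pr_points <- function(score, label) {
  ord <- order(-score)
  score <- score[ord]; label <- label[ord]
  P <- sum(label == 1)
  assert_that(P > 0, "no positive pairs to evaluate")
  grp_last <- which(c(score[-1] != score[-length(score)], TRUE))
  tp <- cumsum(label == 1)[grp_last]
  fp <- cumsum(label == 0)[grp_last]
  precision <- tp / (tp + fp)
  recall <- tp / P
  auprc <- sum(diff(c(0, recall)) * precision)
  list(df = data.frame(threshold = score[grp_last], precision = precision,
                       recall = recall),
       auprc = auprc)
}

#' Precision-recall curve against a labeled gold standard
#'
#' Truth pairs absent from the scored set are assigned score 0 (and counted
#' in the `n_unscored` attribute); scored pairs outside the gold standard are
#' ignored.
#'
#' @param scores Scored network data frame (`id_a`, `id_b`, `score`).
#' @param truth A list with `positives` / `negatives` pair data frames.
#' @return A `pr_curve`: data frame of (threshold, precision, recall) ordered
#'   by descending threshold, with an `auprc` attribute.
#' @export
precision_recall <- function(scores, truth) {
  df <- truth_labels_for(scores, truth)
  pts <- pr_points(df$score, df$label)
  structure(pts$df, auprc = pts$auprc, n_unscored = attr(df, "n_unscored"),
            class = c("pr_curve", "data.frame"))
}

#' @rdname precision_recall
#' @param x A `pr_curve`.
#' @export
auprc <- function(x) attr(x, "auprc")

#' Empirical precision per score bin
#'
#' Used as a calibration check: a well-calibrated classifier's per-bin
#' precision tracks the bin midpoints.
#'
#' @param scores Scored network data frame.
#' @param truth Labeled pairs.
#' @param bins Bin edges over [0, 1].
#' @return Data frame with bin edges, midpoint, pair count, positive count
#'   and empirical precision (`NA` precision with `empty = TRUE` for bins
#'   holding no labeled pair).
#' @export
score_vs_precision_table <- function(scores, truth, bins = seq(0, 1, by = 0.1)) {
  df <- truth_labels_for(scores, truth)
  cut_idx <- findInterval(df$score, bins, rightmost.closed = TRUE,
                          all.inside = TRUE)
  nb <- length(bins) - 1L
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1L])
  out$midpoint <- (out$bin_lo + out$bin_hi) / 2
  out$n <- vapply(seq_len(nb), function(b) sum(cut_idx == b), 0L)
  out$n_pos <- vapply(seq_len(nb), function(b) sum(df$label[cut_idx == b] == 1), 0L)
  out$precision <- ifelse(out$n > 0L, out$n_pos / out$n, NA_real_)
  out$empty <- out$n == 0L
  out
}

eval_metric <- function(score, label, metric) {
  if (metric == "accuracy") mean((score >= 0.5) == (label == 1))
  else pr_points(score, label)$auprc
}

#' Permutation feature importance
#'
#' Shuffles each feature column individually and reports the mean drop in
#' model performance on the labeled evaluation pairs; negative values mean
#' the shuffle improved performance.
#'
#' @param model A `cf_model`.
#' @param features Imputed pair feature table covering the truth pairs.
#' @param truth Labeled pairs (`positives` / `negatives`).
#' @param n_repeats Shuffles per feature.
#' @param seed Integer seed.
#' @param metric `"accuracy"` (default, thresholded at 0.5) or `"auprc"`.
#' @return Data frame `feature`, `importance`, `sd`.
#' @export
permutation_importance <- function(model, features, truth, n_repeats = 5L,
                                   seed = 1L, metric = c("accuracy", "auprc")) {
  metric <- match.arg(metric)
  check_schema(model, features)
  keys <- pair_key(features$id_a, features$id_b)
  pos <- pair_key(truth$positives$id_a, truth$positives$id_b)
  neg <- pair_key(truth$negatives$id_a, truth$negatives$id_b)
  keep <- keys %in% c(pos, neg)
  eval_tab <- features[keep, , drop = FALSE]
  label <- as.numeric(keys[keep] %in% pos)
  base <- eval_metric(predict_scores(model, eval_tab), label, metric)
  with_seed(seed, {
    res <- lapply(model$feature_names, function(cl) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        perm <- eval_tab
        perm[[cl]] <- perm[[cl]][sample.int(nrow(perm))]
        base - eval_metric(predict_scores(model, perm), label, metric)
      }, 0)
      c(mean(drops), stats::sd(drops))
    })
    data.frame(feature = model$feature_names,
               importance = vapply(res, `[`, 0, 1L),
               sd = vapply(res, `[`, 0, 2L),
               stringsAsFactors = FALSE)
  })
}

#' Zero out named feature groups (ablation)
#'
#' @param features Pair feature table.
#' @param groups Named list of column-name vectors to zero.
#' @return The feature table with every listed column set to zero.
#' @export
ablate_feature_groups <- function(features, groups) {
  cols <- unique(unlist(groups))
  unknown <- setdiff(cols, names(features))
  assert_that(length(unknown) == 0L,
              sprintf("unknown feature columns: %s", paste(unknown, collapse = ", ")))
  for (cl in cols) features[[cl]] <- 0
  features
}
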