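#' Random train/test split of a screening cohort
#'
#' Partitions the cohort into training and testing sets at the given
#' fraction (default 7:3, the protocol under which the published models were
#' built and evaluated). By default the split is stratified by AIS label, so
#' both parts keep the cohort's case fraction: each group contributes
#' `round(fraction * n_group)` records to the training set. The split is a
#' deterministic function of the seed.
#'
#' @param records a screening cohort
#' @param train_fraction fraction of records assigned to training, in (0, 1)
#' @param seed integer seed for the partition
#' @param stratify stratify the split by AIS label (default `TRUE`)
#' @return a list with components `train` and `test` (data.frames), plus
#'   attribute `"seed"`
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' parts <- split_cohort(cohort, seed = 7)
#' vapply(parts, nrow, integer(1))  # 1245, 534
#' @export
split_cohort <- function(records, train_fraction = 0.7, seed = NULL,
                         stratify = TRUE) {
  if (nrow(records) < 2) stop("need at least 2 records to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly inside (0, 1)", call. = FALSE)
  }
  idx <- with_seed(seed, {
    if (stratify) {
      unlist(lapply(split(seq_len(nrow(records)), records$ais), function(i) {
        sample(i, round(train_fraction * length(i)))
      }), use.names = FALSE)
    } else {
      sample(seq_len(nrow(records)), round(train_fraction * nrow(records)))
    }
  })
  out <- list(train = records[sort(idx), , drop = FALSE],
              test = records[-sort(idx), , drop = FALSE])
  attr(out, "seed") <- seed
  out
}

#' Confusion-matrix metrics of a binary screening classifier
#'
#' Exact counts and derived rates from true and predicted 0/1 labels:
#' sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, positive
#' and negative predictive values `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`,
#' total accuracy `Ac = (TP+TN)/N`, and Youden's index `YI = Se + Sp - 1`.
#' Rates are kept on the proportion scale; the print method formats them as
#' percentages with two decimals. A rate whose denominator is zero is
#' reported as `NA`, not 0.
#'
#' @param true_labels,predicted_labels equal-length vectors over \{0, 1\}
#' @return an object of class `confusion_metrics`: list with `tp`, `fp`,
#'   `tn`, `fn`, `se`, `sp`, `ppv`, `npv`, `ac`, `yi`
#' @examples
#' m <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' m$se  # 0.5
#' @export
confusion_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (!all(true_labels %in% c(0, 1)) || !all(predicted_labels %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  tp <- sum(true_labels == 1 & predicted_labels == 1)
  fp <- sum(true_labels == 0 & predicted_labels == 1)
  tn <- sum(true_labels == 0 & predicted_labels == 0)
  fn <- sum(true_labels == 1 & predicted_labels == 0)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- rate(tp, tp + fn)
  sp <- rate(tn, tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 se = se, sp = sp,
                 ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
                 ac = rate(tp + tn, tp + fp + tn + fn),
                 yi = se + sp - 1),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat("<confusion_metrics>",
      sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  Se=%s Sp=%s YI=%.2f PPV=%s NPV=%s Ac=%s\n",
              pct(x$se), pct(x$sp), x$yi, pct(x$ppv), pct(x$npv), pct(x$ac)))
  invisible(x)
}

#' Train, weight and evaluate the four prediction models
#'
#' Runs the full evaluation protocol on one cohort: stratified
#' `train_fraction` split; plain multivariate logistic fit on the training
#' part; AOR-, AUC- and AOR+AUC-weighted variants derived from the training
#' part (weights from [aor_weights()] / [auc_weights()] computed on the
#' training data, or the published values with `weights = "printed"`);
#' classification of the test part at `threshold`; and the confusion-matrix
#' battery per scheme.
#'
#' @param records a screening cohort containing both outcome classes
#' @param schemes subset of
#'   `c("plain", "aor_weighted", "auc_weighted", "aor_auc_weighted")`
#' @param seed integer seed for the split
#' @param train_fraction training fraction (default 0.7)
#' @param threshold classification threshold (default 0.5)
#' @param encoding covariate encoding for the fit (default `"single_score"`,
#'   the published equations' encoding)
#' @param weights `"data"` (derive weights from the training split) or
#'   `"printed"` (use the published AOR/AUC values)
#' @return a list with `metrics` (named list of [confusion_metrics()] per
#'   scheme), `models` (named list of [prediction_model]s), and `meta`
#'   (seed, split sizes, threshold)
#' @export
evaluate_models <- function(records,
                            schemes = c("plain", "aor_weighted", "auc_weighted",
                                        "aor_auc_weighted"),
                            seed = NULL, train_fraction = 0.7, threshold = 0.5,
                            encoding = "single_score",
                            weights = c("data", "printed")) {
  weights <- match.arg(weights)
  schemes <- match.arg(schemes, several.ok = TRUE)
  records <- validate_cohort(records)
  if (length(unique(records$ais)) < 2) {
    stop("cohort must contain both outcome classes", call. = FALSE)
  }
  parts <- split_cohort(records, train_fraction, seed = seed)
  base <- fit_multivariate(parts$train, encoding = encoding, drop_constant = TRUE)
  w_aor <- switch(weights, data = aor_weights(base), printed = printed_aor_weights())
  w_auc <- switch(weights, data = auc_weights(parts$train),
                  printed = printed_auc_weights())
  models <- list()
  for (s in schemes) {
    models[[s]] <- switch(s,
      plain = base,
      aor_weighted = apply_weighting(base, w_aor, "aor_weighted"),
      auc_weighted = apply_weighting(base, w_auc, "auc_weighted"),
      aor_auc_weighted = apply_weighting(base, combine_weights(w_aor, w_auc),
                                         "aor_auc_weighted")
    )
  }
  truth <- as.integer(parts$test$ais)
  metrics <- lapply(models, function(m) {
    confusion_metrics(truth, classify(predict_probability(m, parts$test),
                                      threshold))
  })
  list(metrics = metrics, models = models,
       meta = list(seed = seed, n_train = nrow(parts$train),
                   n_test = nrow(parts$test), threshold = threshold,
                   train_fraction = train_fraction, weights = weights))
}

#' Tabular evaluation report
#'
#' Flattens the output of [evaluate_models()] into the conventional report
#' layout: one row per metric (Se, Sp, YI, PPV, NPV, Ac), one column per
#' scheme, rates as percentages with two decimals (Youden's index on its
#' natural -1..1 scale).
#'
#' @param evaluation result of [evaluate_models()]
#' @return a `data.frame` with an `indicator` column and one column per scheme
#' @export
evaluation_report <- function(evaluation) {
  metric_rows <- c(se = "Se", sp = "Sp", yi = "YI", ppv = "PPV",
                   npv = "NPV", ac = "Ac")
  out <- data.frame(indicator = unname(metric_rows))
  for (s in names(evaluation$metrics)) {
    m <- evaluation$metrics[[s]]
    vals <- vapply(names(metric_rows), function(k) {
      v <- m[[k]]
      if (k == "yi") round(v, 2) else round(100 * v, 2)
    }, numeric(1))
    out[[s]] <- vals
  }
  out
}
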