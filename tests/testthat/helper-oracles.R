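# Independent oracles and small fixtures used across the suite.

# Brute-force AUC: expand a contingency table to per-subject scores and
# enumerate every case-control pair (ties count one half). Deliberately
# naive; the closed-form implementation must agree with it.
brute_force_auc <- function(table, score_map = NULL) {
  if (is.null(score_map)) {
    score_map <- stats::setNames(c(0, rep(1, length(table$levels) - 1)),
                                 table$levels)
  }
  s <- score_map[table$levels]
  control <- rep(s, table$counts[, "control"])
  case <- rep(s, table$counts[, "case"])
  cmp <- outer(case, control, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(case) * length(control))
}

# Two-proportion z statistic (pooled), the classical oracle whose square is
# the Pearson chi-square of the corresponding 2x2 table.
two_prop_z <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  (x1 / n1 - x2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

# Bernoulli log-likelihood of a prediction model on records.
model_loglik <- function(model, records) {
  p <- predict_probability(model, records)
  y <- records$ais
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# A small deterministic cohort in which every categorical level occurs.
tiny_cohort <- function(n = 60, seed = 424242) {
  generate_cohort(default_cohort_spec(), seed = seed)[seq_len(n) * 25, ]
}

# A cohort data.frame built directly (no simulator) with given columns,
# all unspecified signs held at their reference level.
manual_cohort <- function(n, ais, seed = 1, ...) {
  base <- list(
    gender = rep("boy", n), age = rep(12, n), school = rep("junior", n),
    shoulder_height_diff = rep("normal", n), scapular_tilt = rep("normal", n),
    lumbar_concave = rep("normal", n), pelvic_tilt = rep("normal", n),
    flat_back = rep("normal", n), thoracic_kyphosis = rep("normal", n),
    lumbar_kyphosis = rep("normal", n),
    atr_thoracic = rep("normal_0_5", n), atr_thoracolumbar = rep("normal_0_5", n),
    atr_lumbar = rep("normal_0_5", n)
  )
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base$ais <- ais
  do.call(data.frame, base)
}
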