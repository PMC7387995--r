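#' Empirical rank AUC for a grouped categorical predictor
#'
#' The area under the ROC curve of a categorical predictor equals the
#' probability that a randomly chosen case scores higher than a randomly
#' chosen control, counting ties one half:
#' `AUC = (#\{case > control\} + 0.5 * #ties) / (n_case * n_control)`.
#' For a predictor given as level counts this is computed in closed form
#' from the contingency table, without expanding records or enumerating
#' pairs, and is invariant to any strictly increasing transform of the level
#' scores. The default scoring collapses to binary — reference ("normal")
#' level 0, any abnormal level 1 — which is how single postural signs are
#' screened; `score_map` can assign any real score per level (e.g. ordinal
#' 0/1/2). The confidence interval is Hanley-McNeil (see [auc_ci()]) and the
#' p-value tests AUC = 0.5 by the normal approximation
#' `z = (AUC - 0.5) / SE`.
#'
#' @param table a [contingency_table()]
#' @param score_map optional named numeric vector assigning a score to every
#'   level; default: 0 for the first (reference) level, 1 for all others
#' @return an object of class `auc_result`: list with `variable`, `auc`,
#'   `ci_low`, `ci_high`, `p_value`, `method = "empirical_rank"`
#' @examples
#' empirical_auc(table1_tables()$shoulder_height_diff)  # 0.70
#' @export
empirical_auc <- function(table, score_map = NULL) {
  stopifnot(inherits(table, "contingency_table"))
  if (is.null(score_map)) {
    score_map <- stats::setNames(c(0, rep(1, length(table$levels) - 1)),
                                 table$levels)
  }
  if (!all(table$levels %in% names(score_map))) {
    stop("score_map must cover every level of the table", call. = FALSE)
  }
  scores <- score_map[table$levels]
  n_control <- sum(table$counts[, "control"])
  n_case <- sum(table$counts[, "case"])
  if (n_control == 0 || n_case == 0) stop("empty group", call. = FALSE)
  ord <- order(scores)
  ctrl <- table$counts[ord, "control"]
  case <- table$counts[ord, "case"]
  s <- scores[ord]
  # collapse tied scores into single strata
  strata <- match(s, unique(s))
  ctrl <- as.numeric(tapply(ctrl, strata, sum))
  case <- as.numeric(tapply(case, strata, sum))
  ctrl_below <- cumsum(c(0, utils::head(ctrl, -1)))
  wins <- sum(case * ctrl_below)   # case strictly above control
  ties <- sum(case * ctrl)         # same stratum
  auc <- (wins + 0.5 * ties) / (as.numeric(n_case) * n_control)
  .auc_result(table$variable, auc, n_case, n_control, "empirical_rank")
}

.auc_result <- function(variable, auc, n_case, n_control, method) {
  if (auc <= 0 || auc >= 1) {
    warning("degenerate AUC of ", auc, ": returning a point interval",
            call. = FALSE)
    ci <- c(auc, auc)
    p <- 0
  } else {
    ci <- auc_ci(auc, n_case, n_control)
    se <- attr(ci, "se")
    p <- 2 * stats::pnorm(-abs((auc - 0.5) / se))
  }
  structure(list(variable = variable, auc = auc, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, n_case = n_case, n_control = n_control,
                 method = method),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> %s (%s): AUC = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$variable, x$method, x$auc, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Binormal AUC for a continuous predictor
#'
#' Closed-form AUC under within-group normality:
#' `AUC = pnorm((mean_case - mean_control) / sqrt(sd_case^2 + sd_control^2))`.
#' Used for age, whose published summaries are within-group means and SDs.
#'
#' @param mean_case,sd_case,mean_control,sd_control group summary statistics
#'   (both SDs must be positive)
#' @param n_case,n_control optional group sizes; if given, a Hanley-McNeil
#'   confidence interval and AUC = 0.5 test are attached
#' @return an `auc_result` with `method = "binormal"`
#' @examples
#' binormal_auc(13.14, 1.87, 12.67, 1.96, 884, 895)  # 0.57
#' @export
binormal_auc <- function(mean_case, sd_case, mean_control, sd_control,
                         n_case = NULL, n_control = NULL) {
  if (sd_case <= 0 || sd_control <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  auc <- unname(stats::pnorm((mean_case - mean_control) /
                               sqrt(sd_case^2 + sd_control^2)))
  if (is.null(n_case) || is.null(n_control)) {
    return(structure(list(variable = "age", auc = auc, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          n_case = NA, n_control = NA, method = "binormal"),
                     class = "auc_result"))
  }
  .auc_result("age", auc, n_case, n_control, "binormal")
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' The Hanley-McNeil (1982) variance of an estimated AUC `A` from `n_case`
#' cases and `n_control` controls uses `Q1 = A / (2 - A)` and
#' `Q2 = 2 A^2 / (1 + A)`:
#' `SE^2 = (A(1-A) + (n_case-1)(Q1-A^2) + (n_control-1)(Q2-A^2)) /
#' (n_case * n_control)`. The 95% interval is `A +/- 1.96 SE`, clipped to
#' \[0, 1\].
#'
#' @param auc estimated AUC, strictly inside (0, 1)
#' @param n_case,n_control positive group sizes
#' @return `c(low, high)`, with the standard error attached as attribute
#'   `"se"`
#' @export
auc_ci <- function(auc, n_case, n_control) {
  if (n_case <= 0 || n_control <= 0) stop("group sizes must be positive", call. = FALSE)
  if (auc <= 0 || auc >= 1) {
    warning("degenerate AUC: returning a point interval", call. = FALSE)
    return(structure(c(auc, auc), se = 0))
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
                (n_control - 1) * (q2 - auc^2)) / (n_case * n_control))
  structure(c(max(0, auc - .z975 * se), min(1, auc + .z975 * se)), se = se)
}

#' Per-variable discrimination report
#'
#' AUC with 95% CI and AUC = 0.5 test for every model covariate of a
#' screening cohort: empirical rank AUC (binary collapse by default) for the
#' categorical signs, binormal AUC for age.
#'
#' @param records a screening cohort with `ais` labels
#' @param ordinal score three-level signs 0/1/2 instead of collapsing to
#'   binary
#' @return a `data.frame` with columns `variable`, `auc`, `ci_low`,
#'   `ci_high`, `p_value`, `method`
#' @export
roc_report <- function(records, ordinal = FALSE) {
  records <- validate_cohort(records)
  rows <- lapply(ais_covariates(), function(v) {
    if (v == "age") {
      ctrl <- records$age[records$ais == 0]
      case <- records$age[records$ais == 1]
      r <- binormal_auc(mean(case), stats::sd(case), mean(ctrl), stats::sd(ctrl),
                        n_case = length(case), n_control = length(ctrl))
    } else {
      tab <- tabulate_by_status(records, v)
      sm <- if (ordinal) {
        stats::setNames(seq_along(tab$levels) - 1, tab$levels)
      } else NULL
      r <- empirical_auc(tab, score_map = sm)
    }
    data.frame(variable = v, auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value, method = r$method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
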