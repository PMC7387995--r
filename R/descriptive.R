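#' Contingency table of one screening variable by AIS status
#'
#' @param variable variable name
#' @param levels ordered level labels (first = reference)
#' @param control,case non-negative integer count vectors, one entry per level
#' @return an object of class `contingency_table`: a list with `variable`,
#'   `levels`, and a `levels x 2` `counts` matrix with columns
#'   `control`, `case`
#' @seealso [tabulate_by_status()] to build one from records,
#'   [table1_tables()] for the packaged published tables
#' @export
contingency_table <- function(variable, levels, control, case) {
  if (length(levels) < 2) stop("need at least 2 levels", call. = FALSE)
  if (length(control) != length(levels) || length(case) != length(levels)) {
    stop("counts must have one entry per level", call. = FALSE)
  }
  counts <- cbind(control = as.integer(control), case = as.integer(case))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rownames(counts) <- levels
  structure(list(variable = variable, levels = levels, counts = counts),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>", x$variable, "\n")
  print(x$counts)
  invisible(x)
}

#' Tabulate a screening variable by AIS status
#'
#' Cross-tabulates one categorical screening variable against the AIS label,
#' preserving the variable's canonical level order. The table conserves the
#' record count: its cell sum equals `nrow(records)`.
#'
#' @param records a screening cohort (see [ais_variables()])
#' @param variable name of a categorical screening variable
#' @return a [contingency_table()]
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' tabulate_by_status(cohort, "scapular_tilt")
#' @export
tabulate_by_status <- function(records, variable) {
  lv <- ais_levels(variable)
  if (nrow(records) == 0) {
    return(contingency_table(variable, lv, rep(0L, length(lv)), rep(0L, length(lv))))
  }
  records <- validate_cohort(records)
  tab <- table(factor(records[[variable]], levels = lv),
               factor(records$ais, levels = c(0, 1)))
  contingency_table(variable, lv, tab[, 1], tab[, 2])
}

#' Chi-square test of independence for a screening table
#'
#' Pearson chi-square test between a categorical variable and AIS status,
#' with an optional Yates continuity correction for 2x2 tables (used where
#' published tables flag it, i.e. for sparse binary signs such as lumbar
#' kyphosis).
#'
#' @param table a [contingency_table()]
#' @param continuity apply the Yates continuity correction (2x2 tables only)
#' @return an object of class `assoc_test`: list with `statistic`, `df`,
#'   `p_value`, `method`
#' @examples
#' chi_square(table1_tables()$gender)  # 146.84
#' @export
chi_square <- function(table, continuity = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  counts <- table$counts
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("chi-square statistic undefined: a margin of the table is empty",
         call. = FALSE)
  }
  if (continuity && nrow(counts) != 2) {
    stop("continuity correction is only defined for 2x2 tables", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = continuity))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 method = if (continuity) "chi2_continuity" else "pearson_chi2"),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("<assoc_test> %s: statistic = %.4f, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-sample t-test with control-minus-case orientation
#'
#' Compares a numeric variable (age, in this pipeline) between controls and
#' cases. The statistic is oriented control minus case, so a variable that is
#' larger among cases yields a negative t. Welch's unequal-variance form is
#' the default; `welch = FALSE` gives the pooled-variance Student form.
#'
#' `welch_t_summary()` computes the same Welch statistic from group summary
#' statistics alone (mean, SD, n per group), with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param values_control,values_case numeric vectors (>= 2 values each, with
#'   positive variance)
#' @param welch use Welch's unequal-variance test (default) rather than the
#'   pooled-variance Student test
#' @return an `assoc_test` with `statistic`, `df`, `p_value`, `method`
#' @examples
#' a <- table1_age()
#' welch_t_summary(a$control["mean"], a$control["sd"], a$control["n"],
#'                 a$case["mean"], a$case["sd"], a$case["n"])
#' @export
two_sample_t <- function(values_control, values_case, welch = TRUE) {
  if (length(values_control) < 2 || length(values_case) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(values_control) <= 0 && stats::var(values_case) <= 0) {
    stop("both groups have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(values_control, values_case, var.equal = !welch)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 method = if (welch) "welch_t" else "student_t"),
            class = "assoc_test")
}

#' @rdname two_sample_t
#' @param mean_control,sd_control,n_control,mean_case,sd_case,n_case group
#'   summary statistics
#' @export
welch_t_summary <- function(mean_control, sd_control, n_control,
                            mean_case, sd_case, n_case) {
  v1 <- sd_control^2 / n_control
  v2 <- sd_case^2 / n_case
  t <- (mean_control - mean_case) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n_control - 1) + v2^2 / (n_case - 1))
  structure(list(statistic = unname(t), df = unname(df),
                 p_value = unname(2 * stats::pt(-abs(t), df)),
                 method = "welch_t"),
            class = "assoc_test")
}

#' Within-group ratio of two level counts
#'
#' Ratio of the counts of two levels within one column of a contingency
#' table, e.g. the girls-to-boys ratio among AIS cases.
#'
#' @param table a [contingency_table()]
#' @param level_a,level_b level labels (numerator, denominator)
#' @param group `"case"` or `"control"`
#' @return a single number
#' @examples
#' group_ratio(table1_tables()$gender, "girl", "boy", "case")  # 1.84
#' @export
group_ratio <- function(table, level_a, level_b, group = c("case", "control")) {
  stopifnot(inherits(table, "contingency_table"))
  group <- match.arg(group)
  for (lv in c(level_a, level_b)) {
    if (!lv %in% table$levels) stop("level not in table: '", lv, "'", call. = FALSE)
  }
  denom <- table$counts[level_b, group]
  if (denom == 0) stop("denominator count is zero", call. = FALSE)
  unname(table$counts[level_a, group] / denom)
}

#' Descriptive report of a screening cohort
#'
#' Builds the standard descriptive table of a case-control screening cohort:
#' per-variable level counts and within-group percentages, the chi-square
#' statistic and p-value per variable (continuity-corrected where requested),
#' and the Welch t-test for age.
#'
#' @param records a screening cohort with `ais` labels
#' @param continuity_for variable names whose 2x2 chi-square should use the
#'   Yates continuity correction (default `"lumbar_kyphosis"`, matching the
#'   published table's convention for its sparsest sign)
#' @return a `data.frame` with one row per variable level (plus one for age)
#'   and columns `variable`, `level`, `control_n`, `control_pct`, `case_n`,
#'   `case_pct`, `statistic`, `df`, `p_value`, `method`
#' @export
describe_cohort <- function(records, continuity_for = "lumbar_kyphosis") {
  records <- validate_cohort(records)
  rows <- list()
  na_test <- structure(list(statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, method = NA_character_),
                       class = "assoc_test")
  # tiny or degenerate cohorts still get the count columns; the statistic is
  # simply not defined and reported as NA
  age_test <- tryCatch(two_sample_t(records$age[records$ais == 0],
                                    records$age[records$ais == 1]),
                       error = function(e) na_test)
  rows[[1]] <- data.frame(
    variable = "age", level = "(years)",
    control_n = NA_integer_,
    control_pct = mean(records$age[records$ais == 0]),
    case_n = NA_integer_,
    case_pct = mean(records$age[records$ais == 1]),
    statistic = age_test$statistic, df = age_test$df,
    p_value = age_test$p_value, method = age_test$method
  )
  for (v in names(.ais_levels)) {
    tab <- tabulate_by_status(records, v)
    ht <- tryCatch(chi_square(tab, continuity = v %in% continuity_for),
                   error = function(e) na_test)
    n <- colSums(tab$counts)
    block <- data.frame(
      variable = v, level = tab$levels,
      control_n = tab$counts[, "control"],
      control_pct = 100 * tab$counts[, "control"] / n["control"],
      case_n = tab$counts[, "case"],
      case_pct = 100 * tab$counts[, "case"] / n["case"],
      statistic = c(ht$statistic, rep(NA, length(tab$levels) - 1)),
      df = c(ht$df, rep(NA, length(tab$levels) - 1)),
      p_value = c(ht$p_value, rep(NA, length(tab$levels) - 1)),
      method = c(ht$method, rep(NA, length(tab$levels) - 1))
    )
    rows[[length(rows) + 1]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
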