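#' Univariate odds ratio for one level of a screening variable
#'
#' Closed-form odds ratio of AIS for one non-reference level of a categorical
#' variable against its reference level, from the 2x2 sub-table, with a Wald
#' 95% confidence interval (`exp(log OR +/- 1.96 * SE)`, SE the square root
#' of the sum of reciprocal cell counts) and a Wald z p-value. This equals
#' the published univariate logistic model's estimate for that level. If any
#' of the four cells is zero, the Haldane-Anscombe correction (+0.5 to all
#' four cells) is applied and the estimate is flagged `corrected`.
#'
#' @param table a [contingency_table()]
#' @param level a non-reference level label
#' @param reference the reference level (default: the table's first level)
#' @return an object of class `effect_estimate`: list with `variable`,
#'   `level`, `estimate`, `ci_low`, `ci_high`, `p_value`, `adjusted = FALSE`,
#'   `corrected`
#' @examples
#' univariate_or(table1_tables()$gender, "girl")  # OR 3.26 (2.69-3.96)
#' @export
univariate_or <- function(table, level, reference = table$levels[1]) {
  stopifnot(inherits(table, "contingency_table"))
  if (!level %in% table$levels) stop("level not in table: '", level, "'", call. = FALSE)
  if (level == reference) stop("level must differ from the reference", call. = FALSE)
  cells <- c(control_ref = table$counts[reference, "control"],
             case_ref = table$counts[reference, "case"],
             control_level = table$counts[level, "control"],
             case_level = table$counts[level, "case"])
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["case_level"] * cells["control_ref"]) /
    (cells["control_level"] * cells["case_ref"])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  new_effect_estimate(
    variable = table$variable, level = level,
    estimate = unname(or),
    ci_low = unname(exp(log(or) - .z975 * se)),
    ci_high = unname(exp(log(or) + .z975 * se)),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    adjusted = FALSE, corrected = corrected
  )
}

new_effect_estimate <- function(variable, level, estimate, ci_low, ci_high,
                                p_value, adjusted, corrected = FALSE) {
  structure(list(variable = variable, level = level, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 adjusted = adjusted, corrected = corrected),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s [%s]: %s = %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n",
              x$variable, x$level, if (x$adjusted) "AOR" else "OR",
              x$estimate, x$ci_low, x$ci_high, x$p_value,
              if (isTRUE(x$corrected)) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Univariate odds ratio for a continuous predictor
#'
#' Single-predictor logistic regression of AIS on a numeric variable; the
#' estimate is the odds ratio per unit increase (`exp(slope)`) with a Wald
#' 95% CI.
#'
#' @param records a screening cohort with `ais` labels
#' @param variable name of a numeric column (e.g. `"age"`)
#' @return an `effect_estimate`
#' @export
univariate_or_continuous <- function(records, variable) {
  records <- validate_cohort(records)
  x <- records[[variable]]
  if (!is.numeric(x)) stop("'", variable, "' is not numeric", call. = FALSE)
  if (stats::var(x) <= 0) stop("'", variable, "' has zero variance", call. = FALSE)
  if (length(unique(records$ais)) < 2) {
    stop("outcome is constant: cannot fit a logistic model", call. = FALSE)
  }
  fit <- stats::glm(records$ais ~ x, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  .check_separation(fit)
  b <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  new_effect_estimate(
    variable = variable, level = "(per unit increase)",
    estimate = exp(b), ci_low = exp(b - .z975 * se), ci_high = exp(b + .z975 * se),
    p_value = 2 * stats::pnorm(-abs(b / se)),
    adjusted = FALSE
  )
}

# internal: flag (quasi-)complete separation by diverging coefficients
.check_separation <- function(fit, limit = 15) {
  bad <- abs(stats::coef(fit)) > limit
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    warning("possible complete separation: coefficient magnitude > ", limit,
            " for ", paste(names(which(bad)), collapse = ", "),
            call. = FALSE)
  }
  if (!fit$converged) {
    warning("logistic fit did not converge within ", fit$iter,
            " iterations; estimates are the last iterate", call. = FALSE)
  }
  invisible(fit)
}

#' Encode screening covariates as a numeric design matrix
#'
#' Maps the twelve model covariates X1..X12 (gender, age, and the nine
#' postural signs; school category is descriptive only) to numbers under one
#' of two encodings:
#'
#' * `"single_score"` — one column per covariate: gender boy = 0 / girl = 1,
#'   age in raw years, three-level signs normal = 0 / left = 1 / right = 2,
#'   binary signs normal = 0 / abnormal = 1. This is the encoding of the
#'   published risk equations.
#' * `"dummy_expanded"` — each three-level sign becomes two indicator
#'   columns (reference = normal), giving per-level adjusted odds ratios.
#'
#' @param records a screening cohort
#' @param encoding `"single_score"` or `"dummy_expanded"`
#' @return a numeric matrix without intercept column; `single_score` columns
#'   are named `X1`..`X12`, dummy columns `<variable>:<level>`
#' @export
encode_covariates <- function(records, encoding = c("dummy_expanded", "single_score")) {
  encoding <- match.arg(encoding)
  records <- validate_cohort(records, require_outcome = FALSE)
  vars <- ais_covariates()
  cols <- list()
  for (i in seq_along(vars)) {
    v <- vars[i]
    if (v == "age") {
      cols[[if (encoding == "single_score") paste0("X", i) else "age"]] <-
        records$age
      next
    }
    f <- records[[v]]
    if (encoding == "single_score") {
      cols[[paste0("X", i)]] <- as.numeric(f) - 1
    } else {
      for (lv in levels(f)[-1]) {
        cols[[paste0(v, ":", lv)]] <- as.numeric(f == lv)
      }
    }
  }
  x <- do.call(cbind, cols)
  attr(x, "encoding") <- encoding
  x
}

#' Multivariate logistic model of AIS on all twelve covariates
#'
#' Fits the multivariate logistic regression of AIS status on gender, age and
#' the nine postural signs by maximum likelihood (iteratively reweighted
#' least squares, convergence tolerance 1e-10, at most 100 iterations).
#' Adjusted odds ratios are `exp(coefficient)` with Wald 95% CIs. Possible
#' complete separation (a coefficient magnitude above 15) and non-convergence
#' are reported as warnings carrying the offending terms; a rank-deficient
#' design is an error.
#'
#' @param records a screening cohort with both outcome classes present
#' @param encoding covariate encoding, see [encode_covariates()]
#' @param drop_constant if `TRUE`, covariate columns that are constant in
#'   `records` (a sign nobody in the sample shows, as can happen for the
#'   rarest signs in a resampled training split) are dropped from the fit
#'   with a warning and returned with coefficient 0, rather than making the
#'   design rank deficient
#' @return a [prediction_model] with `provenance = "fitted"`, carrying
#'   coefficient standard errors, AORs with CIs, and the training design
#'   (used later for weight derivation and intercept recalibration)
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' fit <- fit_multivariate(cohort, encoding = "single_score")
#' fit$aor["X12"]  # adjusted OR per step of lumbar trunk-rotation score
#' @export
fit_multivariate <- function(records, encoding = c("dummy_expanded", "single_score"),
                             drop_constant = FALSE) {
  encoding <- match.arg(encoding)
  records <- validate_cohort(records)
  if (length(unique(records$ais)) < 2) {
    stop("outcome is constant: cannot fit a logistic model", call. = FALSE)
  }
  x <- encode_covariates(records, encoding)
  y <- as.integer(records$ais)
  constant <- apply(x, 2, function(col) min(col) == max(col))
  if (any(constant) && drop_constant) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
    xf <- x[, !constant, drop = FALSE]
  } else {
    xf <- x
  }
  if (nrow(xf) < 20 * (ncol(xf) + 1)) {
    warning("fewer than 20 records per parameter (", nrow(xf), " records, ",
            ncol(xf) + 1, " parameters); estimates may be unstable", call. = FALSE)
  }
  if (qr(cbind(1, xf))$rank < ncol(xf) + 1) {
    stop("design matrix is rank deficient: a covariate is constant or aliased",
         call. = FALSE)
  }
  xm <- cbind(`(Intercept)` = 1, xf)
  fit <- stats::glm.fit(xm, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  .check_separation(fit)
  b <- fit$coefficients
  p <- ncol(xm)
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  names(se) <- names(b)
  # dropped columns re-enter with coefficient 0 and no standard error
  coefs <- stats::setNames(rep(0, ncol(x)), colnames(x))
  ses <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  coefs[names(b)[-1]] <- b[-1]
  ses[names(b)[-1]] <- se[-1]
  new_prediction_model(
    intercept = unname(b[1]),
    coefficients = coefs,
    encoding = encoding,
    scheme = "plain",
    provenance = "fitted",
    se = ses,
    intercept_se = unname(se[1]),
    train = list(x = x, y = y)
  )
}

#' Per-level adjusted odds ratios from a fitted multivariate model
#'
#' Extracts the effect estimates (AOR, Wald 95% CI, p) for every coefficient
#' of a fitted multivariate model, the multivariate analogue of
#' [univariate_or()].
#'
#' @param model a fitted [prediction_model] (provenance `"fitted"`)
#' @return a list of `effect_estimate` objects, one per coefficient
#' @export
adjusted_or <- function(model) {
  stopifnot(inherits(model, "prediction_model"))
  if (is.null(model$se)) stop("model carries no standard errors", call. = FALSE)
  out <- lapply(names(model$coefficients), function(nm) {
    b <- model$coefficients[[nm]]
    se <- model$se[[nm]]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    new_effect_estimate(
      variable = parts[1], level = if (length(parts) > 1) parts[2] else nm,
      estimate = exp(b), ci_low = exp(b - .z975 * se),
      ci_high = exp(b + .z975 * se),
      p_value = 2 * stats::pnorm(-abs(b / se)),
      adjusted = TRUE
    )
  })
  names(out) <- names(model$coefficients)
  out
}

#' Association report for a screening cohort
#'
#' The standard association table: univariate odds ratios per non-reference
#' level of every categorical covariate plus age per year (model 1), and
#' adjusted odds ratios from the multivariate fit (model 2).
#'
#' @param records a screening cohort with `ais` labels
#' @return a `data.frame` with one row per (variable, level), columns for OR
#'   and AOR with CIs and p-values
#' @export
associate_cohort <- function(records) {
  records <- validate_cohort(records)
  uni <- list()
  for (v in ais_covariates()) {
    if (v == "age") {
      uni[[v]] <- list(univariate_or_continuous(records, v))
      next
    }
    tab <- tabulate_by_status(records, v)
    uni[[v]] <- lapply(tab$levels[-1], function(lv) univariate_or(tab, lv))
  }
  uni <- unlist(uni, recursive = FALSE)
  fit <- fit_multivariate(records, encoding = "dummy_expanded")
  adj <- adjusted_or(fit)
  row_of <- function(e) data.frame(variable = e$variable, level = e$level,
                                   estimate = e$estimate, ci_low = e$ci_low,
                                   ci_high = e$ci_high, p_value = e$p_value)
  out <- do.call(rbind, lapply(uni, row_of))
  names(out)[3:6] <- paste0("or_", c("estimate", "ci_low", "ci_high", "p"))
  adj_df <- do.call(rbind, lapply(adj, row_of))
  # align: age's dummy name is "age"
  key <- function(d) paste(d$variable, d$level)
  adj_key <- key(adj_df)
  adj_key[adj_df$variable == "age"] <- "age (per unit increase)"
  m <- match(key(out), adj_key)
  out$aor_estimate <- adj_df$estimate[m]
  out$aor_ci_low <- adj_df$ci_low[m]
  out$aor_ci_high <- adj_df$ci_high[m]
  out$aor_p <- adj_df$p_value[m]
  rownames(out) <- NULL
  out
}
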