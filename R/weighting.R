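#' Variable weights for coefficient re-weighting
#'
#' The weighted prediction models rescale each covariate's log-odds
#' coefficient by a positive per-variable weight, normalized to mean 1 so
#' that the overall coefficient scale (and uniform weights as the identity)
#' is preserved:
#'
#' * `aor_weights(model)` — weights derive from the model's own adjusted
#'   odds ratios, `exp(coefficient)` per covariate (for dummy-expanded
#'   models, the mean of the level-specific AORs of each variable), mapped
#'   to the bounded probability scale `AOR / (1 + AOR)` by [aor_to_weight()].
#'   An AOR measures the strength of the covariate-outcome association; the
#'   probability-scale transform makes AOR weights commensurable with AUC
#'   weights (both live in (0, 1), 0.5 = no association) and keeps a
#'   quasi-separated covariate's exploding AOR from dominating the weight
#'   vector.
#' * `auc_weights(records)` — weights are the per-variable discrimination
#'   AUCs on `records`: the binary-collapse empirical AUC for categorical
#'   signs, the binormal AUC for age. An AUC measures the covariate's
#'   stand-alone diagnostic performance.
#' * `combine_weights(a, b)` — the elementwise product of two mean-normalized
#'   weight vectors (the AOR+AUC scheme).
#'
#' @param model a fitted [prediction_model]
#' @return a named positive numeric vector over [ais_covariates()]
#' @export
aor_weights <- function(model) {
  stopifnot(inherits(model, "prediction_model"))
  vars <- ais_covariates()
  mult <- .coef_variable(names(model$coefficients), model$encoding)
  aor <- vapply(vars, function(v) mean(exp(model$coefficients[mult == v])),
                numeric(1))
  aor_to_weight(aor)
}

#' @rdname aor_weights
#' @param aor positive odds ratio(s)
#' @details `aor_to_weight()` maps an odds ratio to `AOR / (1 + AOR)`: the
#'   probability that the exposed subject is the case in a discordant pair,
#'   0.5 at no association, approaching 1 as the association strengthens —
#'   the odds-ratio analogue of an AUC.
#' @export
aor_to_weight <- function(aor) {
  if (any(aor <= 0)) stop("odds ratios must be positive", call. = FALSE)
  aor / (1 + aor)
}

#' @rdname aor_weights
#' @param records a screening cohort with `ais` labels
#' @export
auc_weights <- function(records) {
  records <- validate_cohort(records)
  w <- vapply(ais_covariates(), function(v) {
    if (v == "age") {
      ctrl <- records$age[records$ais == 0]
      case <- records$age[records$ais == 1]
      return(binormal_auc(mean(case), stats::sd(case),
                          mean(ctrl), stats::sd(ctrl))$auc)
    }
    empirical_auc(tabulate_by_status(records, v))$auc
  }, numeric(1))
  w
}

#' @rdname aor_weights
#' @param a,b named weight vectors over the same variables
#' @export
combine_weights <- function(a, b) {
  stopifnot(identical(sort(names(a)), sort(names(b))))
  an <- a / mean(a)
  bn <- b[names(a)] / mean(b)
  an * bn
}

# internal: map coefficient names to the covariate they belong to
.coef_variable <- function(coef_names, encoding) {
  vars <- ais_covariates()
  if (encoding == "single_score") {
    idx <- as.integer(sub("^X", "", coef_names))
    return(vars[idx])
  }
  vapply(strsplit(coef_names, ":", fixed = TRUE), `[[`, character(1), 1)
}

#' Re-weight a fitted prediction model's coefficients
#'
#' Produces a weighted variant of a fitted logistic model: the coefficient of
#' every covariate `j` becomes `beta_j * w_j / mean(w)` (for dummy-expanded
#' models, both indicators of a variable share its weight), and the intercept
#' is recalibrated so that the mean predicted probability on the training
#' records equals the observed case fraction — the calibration-in-the-large
#' property that the unweighted maximum-likelihood fit has by construction.
#' Uniform weights therefore return the model unchanged, and rescaling all
#' raw weights by a constant has no effect.
#'
#' @param base a fitted plain [prediction_model] carrying its training design
#' @param weights named positive weight vector over [ais_covariates()], e.g.
#'   from [aor_weights()], [auc_weights()] or [combine_weights()]
#' @param scheme tag recorded on the result: `"aor_weighted"`,
#'   `"auc_weighted"` or `"aor_auc_weighted"`
#' @return a [prediction_model] with the new scheme tag (standard errors are
#'   dropped: Wald SEs of the base fit do not transfer to rescaled
#'   coefficients)
#' @export
apply_weighting <- function(base, weights,
                            scheme = c("aor_weighted", "auc_weighted",
                                       "aor_auc_weighted")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(base, "prediction_model"))
  if (base$provenance != "fitted" || is.null(base$train)) {
    stop("base must be a fitted model carrying its training design", call. = FALSE)
  }
  vars <- ais_covariates()
  missing <- setdiff(vars, names(weights))
  if (length(missing) > 0) {
    stop("missing weight(s) for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(weights <= 0)) stop("all weights must be positive", call. = FALSE)
  wn <- weights[vars] / mean(weights[vars])
  mult <- wn[.coef_variable(names(base$coefficients), base$encoding)]
  coefs <- base$coefficients * as.numeric(mult)
  eta <- drop(base$train$x[, names(coefs), drop = FALSE] %*% coefs)
  target <- mean(base$train$y)
  delta <- stats::uniroot(function(d) mean(stats::plogis(d + eta)) - target,
                          lower = -50, upper = 50, tol = 1e-10)$root
  new_prediction_model(
    intercept = delta, coefficients = coefs, encoding = base$encoding,
    scheme = scheme, provenance = "fitted", train = base$train
  )
}
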