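#' Logistic AIS prediction model
#'
#' A prediction model is an intercept plus a coefficient vector on the
#' log-odds scale, tagged with its covariate encoding (see
#' [encode_covariates()]), its weighting scheme (`plain`, `aor_weighted`,
#' `auc_weighted`, `aor_auc_weighted`) and its provenance (`fitted` from
#' data, or `printed_equation` for the published fixed equations). Fitted
#' models additionally carry Wald standard errors and their training design,
#' which weighting and intercept recalibration reuse.
#'
#' @name prediction_model
#' @seealso [fit_multivariate()], [printed_equation()], [apply_weighting()],
#'   [predict_probability()]
NULL

new_prediction_model <- function(intercept, coefficients, encoding, scheme,
                                 provenance, se = NULL, intercept_se = NULL,
                                 train = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)))
  m <- list(intercept = intercept, coefficients = coefficients,
            encoding = encoding, scheme = scheme, provenance = provenance,
            se = se, intercept_se = intercept_se, train = train)
  m$aor <- exp(coefficients)
  structure(m, class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, digits = 3, ...) {
  cat(sprintf("<prediction_model> %s / %s / %s\n", x$encoding, x$scheme,
              x$provenance))
  terms <- paste(sprintf("%+.*f %s", digits, x$coefficients,
                         names(x$coefficients)), collapse = " ")
  cat(sprintf("  logit(p) = %.*f %s\n", digits, x$intercept, terms))
  invisible(x)
}

#' Predicted AIS probability
#'
#' Evaluates the logistic model: `p = 1 / (1 + exp(-(b0 + x . beta)))`.
#' Covariates may be a screening cohort `data.frame` (encoded automatically
#' with the model's encoding) or an already-encoded numeric matrix/vector
#' whose columns match the model's coefficients.
#'
#' @param model a [prediction_model]
#' @param covariates screening records or an encoded design matrix
#' @return a vector of probabilities, strictly inside (0, 1)
#' @examples
#' eq1 <- printed_equation(1)
#' predict_probability(eq1, setNames(rep(0, 12), names(eq1$coefficients)))
#' @export
predict_probability <- function(model, covariates) {
  stopifnot(inherits(model, "prediction_model"))
  if (is.data.frame(covariates)) {
    covariates <- encode_covariates(covariates, model$encoding)
  }
  if (is.null(dim(covariates))) {
    covariates <- matrix(covariates, nrow = 1,
                         dimnames = list(NULL, names(covariates)))
  }
  enc <- attr(covariates, "encoding")
  if (!is.null(enc) && enc != model$encoding) {
    stop("covariate encoding '", enc, "' does not match model encoding '",
         model$encoding, "'", call. = FALSE)
  }
  missing <- setdiff(names(model$coefficients), colnames(covariates))
  if (length(missing) > 0) {
    stop("covariates are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  eta <- model$intercept +
    drop(covariates[, names(model$coefficients), drop = FALSE] %*%
           model$coefficients)
  stats::plogis(eta)
}

#' Classify a predicted probability
#'
#' Binary classification at a probability threshold. A probability exactly at
#' the threshold classifies positive (documented boundary convention).
#'
#' @param probability vector of probabilities in \[0, 1\]
#' @param threshold classification threshold in (0, 1); default 0.5, the
#'   single operating point at which the screening models are reported
#' @return an integer vector of 0/1 labels
#' @export
classify <- function(probability, threshold = 0.5) {
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number strictly inside (0, 1)", call. = FALSE)
  }
  as.integer(probability >= threshold)
}
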