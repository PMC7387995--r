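# Access to the packaged fixtures: the published case-control screening
# table, the four published risk equations, and the published summary values
# they are checked against.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "scolioscreen")
  if (path == "") stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

#' Published case-control screening counts
#'
#' The grouped counts of the published screening study: for each categorical
#' variable, the number of control (Cobb < 10 degrees, n = 895) and case
#' (Cobb >= 10 degrees, n = 884) subjects at each level.
#'
#' @return `table1_counts()`: a `data.frame` with columns `variable`,
#'   `level`, `control`, `case`. `table1_tables()`: the same counts as a
#'   named list of [contingency_table()] objects. `table1_age()`: the
#'   published within-group age summaries as a list with components
#'   `control` and `case`, each `c(mean, sd, n)`.
#' @examples
#' table1_tables()$gender
#' @export
table1_counts <- function() {
  utils::read.csv(.extdata("table1_counts.csv"), stringsAsFactors = FALSE)
}

#' @rdname table1_counts
#' @export
table1_tables <- function() {
  counts <- table1_counts()
  out <- lapply(names(.ais_levels), function(v) {
    rows <- counts[counts$variable == v, ]
    rows <- rows[match(.ais_levels[[v]], rows$level), ]
    contingency_table(v, rows$level, rows$control, rows$case)
  })
  names(out) <- names(.ais_levels)
  out
}

#' @rdname table1_counts
#' @export
table1_age <- function() {
  ref <- printed_reference()
  list(control = c(mean = ref$age$control$mean, sd = ref$age$control$sd, n = 895),
       case = c(mean = ref$age$case$mean, sd = ref$age$case$sd, n = 884))
}

#' Published AIS risk prediction equations
#'
#' The four published logistic risk equations for AIS, as fixed coefficient
#' sets on the log-odds scale: the plain multivariate fit and its
#' AOR-weighted, AUC-weighted, and AOR+AUC-weighted variants. All four use
#' the single-score covariate encoding (see [encode_covariates()]): gender
#' boy = 0 / girl = 1, age in years, three-level signs scored
#' normal = 0 / left = 1 / right = 2, binary signs 0/1.
#'
#' These are verbatim published coefficients (provenance `"printed_equation"`),
#' not refits: they came from a 70% training split of the original study data,
#' which is not redistributable, so they ship as fixtures.
#'
#' @param which equation number, 1 to 4 (1 = plain multivariate, 2 =
#'   AOR-weighted, 3 = AUC-weighted, 4 = AOR+AUC-weighted)
#' @return a [prediction_model] with intercept and coefficients `X1`..`X12`
#' @examples
#' printed_equation(1)$intercept  # -7.124
#' @export
printed_equation <- function(which) {
  if (!length(which) == 1 || !which %in% 1:4) {
    stop("'which' must be 1, 2, 3 or 4", call. = FALSE)
  }
  eqs <- jsonlite::read_json(.extdata("printed_equations.json"),
                             simplifyVector = TRUE)$equations
  row <- which(eqs$id == which)
  coefs <- unlist(eqs$coefficients[row, ])
  new_prediction_model(
    intercept = eqs$intercept[row],
    coefficients = coefs,
    encoding = "single_score",
    scheme = eqs$scheme[row],
    provenance = "printed_equation"
  )
}

#' @rdname printed_equation
#' @return `printed_reference()`: the published summary values (chi-square
#'   statistics, odds ratios, AUCs, adjusted odds ratios) as a nested list,
#'   the comparison surface of [reproduce_paper()].
#' @export
printed_reference <- function() {
  jsonlite::read_json(.extdata("printed_reference.json"), simplifyVector = FALSE)
}

#' Published AOR and AUC variable weights
#'
#' Per-variable weights over the twelve model covariates taken from the
#' published study: `printed_aor_weights()` uses the adjusted odds ratios of
#' the published multivariate model (for three-level signs, the mean of the
#' two level-specific AORs), mapped to the probability scale by
#' [aor_to_weight()]; `printed_auc_weights()` uses the published
#' per-variable AUCs, completed for the three sagittal-profile flags (whose
#' AUCs were not reported because they did not differ from 0.5) by the
#' count-derived empirical AUCs.
#'
#' @return a named positive numeric vector over [ais_covariates()]
#' @export
printed_aor_weights <- function() {
  aor <- printed_reference()$printed_aor
  w <- vapply(ais_covariates(), function(v) mean(unlist(aor[[v]])), numeric(1))
  aor_to_weight(w)
}

#' @rdname printed_aor_weights
#' @export
printed_auc_weights <- function() {
  ref <- printed_reference()$printed_auc_all
  tabs <- table1_tables()
  w <- vapply(ais_covariates(), function(v) {
    if (!is.null(ref[[v]])) return(as.numeric(ref[[v]]))
    empirical_auc(tabs[[v]])$auc
  }, numeric(1))
  w
}
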