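# Canonical screening-record schema shared by every stage of the pipeline.
# Order matters: model covariates X1..X12 follow ais_covariates().

.ais_levels <- list(
  gender               = c("boy", "girl"),
  school               = c("primary", "junior", "senior"),
  shoulder_height_diff = c("normal", "left", "right"),
  scapular_tilt        = c("normal", "left", "right"),
  lumbar_concave       = c("normal", "left", "right"),
  pelvic_tilt          = c("normal", "left", "right"),
  flat_back            = c("normal", "abnormal"),
  thoracic_kyphosis    = c("normal", "abnormal"),
  lumbar_kyphosis      = c("normal", "abnormal"),
  atr_thoracic         = c("normal_0_5", "left_gt5", "right_gt5"),
  atr_thoracolumbar    = c("normal_0_5", "left_gt5", "right_gt5"),
  atr_lumbar           = c("normal_0_5", "left_gt5", "right_gt5")
)

.ais_columns <- c("gender", "age", "school", names(.ais_levels)[-(1:2)], "ais")

#' Screening-record variables
#'
#' Column names and category levels of a screening cohort. A cohort is a
#' `data.frame` with one row per screened subject: `gender` (boy/girl),
#' `age` in years, `school` category, nine postural-sign variables, and the
#' binary outcome `ais` (1 = radiographic Cobb angle >= 10 degrees).
#' Trunk-rotation variables (`atr_*`) encode the scoliometer screening
#' cut-off: `normal_0_5` is an angle of trunk rotation of 0-5 degrees,
#' `left_gt5`/`right_gt5` a rotation beyond 5 degrees to either side.
#'
#' @return `ais_variables()` returns the names of all categorical variables;
#'   `ais_levels(variable)` the ordered category levels of one variable
#'   (first level = reference); `ais_covariates()` the twelve model
#'   covariates in their conventional X1..X12 order (gender, age, then the
#'   postural signs; school category is descriptive only and excluded).
#' @examples
#' ais_covariates()
#' ais_levels("scapular_tilt")
#' @export
ais_variables <- function() names(.ais_levels)

#' @rdname ais_variables
#' @param variable name of a categorical screening variable
#' @export
ais_levels <- function(variable) {
  if (!variable %in% names(.ais_levels)) {
    stop("unknown categorical screening variable: '", variable, "'", call. = FALSE)
  }
  .ais_levels[[variable]]
}

#' @rdname ais_variables
#' @export
ais_covariates <- function() {
  c("gender", "age", setdiff(names(.ais_levels), c("gender", "school")))
}

# internal: assert a data.frame is a valid cohort; returns it with factor
# columns coerced to the canonical levels
validate_cohort <- function(records, require_outcome = TRUE) {
  if (!is.data.frame(records)) stop("cohort must be a data.frame", call. = FALSE)
  needed <- setdiff(.ais_columns, if (require_outcome) character() else "ais")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (v in names(.ais_levels)) {
    col <- as.character(records[[v]])
    bad <- !is.na(col) & !col %in% .ais_levels[[v]]
    if (any(bad)) {
      stop("unknown level(s) for '", v, "' in row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "), ": ",
           paste(unique(col[bad]), collapse = ", "), call. = FALSE)
    }
    records[[v]] <- factor(col, levels = .ais_levels[[v]])
  }
  if (!is.numeric(records$age) || anyNA(records$age)) {
    stop("age must be numeric with no missing values", call. = FALSE)
  }
  if (require_outcome && !all(records$ais %in% c(0L, 1L))) {
    stop("ais labels must be 0 or 1", call. = FALSE)
  }
  records
}

# internal: seeded evaluation without touching the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# internal: derive a per-stage child seed from a master seed (documented
# stream-splitting rule: one child stream per pipeline stage)
child_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + 1000003 * stage_index) %% 2147483629)
}

.z975 <- 1.959964
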