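#' Specify a synthetic case-control screening cohort
#'
#' A cohort specification fixes everything the simulator needs: the two group
#' sizes, the per-variable category probabilities conditional on AIS status,
#' the within-group age distribution, an optional latent correlation matrix,
#' and a seed. The simulator draws each subject's categorical signs from the
#' group-conditional marginals through a Gaussian copula: with no `dependence`
#' matrix the latent normals are independent, so signs are conditionally
#' independent given AIS status (the weakest assumption consistent with
#' published marginal-by-status tables); supplying a correlation matrix
#' induces rank dependence between signs while preserving every marginal.
#'
#' @param n_controls,n_cases number of subjects without / with AIS
#' @param category_probs named list over the categorical screening variables;
#'   each element is a list with components `control` and `case`, probability
#'   vectors over that variable's levels (named or in level order)
#' @param age_params list with components `control` and `case`, each
#'   `c(mean, sd)` in years; ages are drawn truncated-normal on
#'   \[`age_range`\]
#' @param age_range lower/upper truncation bounds for age in years
#'   (default 6-19, the age span of grades 1-12)
#' @param dependence optional latent correlation matrix, one row/column per
#'   entry of `latent_order()`; must be symmetric with unit diagonal and
#'   positive semi-definite
#' @param seed integer seed governing the entire cohort draw
#' @return an object of class `cohort_spec`
#' @seealso [default_cohort_spec()] for the calibrated defaults,
#'   [generate_cohort()] to draw a cohort
#' @export
cohort_spec <- function(n_controls, n_cases, category_probs, age_params,
                        age_range = c(6, 19), dependence = NULL,
                        seed = 20190901L) {
  if (n_controls < 0 || n_cases < 0) {
    stop("group sizes must be non-negative", call. = FALSE)
  }
  vars <- names(.ais_levels)
  missing <- setdiff(vars, names(category_probs))
  if (length(missing) > 0) {
    stop("category_probs missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in vars) {
    for (grp in c("control", "case")) {
      p <- category_probs[[v]][[grp]]
      if (length(p) != length(.ais_levels[[v]])) {
        stop("probability vector for ", v, " (", grp, ") must have ",
             length(.ais_levels[[v]]), " entries", call. = FALSE)
      }
      if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
        stop("probabilities for ", v, " (", grp,
             ") must be non-negative and sum to 1", call. = FALSE)
      }
      names(category_probs[[v]][[grp]]) <- .ais_levels[[v]]
    }
  }
  for (grp in c("control", "case")) {
    ap <- age_params[[grp]]
    if (length(ap) != 2 || ap[2] <= 0) {
      stop("age_params$", grp, " must be c(mean, sd) with sd > 0", call. = FALSE)
    }
  }
  if (!is.null(dependence)) {
    k <- length(latent_order())
    if (!is.matrix(dependence) || any(dim(dependence) != k)) {
      stop("dependence must be a ", k, "x", k, " matrix ordered as latent_order()",
           call. = FALSE)
    }
    if (max(abs(dependence - t(dependence))) > 1e-8 ||
        max(abs(diag(dependence) - 1)) > 1e-8) {
      stop("dependence must be symmetric with unit diagonal", call. = FALSE)
    }
    ev <- eigen(dependence, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("dependence matrix is not positive semi-definite", call. = FALSE)
    }
  }
  structure(
    list(n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
         category_probs = category_probs, age_params = age_params,
         age_range = as.numeric(age_range), dependence = dependence,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @details `latent_order()` gives the variable order of the copula's latent
#'   dimensions (and hence of any `dependence` matrix): gender, age, school,
#'   then the nine postural signs.
#' @export
latent_order <- function() c("gender", "age", "school", names(.ais_levels)[-(1:2)])

#' Default cohort specification calibrated to the published screening study
#'
#' Returns the specification whose group-conditional category frequencies
#' equal the published case-control screening table (895 controls with Cobb
#' angle < 10 degrees, 884 AIS cases with Cobb angle >= 10 degrees; e.g.
#' control-group scapular tilt 764/895 normal, 85/895 left, 46/895 right),
#' with age normal within group at 12.67 (SD 1.96) years for controls and
#' 13.14 (SD 1.87) years for cases, truncated to 6-19 years, and no latent
#' dependence between signs.
#'
#' @param seed integer seed stored in the spec (default 20190901)
#' @return a `cohort_spec`
#' @examples
#' spec <- default_cohort_spec()
#' spec$n_controls + spec$n_cases  # 1779
#' @export
default_cohort_spec <- function(seed = 20190901L) {
  counts <- table1_counts()
  probs <- lapply(names(.ais_levels), function(v) {
    rows <- counts[counts$variable == v, ]
    rows <- rows[match(.ais_levels[[v]], rows$level), ]
    list(control = rows$control / sum(rows$control),
         case = rows$case / sum(rows$case))
  })
  names(probs) <- names(.ais_levels)
  cohort_spec(
    n_controls = 895L, n_cases = 884L,
    category_probs = probs,
    age_params = list(control = c(12.67, 1.96), case = c(13.14, 1.87)),
    seed = seed
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_controls, "controls /", x$n_cases, "cases;",
      if (is.null(x$dependence)) "independent signs" else "copula-dependent signs",
      "; seed", x$seed, "\n")
  invisible(x)
}

# internal: map copula uniforms to category levels through cumulative
# probability thresholds
.u_to_level <- function(u, probs, levels) {
  cums <- cumsum(probs)
  idx <- findInterval(u, cums[-length(cums)], left.open = TRUE) + 1L
  factor(levels[idx], levels = levels)
}

# internal: draw one group's records (latent Gaussian copula; identity
# correlation when dependence is absent)
.draw_group <- function(n, spec, group, ais_label) {
  vars <- latent_order()
  z <- matrix(stats::rnorm(n * length(vars)), nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  if (!is.null(spec$dependence)) {
    ev <- eigen(spec$dependence, symmetric = TRUE)
    l <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(vars)) %*% t(ev$vectors)
    z <- z %*% l
    colnames(z) <- vars
  }
  u <- stats::pnorm(z)
  dim(u) <- dim(z)
  dimnames(u) <- dimnames(z)
  ap <- spec$age_params[[group]]
  plo <- stats::pnorm(spec$age_range[1], ap[1], ap[2])
  phi <- stats::pnorm(spec$age_range[2], ap[1], ap[2])
  age <- stats::qnorm(plo + u[, "age"] * (phi - plo), ap[1], ap[2])
  out <- data.frame(
    gender = .u_to_level(u[, "gender"], spec$category_probs$gender[[group]],
                         .ais_levels$gender),
    age = age,
    school = .u_to_level(u[, "school"], spec$category_probs$school[[group]],
                         .ais_levels$school)
  )
  for (v in names(.ais_levels)[-(1:2)]) {
    out[[v]] <- .u_to_level(u[, v], spec$category_probs[[v]][[group]],
                            .ais_levels[[v]])
  }
  out$ais <- rep(ais_label, n)
  attr(out, "latent") <- z
  out
}

#' Simulate a screening cohort
#'
#' Draws exactly `n_controls` records with `ais = 0` followed by `n_cases`
#' records with `ais = 1`. Given AIS status, each categorical sign follows
#' its group-conditional probability vector; age is truncated-normal with the
#' group's mean/SD. All randomness flows from one integer seed, so the same
#' seed reproduces the cohort byte-for-byte; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [cohort_spec()]
#' @param seed override of `spec$seed` (convenient for replicate draws)
#' @param keep_latent keep the latent Gaussian draws as attribute `"latent"`
#'   (used to verify copula behaviour)
#' @return a `data.frame` of screening records, one row per subject
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' table(cohort$ais)
#' @export
generate_cohort <- function(spec, seed = spec$seed, keep_latent = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    controls <- .draw_group(spec$n_controls, spec, "control", 0L)
    cases <- .draw_group(spec$n_cases, spec, "case", 1L)
    latent <- rbind(attr(controls, "latent"), attr(cases, "latent"))
    attr(controls, "latent") <- NULL
    attr(cases, "latent") <- NULL
    out <- rbind(controls, cases)
    rownames(out) <- NULL
    if (keep_latent) attr(out, "latent") <- latent
    out
  })
}
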