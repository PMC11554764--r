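#' Fit the normative correction model on healthy individuals
#'
#' Ordinary least squares of the raw score on the (centered) transformed
#' age and education terms of the generating equation, restricted to the
#' cognitively healthy members of the development cohort.  This is the
#' regression whose predictions and intercept define the corrected score.
#'
#' The basis always matches the equation used to generate the scores, so
#' the fitted model is well specified for the healthy subpopulation.
#'
#' @param dev_cohort A cohort with `raw_score` set (see
#'   [generate_raw_scores()]).
#' @param eq The [normative_equation()] whose age/education basis the
#'   regression uses.
#' @return An object of class `correction_model` with elements `beta0`
#'   (fitted intercept), `beta_age`, `beta_edu`, `residual_sd_hat`
#'   (residual standard deviation, denominator n - 3), `n_healthy`, and
#'   the basis description.
#' @export
fit_normative <- function(dev_cohort, eq) {
  stopifnot(inherits(dev_cohort, "moca_cohort"),
            inherits(eq, "normative_equation"))
  if (is.null(dev_cohort$raw_score)) {
    stop("development cohort has no raw scores; call generate_raw_scores() first")
  }
  healthy <- dev_cohort[dev_cohort$status == "healthy", , drop = FALSE]
  if (nrow(healthy) < 3L) {
    stop("need at least 3 healthy individuals to fit the correction model")
  }
  x_age <- age_transform(eq$age_basis, healthy$age) - eq$age_center
  x_edu <- edu_transform(eq$edu_basis, healthy$edu_years) - eq$edu_center
  X <- cbind(`(Intercept)` = 1, age_term = x_age, edu_term = x_edu)
  fit <- stats::lm.fit(X, healthy$raw_score)
  if (fit$rank < 3L) {
    stop("rank-deficient design: healthy covariates do not span age and education")
  }
  beta <- fit$coefficients
  structure(
    list(equation_id = eq$id,
         age_basis = eq$age_basis, edu_basis = eq$edu_basis,
         age_center = eq$age_center, edu_center = eq$edu_center,
         beta0 = unname(beta[1]),
         beta_age = unname(beta[2]),
         beta_edu = unname(beta[3]),
         residual_sd_hat = sqrt(sum(fit$residuals^2) / (nrow(healthy) - 3L)),
         n_healthy = nrow(healthy)),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "Normative correction fit (basis of '%s', %d healthy individuals)\n",
    x$equation_id, x$n_healthy))
  cat(sprintf("  beta0 = %.4f, beta_age = %.6g, beta_edu = %.6g\n",
              x$beta0, x$beta_age, x$beta_edu))
  cat(sprintf("  residual SD = %.4f points\n", x$residual_sd_hat))
  invisible(x)
}

#' Predicted healthy mean score under a fitted correction model
#'
#' @param model A [fit_normative()] result.
#' @param age,edu Vectors of ages and education years.
#' @return Predicted raw score of a healthy peer of that age/education.
#' @export
predict_normative <- function(model, age, edu) {
  stopifnot(inherits(model, "correction_model"))
  model$beta0 +
    model$beta_age * (age_transform(model$age_basis, age) - model$age_center) +
    model$beta_edu * (edu_transform(model$edu_basis, edu) - model$edu_center)
}

#' Apply the age-education correction to a cohort
#'
#' The corrected score compares each individual to a healthy peer of the
#' same age and education:
#' \deqn{corrected = raw - \widehat{y}(age, edu) + \beta_0}
#' i.e. the raw score minus the model prediction plus the fitted
#' intercept, so that the healthy population mean is preserved.  Corrected
#' scores are never rounded or clipped.  In rank terms this is equivalent
#' to the usual Z-score correction, since the residual SD is constant.
#'
#' @param cohort A cohort with `raw_score` set (any mix of statuses).
#' @param model A [fit_normative()] result.
#' @return The cohort with a `corrected_score` column added.
#' @export
apply_correction <- function(cohort, model) {
  stopifnot(inherits(cohort, "moca_cohort"),
            inherits(model, "correction_model"))
  if (is.null(cohort$raw_score)) {
    stop("cohort has no raw scores to correct")
  }
  pred <- predict_normative(model, cohort$age, cohort$edu_years)
  cohort$corrected_score <- cohort$raw_score - pred + model$beta0
  cohort
}
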