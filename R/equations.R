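#' Published normative equations for mean MoCA scores
#'
#' Four regression models of the mean raw MoCA score among cognitively
#' healthy Italians, each a linear model in a transformed age term and a
#' transformed education term, written in centered form:
#'
#' \deqn{\hat y = \beta_0 + \beta_a (t_a(age) - c_a) + \beta_e (t_e(edu) - c_e)}
#'
#' The four published bases are: `aiello` (cubic age, natural-log
#' education), `conti` (linear age, reciprocal education), `santangelo`
#' (log10 of 100 minus age, square-root education), and `montemurro`
#' (linear age and education).  Evaluating any equation at its centering
#' constants returns exactly its printed intercept.
#'
#' @param id One of `"aiello"`, `"conti"`, `"santangelo"`, `"montemurro"`.
#' @return An object of class `normative_equation`.
#' @examples
#' eq <- normative_equation("aiello")
#' expected_score(eq, age = 70, edu = 8)
#' @export
normative_equation <- function(id = c("aiello", "conti", "santangelo",
                                      "montemurro")) {
  id <- match.arg(id)
  .equation_registry[[id]]
}

#' Construct a custom normative equation
#'
#' Assemble a `normative_equation` from basis names and coefficients.
#' Mainly useful for controlled experiments, e.g. an equation with zero
#' covariate coefficients to remove all age and education effects from
#' the score-generating process.
#'
#' @param id Name for the equation.
#' @param age_basis One of `"cubic"`, `"identity"`, `"log10_100_minus_age"`.
#' @param edu_basis One of `"log"`, `"reciprocal"`, `"sqrt"`, `"identity"`.
#' @param intercept,age_coefficient,edu_coefficient,age_center,edu_center
#'   Real coefficients of the centered linear form.
#' @return An object of class `normative_equation`.
#' @export
new_normative_equation <- function(id, age_basis, edu_basis, intercept,
                                   age_coefficient, edu_coefficient,
                                   age_center, edu_center) {
  age_basis <- match.arg(age_basis,
                         c("cubic", "identity", "log10_100_minus_age"))
  edu_basis <- match.arg(edu_basis,
                         c("log", "reciprocal", "sqrt", "identity"))
  stopifnot(is.numeric(intercept), is.numeric(age_coefficient),
            is.numeric(edu_coefficient), is.numeric(age_center),
            is.numeric(edu_center))
  structure(
    list(id = id, age_basis = age_basis, edu_basis = edu_basis,
         intercept = intercept,
         age_coefficient = age_coefficient,
         edu_coefficient = edu_coefficient,
         age_center = age_center, edu_center = edu_center),
    class = "normative_equation"
  )
}

.equation_registry <- list(
  aiello = new_normative_equation(
    "aiello", "cubic", "log",
    intercept = 24.17, age_coefficient = -0.000008,
    edu_coefficient = 3.331407,
    age_center = 297697.18, edu_center = 2.325648),
  conti = new_normative_equation(
    "conti", "identity", "reciprocal",
    intercept = 23.28, age_coefficient = -0.175, edu_coefficient = -24.3,
    age_center = 70.08, edu_center = 0.126),
  santangelo = new_normative_equation(
    "santangelo", "log10_100_minus_age", "sqrt",
    intercept = 21.98, age_coefficient = 4.228, edu_coefficient = 3.201,
    age_center = 1.58, edu_center = 3.25),
  montemurro = new_normative_equation(
    "montemurro", "identity", "identity",
    intercept = 25.468, age_coefficient = -0.089, edu_coefficient = 0.187,
    age_center = 67.086, edu_center = 11.245)
)

#' @export
print.normative_equation <- function(x, ...) {
  cat(sprintf(
    "Normative equation '%s':\n  %.6g + %.6g * (%s(age) - %.6g) + %.6g * (%s(edu) - %.6g)\n",
    x$id, x$intercept, x$age_coefficient, x$age_basis, x$age_center,
    x$edu_coefficient, x$edu_basis, x$edu_center))
  invisible(x)
}

# Basis transforms.  Domain violations raise errors rather than NaN.
age_transform <- function(basis, age) {
  switch(basis,
    cubic    = age^3,
    identity = age,
    log10_100_minus_age = {
      if (any(age >= 100)) stop("age must be below 100 for the log10(100 - age) basis")
      log10(100 - age)
    },
    stop("unknown age basis: ", basis)
  )
}

edu_transform <- function(basis, edu) {
  if (basis %in% c("log", "reciprocal", "sqrt") && any(edu <= 0)) {
    stop("education years must be positive for the ", basis, " basis")
  }
  switch(basis,
    log        = log(edu),
    reciprocal = 1 / edu,
    sqrt       = sqrt(edu),
    identity   = edu,
    stop("unknown education basis: ", basis)
  )
}

#' Expected raw score of a healthy individual
#'
#' Evaluates a normative equation at given age and education, i.e. the
#' model mean raw MoCA score for a cognitively healthy person.  No
#' rounding or clipping is applied.
#'
#' @param eq A [normative_equation()].
#' @param age Age in years (vectorized).
#' @param edu Completed education in years (vectorized).
#' @return Numeric vector of expected scores in points.
#' @export
expected_score <- function(eq, age, edu) {
  stopifnot(inherits(eq, "normative_equation"))
  eq$intercept +
    eq$age_coefficient * (age_transform(eq$age_basis, age) - eq$age_center) +
    eq$edu_coefficient * (edu_transform(eq$edu_basis, edu) - eq$edu_center)
}
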