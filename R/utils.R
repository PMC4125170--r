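#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis rbinom rnorm runif quantile pchisq qchisq
#'   glm binomial coef vcov sd var cov aggregate uniroot kmeans predict
#'   setNames complete.cases dnorm pnorm
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

#' Five-year age bins of the reference grid
#'
#' Ages are binned into twelve half-open five-year intervals
#' \code{[20,25), [25,30), ..., [70,75)} with a terminal open-ended
#' \code{[75, Inf)} bin, so that crossing with the two sexes yields the
#' 24 reference groups used per cluster.
#'
#' @param age Numeric vector of ages in years; all values must be >= 20.
#' @return Integer vector of bin indices in 1..12.
#' @export
#' @examples
#' age_bin(c(20, 24.9, 25, 74, 75, 90))
age_bin <- function(age) {
  if (any(!is.finite(age)) || any(age < 20))
    stop_domain("age must be finite and >= 20 (got %s)",
                paste(utils::head(age[!is.finite(age) | age < 20], 3), collapse = ", "))
  pmin(floor((age - 20) / 5) + 1L, 12L)
}

age_bin_labels <- function() {
  c(sprintf("[%d,%d)", seq(20, 70, 5), seq(25, 75, 5)), "[75,Inf)")
}

# canonical cohort column order
COHORT_COLS <- c("id", "age", "sex", "bmi", "waist", "sbp", "dbp",
                 "glu", "chol", "tg", "hdl", "ldl", "psh", "diabetes")

CONT_VARS <- c("age", "bmi", "waist", "sbp", "dbp", "glu", "chol", "tg",
               "hdl", "ldl")

#' The nine default risk variables
#'
#' The shipped default variable set for the cluster-conditional logistic
#' models and the clustering step: age, sex, BMI, waist, CHOL, TG, HDL,
#' DBP and family history (PSH). Fasting glucose is deliberately absent --
#' it is consumed by the absolute glycemia criterion of the stratifier,
#' not by the probability model.
#'
#' @return Character vector of length nine.
#' @export
default_risk_variables <- function() {
  c("age", "sex", "bmi", "waist", "chol", "tg", "hdl", "dbp", "psh")
}
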