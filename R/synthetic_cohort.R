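# Synthetic cohort generation -------------------------------------------
#
# A baseline cohort of adults (>= 20 y) with correlated anthropometric and
# blood-chemistry covariates drawn per sex from a truncated multivariate
# normal, a latent 3-cluster mixture, a prevalence-calibrated diabetes
# label, and a 6-year incident-diabetes follow-up process.

default_correlation <- function() {
  vars <- CONT_VARS
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  set2 <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set2("age", "bmi", .10);  set2("age", "waist", .20); set2("age", "sbp", .35)
  set2("age", "dbp", .20);  set2("age", "glu", .15);   set2("age", "chol", .20)
  set2("age", "tg", .05);   set2("age", "ldl", .20)
  set2("bmi", "waist", .80); set2("bmi", "sbp", .25);  set2("bmi", "dbp", .25)
  set2("bmi", "glu", .20);  set2("bmi", "chol", .15);  set2("bmi", "tg", .30)
  set2("bmi", "hdl", -.25); set2("bmi", "ldl", .15)
  set2("waist", "sbp", .25); set2("waist", "dbp", .25); set2("waist", "glu", .20)
  set2("waist", "chol", .15); set2("waist", "tg", .30); set2("waist", "hdl", -.25)
  set2("waist", "ldl", .15)
  set2("sbp", "dbp", .70);  set2("sbp", "glu", .10);   set2("sbp", "chol", .10)
  set2("sbp", "tg", .10);   set2("sbp", "hdl", -.05);  set2("sbp", "ldl", .10)
  set2("dbp", "glu", .10);  set2("dbp", "chol", .10);  set2("dbp", "tg", .10)
  set2("dbp", "hdl", -.05); set2("dbp", "ldl", .10)
  set2("glu", "chol", .10); set2("glu", "tg", .20);    set2("glu", "hdl", -.10)
  set2("glu", "ldl", .10)
  set2("chol", "tg", .30);  set2("chol", "hdl", .15);  set2("chol", "ldl", .85)
  set2("tg", "hdl", -.40);  set2("tg", "ldl", .20)
  set2("hdl", "ldl", -.05)
  R
}

default_moments <- function() {
  # per-sex means and SDs of the model population (men n=8624, women n=6613);
  # LDL is not tabulated with the others and carries assumed values.
  data.frame(
    variable = CONT_VARS,
    mean_male   = c(46.52, 24.19, 84.87, 121.0, 78.80, 4.91, 4.82, 1.61, 1.26, 2.95),
    sd_male     = c(16.20,  3.60,  9.50,  16.0, 10.20, 0.62, 0.95, 1.26, 0.30, 0.85),
    mean_female = c(47.47, 23.31, 76.57, 115.6, 74.58, 4.90, 4.97, 1.39, 1.47, 3.05),
    sd_female   = c(14.80,  4.10,  9.80,  18.0, 10.30, 0.61, 1.10, 1.00, 0.34, 0.90),
    floor       = c(20.0,  13.0,  50.0,  70.0, 40.0, 2.5, 1.5, 0.2, 0.4, 0.5),
    stringsAsFactors = FALSE
  )
}

default_displacements <- function() {
  # standardized-unit shifts of the three latent subpopulations:
  # 1 = general metabolic status, 2 = aging pattern, 3 = elevated risk profile
  d <- matrix(0, 3, length(CONT_VARS), dimnames = list(NULL, CONT_VARS))
  d[2, c("age", "sbp", "dbp", "chol", "glu")] <- c(1.2, 0.4, 0.2, 0.3, 0.2)
  d[3, c("age", "bmi", "waist", "tg", "sbp", "dbp", "glu", "chol", "hdl")] <-
    c(0.2, 0.9, 0.9, 0.9, 0.5, 0.5, 0.5, 0.5, -0.6)
  d
}

default_risk_coefficients <- function() {
  # true risk process on standardized continuous covariates plus sex/psh;
  # drives both the prevalent-diabetes label and the incident process
  c(age = 0.9, bmi = 0.2, waist = 0.35, sbp = 0.1, dbp = 0.2, glu = 1.1,
    chol = 0.15, tg = 0.3, hdl = -0.3, ldl = 0.05, sex = 0.15, psh = 0.6)
}

#' Specification of a synthetic study cohort
#'
#' Collects every parameter of the synthetic-data process: per-sex covariate
#' moments, physiologic floors, the covariate correlation matrix, the latent
#' cluster mixture, family-history prevalence, the baseline diabetes
#' prevalence, the true logistic risk process and the follow-up horizon.
#' Defaults reproduce the published characteristics of the model population
#' (per-sex means/SDs, PSH prevalence 13.73\% in men and 17.8\% in women,
#' overall prevalence 1009/16246) with declared assumptions for what is not
#' published (the correlation structure, the LDL moments, the latent-cluster
#' displacement vectors).
#'
#' @param n_subjects Number of subjects to generate.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param sex_fraction_male Proportion of men.
#' @param moments Data frame with columns \code{variable}, \code{mean_male},
#'   \code{sd_male}, \code{mean_female}, \code{sd_female}, \code{floor}.
#' @param correlation Positive-definite covariate correlation matrix over the
#'   ten continuous variables (shared across sexes).
#' @param psh_prevalence Named vector \code{c(male=, female=)} of
#'   family-history prevalence.
#' @param n_latent_clusters Number of latent subpopulations.
#' @param cluster_props Mixture proportions (length \code{n_latent_clusters}).
#' @param cluster_displacements Matrix (clusters x variables) of standardized
#'   mean shifts; they are re-centred so marginal moments are preserved.
#' @param prevalence Baseline diabetes prevalence to calibrate the label to.
#' @param risk_coefficients Named coefficients of the true logistic risk
#'   process on standardized covariates (plus \code{sex}, \code{psh}).
#' @param followup_years Follow-up horizon in years.
#' @param incidence_rate True average incidence, cases per person-year, used
#'   to calibrate the incident process intercept.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 16246, seed = 1,
                        sex_fraction_male = 8624 / 15237,
                        moments = default_moments(),
                        correlation = default_correlation(),
                        psh_prevalence = c(male = 0.1373, female = 0.178),
                        n_latent_clusters = 3,
                        cluster_props = c(0.55, 0.25, 0.20),
                        cluster_displacements = default_displacements(),
                        prevalence = 1009 / 16246,
                        risk_coefficients = default_risk_coefficients(),
                        followup_years = 6,
                        incidence_rate = 4.5 / 1000) {
  spec <- list(n_subjects = n_subjects, seed = as.integer(seed),
               sex_fraction_male = sex_fraction_male, moments = moments,
               correlation = correlation, psh_prevalence = psh_prevalence,
               n_latent_clusters = n_latent_clusters,
               cluster_props = cluster_props / sum(cluster_props),
               cluster_displacements = cluster_displacements,
               prevalence = prevalence,
               risk_coefficients = risk_coefficients,
               followup_years = followup_years,
               incidence_rate = incidence_rate)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  m <- spec$moments
  if (any(m$sd_male <= 0) || any(m$sd_female <= 0))
    stop_domain("all covariate SDs must be > 0")
  props <- c(spec$sex_fraction_male, spec$psh_prevalence, spec$prevalence)
  if (any(props < 0 | props > 1))
    stop_domain("proportions must lie in [0, 1]")
  if (spec$n_subjects < 0)
    stop_domain("n_subjects must be >= 0")
  R <- spec$correlation
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)))
    stop_domain("correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_domain("correlation matrix must be positive definite (min eigenvalue %.3g)",
                min(ev))
  if (spec$followup_years <= 0) stop_domain("followup_years must be > 0")
  invisible(spec)
}

# Underlying location of a left-truncated normal whose truncated mean
# matches the target mean (scale kept at the target SD; the matching is
# only solved when the floor is close enough to bias the mean).
truncnorm_match <- function(m, s, a) {
  m <- as.numeric(m)[1]; s <- as.numeric(s)[1]; a <- as.numeric(a)[1]
  if (a < m - 4 * s) return(c(mu = m, sigma = s))
  trunc_mean <- function(mu) {
    alpha <- (a - mu) / s
    lam <- exp(dnorm(alpha, log = TRUE) -
                 pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
    mu + s * lam
  }
  mu <- uniroot(function(mu) trunc_mean(mu) - m,
                lower = m - 30 * s, upper = m, tol = 1e-10)$root
  c(mu = mu, sigma = s)
}

standardized_covariates <- function(cohort, spec) {
  # covariates standardized with the spec's target per-sex moments
  m <- spec$moments
  out <- matrix(0, nrow(cohort), length(CONT_VARS),
                dimnames = list(NULL, CONT_VARS))
  male <- cohort$sex == 1
  for (j in seq_along(CONT_VARS)) {
    v <- CONT_VARS[j]
    out[, j] <- ifelse(male,
                       (cohort[[v]] - m$mean_male[j]) / m$sd_male[j],
                       (cohort[[v]] - m$mean_female[j]) / m$sd_female[j])
  }
  out
}

risk_linear_predictor <- function(cohort, spec) {
  z <- standardized_covariates(cohort, spec)
  b <- spec$risk_coefficients
  lp <- rep(0, nrow(cohort))
  for (v in names(b)) {
    lp <- lp + b[[v]] * switch(v,
      sex = cohort$sex, psh = cohort$psh, z[, v])
  }
  lp
}

calibrate_intercept <- function(lp, target, forced = rep(FALSE, length(lp))) {
  # intercept b0 so that mean(forced | bernoulli(plogis(b0 + lp))) == target
  free <- !forced
  n <- length(lp)
  n_forced <- sum(forced)
  if (n_forced / n >= target) return(-Inf)
  f <- function(b0) (n_forced + sum(plogis(b0 + lp[free]))) / n - target
  uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
}

#' Generate a synthetic baseline cohort
#'
#' Covariates are drawn per sex from a multivariate normal with the spec's
#' correlation matrix, shifted by re-centred latent-cluster displacement
#' vectors, and truncated at physiologic floors by row-wise rejection
#' resampling (the age marginal is pre-adjusted so that its post-truncation
#' mean and SD match the target moments). Prevalent diabetes combines the
#' diagnostic rule (fasting glucose > 7.0 mmol/L) with a Bernoulli draw from
#' the true logistic risk process, whose intercept is recalibrated so the
#' marginal prevalence matches the spec.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns \code{id, age, sex, bmi, waist, sbp,
#'   dbp, glu, chol, tg, hdl, ldl, psh, diabetes} (sex: 1 = male, 0 = female;
#'   psh and diabetes are 0/1). The latent cluster index is attached as
#'   attribute \code{"latent_cluster"}.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  empty <- data.frame(id = character(), age = numeric(), sex = integer(),
                      bmi = numeric(), waist = numeric(), sbp = numeric(),
                      dbp = numeric(), glu = numeric(), chol = numeric(),
                      tg = numeric(), hdl = numeric(), ldl = numeric(),
                      psh = integer(), diabetes = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  m <- spec$moments
  p <- length(CONT_VARS)
  set.seed(spec$seed)
  sex <- rbinom(n, 1, spec$sex_fraction_male)
  latent <- sample.int(spec$n_latent_clusters, n, replace = TRUE,
                       prob = spec$cluster_props)
  # re-centre displacements so marginal moments are preserved
  d <- spec$cluster_displacements
  d <- sweep(d, 2, colSums(d * spec$cluster_props), "-")

  draw_sex <- function(idx, mu, sigma, offset_seed) {
    # Component-wise moment matching: for each (variable, latent cluster)
    # the underlying normal parameters are adjusted so the left-truncated
    # component keeps the displaced target mean/SD; with re-centred
    # displacements the marginal mean then matches the spec mean.
    set.seed(spec$seed + offset_seed)
    nc <- spec$n_latent_clusters
    mu_adj <- sig_adj <- matrix(NA_real_, nc, p, dimnames = list(NULL, CONT_VARS))
    for (j in seq_len(p)) for (cc in seq_len(nc)) {
      ms <- truncnorm_match(mu[j] + sigma[j] * d[cc, j], sigma[j], m$floor[j])
      mu_adj[cc, j] <- ms[["mu"]]; sig_adj[cc, j] <- ms[["sigma"]]
    }
    k <- length(idx)
    z <- MASS::mvrnorm(k, mu = rep(0, p), Sigma = spec$correlation)
    z <- matrix(z, ncol = p)
    cc <- latent[idx]
    x <- mu_adj[cc, , drop = FALSE] + sig_adj[cc, , drop = FALSE] * z
    colnames(x) <- CONT_VARS
    # Exact per-coordinate truncation: entries below the floor are resampled
    # from the left-truncated normal by inverse CDF, so each marginal is
    # exactly the matched truncated normal. (Resampled entries lose their
    # correlation with the other coordinates; see the methods vignette.)
    for (j in seq_len(p)) {
      viol <- which(x[, j] < m$floor[j])
      if (!length(viol)) next
      muv <- mu_adj[cc[viol], j]; sgv <- sig_adj[cc[viol], j]
      alpha <- (m$floor[j] - muv) / sgv
      u <- runif(length(viol), pnorm(alpha), 1)
      x[viol, j] <- muv + sgv * stats::qnorm(pmin(u, 1 - 1e-16))
    }
    x
  }

  x <- matrix(NA_real_, n, p, dimnames = list(NULL, CONT_VARS))
  im <- which(sex == 1); if_ <- which(sex == 0)
  if (length(im))
    x[im, ] <- draw_sex(im, m$mean_male, m$sd_male, 101L)
  if (length(if_))
    x[if_, ] <- draw_sex(if_, m$mean_female, m$sd_female, 202L)

  set.seed(spec$seed + 303L)
  psh <- rbinom(n, 1, ifelse(sex == 1, spec$psh_prevalence[["male"]],
                             spec$psh_prevalence[["female"]]))

  cohort <- data.frame(id = sprintf("S%06d", seq_len(n)), age = x[, "age"],
                       sex = sex, x[, setdiff(CONT_VARS, "age")],
                       psh = psh, diabetes = 0L, stringsAsFactors = FALSE)
  cohort <- cohort[, COHORT_COLS]

  # prevalent diabetes: diagnostic glucose rule plus calibrated risk process
  set.seed(spec$seed + 404L)
  lp <- risk_linear_predictor(cohort, spec)
  forced <- cohort$glu > 7.0
  b0 <- calibrate_intercept(lp, spec$prevalence, forced)
  pr <- ifelse(forced, 1, plogis(b0 + lp))
  cohort$diabetes <- as.integer(runif(n) < pr)
  attr(cohort, "latent_cluster") <- latent
  cohort
}

#' Generate follow-up outcomes for a baseline cohort
#'
#' One record per baseline non-diabetic subject. The probability of incident
#' diabetes over the follow-up horizon is the true logistic risk process
#' evaluated at baseline covariates, with the intercept recalibrated so the
#' expected cumulative incidence equals \code{incidence_rate *
#' followup_years}.
#'
#' @param cohort A baseline cohort from [generate_cohort()].
#' @param spec The [cohort_spec()] that produced it.
#' @return Data frame with columns \code{id}, \code{incident_diabetes} (0/1)
#'   and \code{years_observed}.
#' @export
generate_followup <- function(cohort, spec) {
  if (!nrow(cohort)) stop_domain("cohort is empty")
  at_risk <- cohort[cohort$diabetes == 0, , drop = FALSE]
  if (!nrow(at_risk)) {
    warning("no baseline non-diabetic subjects; empty follow-up returned")
    return(data.frame(id = character(), incident_diabetes = integer(),
                      years_observed = numeric(), stringsAsFactors = FALSE))
  }
  target <- min(spec$incidence_rate * spec$followup_years, 0.999)
  set.seed(spec$seed + 505L)
  lp <- risk_linear_predictor(at_risk, spec)
  b0 <- calibrate_intercept(lp, target)
  pr <- plogis(b0 + lp)
  data.frame(id = at_risk$id,
             incident_diabetes = as.integer(runif(nrow(at_risk)) < pr),
             years_observed = spec$followup_years,
             stringsAsFactors = FALSE)
}
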