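# Model validation -------------------------------------------------------
#
# Two instruments: (1) jackknife leave-one-out accuracy of the three-way
# categorization (non-risk / different-risk / diabetes), where each subject
# is assessed by a model trained without them and scored against the
# category the full-data model assigns; (2) person-year incidence of
# diabetes by baseline category over the follow-up horizon, with exact
# Poisson (Garwood) confidence intervals.

#' Collapse four-tier categories to the three-way validation classes
#'
#' Low, medium and high risk collapse to \code{"different-risk"}; prevalent
#' diabetics are \code{"diabetes"} whatever their nominal category.
#'
#' @param assessment Data frame from [assess_risk()].
#' @return Character vector over \code{"non-risk"}, \code{"different-risk"},
#'   \code{"diabetes"}.
#' @export
collapse_category <- function(assessment) {
  ifelse(assessment$prevalent_diabetes, "diabetes",
         ifelse(assessment$category == "non", "non-risk", "different-risk"))
}

#' Jackknife leave-one-out accuracy of the risk categorization
#'
#' For each subject, a model is trained on the other n - 1 subjects and the
#' held-out subject is assessed; the prediction is correct when its
#' collapsed three-way class equals the class assigned by the model trained
#' on all n subjects. Two refit modes: \code{"logits"} (default) freezes
#' the cluster partition and rule thresholds of the full-data model and
#' refits the per-cluster logistic models and reference grid on each fold
#' (the dominant source of leave-one-out variation); \code{"full"} retrains
#' the entire pipeline (clustering included) on every fold. Folds whose
#' model cannot be fitted are recorded as incorrect.
#'
#' @param cohort Cohort to validate on.
#' @param config A [pipeline_config()]; \code{select_cutoff} is forced off
#'   so the RR cutoff is a fixed constant across folds.
#' @param mode \code{"logits"} or \code{"full"}.
#' @param indices Row indices of the subjects to hold out and evaluate;
#'   default all of them. Each fold still trains on the other n - 1
#'   subjects of the full cohort, so a subsample of folds estimates the
#'   same leave-one-out accuracy at reduced cost.
#' @return Object of class \code{jackknife_result}: list with
#'   \code{n_evaluations}, \code{n_correct}, \code{accuracy},
#'   \code{confusion} (3 x 3 table, reference in rows).
#' @export
jackknife_accuracy <- function(cohort, config = pipeline_config(),
                               mode = c("logits", "full"),
                               indices = seq_len(nrow(cohort))) {
  mode <- match.arg(mode)
  n <- nrow(cohort)
  if (n < 10) stop_domain("need at least 10 subjects")
  config$select_cutoff <- FALSE
  config$run_selection <- FALSE
  ref_model <- train_risk_model(cohort, config)
  ref_class <- collapse_category(assess_risk(cohort, ref_model))
  classes <- c("non-risk", "different-risk", "diabetes")
  pred_class <- rep(NA_character_, n)
  for (i in indices) {
    rest <- cohort[-i, , drop = FALSE]
    pred_class[i] <- tryCatch({
      fold_model <- if (mode == "full") {
        train_risk_model(rest, config)
      } else {
        asg <- ref_model$cluster_model$assignments[-i]
        logits <- fit_cluster_logits(rest, asg, config$variables,
                                     hl_groups = config$hl_groups)
        grid <- build_reference_grid(rest, asg, logits, config$variables)
        fold <- ref_model
        fold$logits <- logits
        fold$grid <- grid
        fold
      }
      collapse_category(assess_risk(cohort[i, , drop = FALSE], fold_model))
    }, error = function(e) {
      warning("fold ", i, " failed: ", conditionMessage(e))
      NA_character_
    })
  }
  correct <- !is.na(pred_class[indices]) &
    pred_class[indices] == ref_class[indices]
  confusion <- table(factor(ref_class[indices], levels = classes),
                     factor(pred_class[indices], levels = classes),
                     dnn = c("reference", "predicted"))
  out <- list(n_evaluations = length(indices), n_correct = sum(correct),
              accuracy = sum(correct) / length(indices), confusion = confusion,
              mode = mode)
  class(out) <- "jackknife_result"
  out
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("Jackknife (%s refit): %d/%d correct, accuracy %.2f%%\n",
              x$mode, x$n_correct, x$n_evaluations, 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

# Exact Poisson (Garwood) CI for a count, scaled to a rate per 1000 PY.
poisson_rate_ci <- function(cases, person_years, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (cases == 0) 0 else qchisq(a, 2 * cases) / 2
  hi <- qchisq(1 - a, 2 * cases + 2) / 2
  c(lower = 1000 * lo / person_years, upper = 1000 * hi / person_years)
}

#' Person-year incidence of diabetes by baseline risk category
#'
#' Assumes complete follow-up (person-years = persons x years) and reports
#' cases per 1000 person-years with exact Poisson 95 percent confidence
#' intervals, per category plus a total row.
#'
#' @param baseline_categories Data frame with columns \code{id} and
#'   \code{category}.
#' @param followup Data frame with columns \code{id},
#'   \code{incident_diabetes} and optionally \code{years_observed}.
#' @param years Follow-up horizon used when \code{years_observed} is absent.
#' @return Data frame with \code{category}, \code{n_baseline}, \code{cases},
#'   \code{person_years}, \code{rate} (per 1000 PY), \code{rate_display}
#'   (1-decimal rounding), \code{ci_low}, \code{ci_high}.
#' @export
incidence_table <- function(baseline_categories, followup, years = 6) {
  if (years <= 0) stop_domain("years must be > 0")
  m <- match(followup$id, baseline_categories$id)
  if (anyNA(m))
    stop_domain("follow-up id(s) without baseline category: %s",
                paste(utils::head(followup$id[is.na(m)], 3), collapse = ", "))
  cat_f <- as.character(baseline_categories$category[m])
  yrs <- followup$years_observed %||% rep(years, nrow(followup))
  if (is.null(followup$years_observed)) yrs <- rep(years, nrow(followup))
  lev <- intersect(c("non", "low", "medium", "high"), unique(cat_f))
  lev <- c(lev, setdiff(unique(cat_f), lev))
  one_row <- function(name, sel) {
    n <- sum(sel); cases <- sum(followup$incident_diabetes[sel])
    py <- sum(yrs[sel])
    ci <- if (py > 0) poisson_rate_ci(cases, py) else c(lower = NA, upper = NA)
    rate <- if (py > 0) 1000 * cases / py else NA_real_
    data.frame(category = name, n_baseline = n, cases = cases,
               person_years = py, rate = rate,
               rate_display = round(rate, 1),
               ci_low = unname(ci["lower"]), ci_high = unname(ci["upper"]),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(lev, function(cc) one_row(cc, cat_f == cc))
  rows <- c(rows, list(one_row("total", rep(TRUE, nrow(followup)))))
  do.call(rbind, rows)
}
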