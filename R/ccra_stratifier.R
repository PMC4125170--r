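# Comprehensive risk assessment (CCRA) ----------------------------------
#
# Three-step cascade assigning one of four categories:
#   (1) absolute criterion: fasting glucose above the glycemia cutoff
#       (5.85 mmol/L) -> high risk;
#   (2) relative criterion: relative risk at or below the RR cutoff (2.2)
#       -> non risk;
#   (3) cluster rules: count how many of the cluster's threshold criteria
#       (degree 0-3) the subject satisfies; 3 -> high, 2 -> medium,
#       1 -> low (0 with elevated RR also maps to low).

#' The published criteria of the first (largest) cluster
#'
#' BMI > 26.8 kg/m^2, CHOL > 5.18 mmol/L, TG > 1.7 mmol/L. All comparators
#' are strict.
#'
#' @return List of criterion descriptors.
#' @export
cluster1_criteria <- function() {
  list(list(variable = "bmi", op = ">", threshold = 26.8),
       list(variable = "chol", op = ">", threshold = 5.18),
       list(variable = "tg", op = ">", threshold = 1.7))
}

#' Construct a rule set
#'
#' @param rules Named list (cluster index as name) of criterion lists; each
#'   criterion is \code{list(variable, op, threshold)} with strict
#'   comparators \code{">"} or \code{"<"}.
#' @param glu_cutoff Absolute glycemia cutoff (mmol/L).
#' @param rr_cutoff Relative-risk cutoff.
#' @param degree_map Named map from degree (0-3) to category; the default
#'   assigns degree 0 with elevated RR to low risk.
#' @param source Character tag recording how the rules were obtained
#'   (\code{"published"} or \code{"derived"}).
#' @return Object of class \code{ccra_ruleset}.
#' @export
ccra_ruleset <- function(rules, glu_cutoff = 5.85, rr_cutoff = 2.2,
                         degree_map = c(`0` = "low", `1` = "low",
                                        `2` = "medium", `3` = "high"),
                         source = "published") {
  stopifnot(glu_cutoff > 0, rr_cutoff > 0)
  for (cl in rules) for (cr in cl)
    if (cr$threshold <= 0) stop_domain("rule thresholds must be positive")
  structure(list(rules = rules, glu_cutoff = glu_cutoff,
                 rr_cutoff = rr_cutoff, degree_map = degree_map,
                 source = source),
            class = "ccra_ruleset")
}

#' Default rule set
#'
#' Applies the published first-cluster criteria to every cluster that has no
#' rules of its own; used when no training data are available to derive
#' cluster-specific thresholds.
#'
#' @param k Number of clusters.
#' @inheritParams ccra_ruleset
#' @return A \code{ccra_ruleset}.
#' @export
default_ruleset <- function(k = 3, glu_cutoff = 5.85, rr_cutoff = 2.2) {
  rules <- setNames(rep(list(cluster1_criteria()), k), as.character(seq_len(k)))
  ccra_ruleset(rules, glu_cutoff, rr_cutoff, source = "published")
}

#' Derive cluster-specific rules from training data
#'
#' Cluster 1 (the largest) keeps the published criteria; the criteria of the
#' remaining clusters are unpublished and are reconstructed as the cluster's
#' 75th percentiles of BMI, CHOL and TG among non-diabetic members. Derived
#' rules are tagged \code{source = "derived"} and are fully overridable.
#'
#' @param cohort Training cohort.
#' @param assignments Cluster index per row.
#' @param variables Rule variables (default BMI, CHOL, TG).
#' @param prob Quantile used for derived thresholds.
#' @param cluster1_published Keep the published thresholds for cluster 1.
#' @inheritParams ccra_ruleset
#' @return A \code{ccra_ruleset}.
#' @export
derive_ruleset <- function(cohort, assignments,
                           variables = c("bmi", "chol", "tg"), prob = 0.75,
                           cluster1_published = TRUE,
                           glu_cutoff = 5.85, rr_cutoff = 2.2) {
  ks <- sort(unique(assignments))
  nondiab <- if ("diabetes" %in% names(cohort)) cohort$diabetes == 0
             else rep(TRUE, nrow(cohort))
  rules <- list()
  for (k in ks) {
    if (k == 1 && cluster1_published) {
      rules[[as.character(k)]] <- cluster1_criteria()
      next
    }
    dat <- cohort[assignments == k & nondiab, , drop = FALSE]
    rules[[as.character(k)]] <- lapply(variables, function(v)
      list(variable = v, op = ">",
           threshold = unname(quantile(dat[[v]], prob))))
  }
  ccra_ruleset(rules, glu_cutoff, rr_cutoff, source = "derived")
}

#' Count satisfied cluster criteria
#'
#' @param subjects Data frame; must contain every rule variable.
#' @param criteria List of criterion descriptors for one cluster.
#' @return Integer vector of degrees (number of criteria satisfied).
#' @export
evaluate_degree <- function(subjects, criteria) {
  deg <- integer(nrow(subjects))
  for (cr in criteria) {
    if (!cr$variable %in% names(subjects))
      stop_domain("missing rule variable '%s'", cr$variable)
    hit <- switch(cr$op,
                  ">" = subjects[[cr$variable]] > cr$threshold,
                  "<" = subjects[[cr$variable]] < cr$threshold,
                  stop_domain("unsupported comparator '%s'", cr$op))
    deg <- deg + as.integer(hit)
  }
  deg
}

#' Assess subjects with a trained model and rule set
#'
#' Runs the full CCRA cascade on each subject. Prevalent diabetics are
#' flagged (and excluded from category counts by [stratify_cohort()]) but
#' still receive a relative risk and a category.
#'
#' @param subjects Data frame of subjects.
#' @param model A trained model from [train_risk_model()], or a list with
#'   elements \code{cluster_model}, \code{logits}, \code{grid},
#'   \code{ruleset}.
#' @param ruleset Optional \code{ccra_ruleset} overriding the model's.
#' @return Data frame with \code{id}, \code{cluster}, \code{rr},
#'   \code{glu_flag}, \code{degree}, \code{category} (factor non < low <
#'   medium < high), \code{prevalent_diabetes}.
#' @export
assess_risk <- function(subjects, model, ruleset = NULL) {
  ruleset <- ruleset %||% model$ruleset
  if (is.null(ruleset)) stop_domain("no rule set supplied")
  rr <- compute_rr(subjects, model$cluster_model, model$logits, model$grid)
  if (!nrow(rr))
    return(data.frame(id = character(), cluster = integer(), rr = numeric(),
                      glu_flag = logical(), degree = integer(),
                      category = factor(character(),
                                        levels = c("non", "low", "medium", "high")),
                      prevalent_diabetes = logical(), stringsAsFactors = FALSE))
  glu_flag <- subjects$glu > ruleset$glu_cutoff
  degree <- integer(nrow(subjects))
  for (k in sort(unique(rr$cluster))) {
    sel <- rr$cluster == k
    crit <- ruleset$rules[[as.character(k)]] %||% cluster1_criteria()
    degree[sel] <- evaluate_degree(subjects[sel, , drop = FALSE], crit)
  }
  category <- ifelse(glu_flag, "high",
                     ifelse(rr$rr <= ruleset$rr_cutoff, "non",
                            unname(ruleset$degree_map[as.character(degree)])))
  data.frame(id = rr$id, cluster = rr$cluster, rr = rr$rr,
             glu_flag = glu_flag, degree = degree,
             category = factor(category,
                               levels = c("non", "low", "medium", "high")),
             prevalent_diabetes = rr$prevalent_diabetes,
             stringsAsFactors = FALSE)
}

#' Stratify a cohort into the four risk categories
#'
#' Assesses every subject, tabulates category counts over the non-diabetic
#' population, and summarizes the metabolic profile (mean and SD of the key
#' variables, family-history percentage) per category.
#'
#' @inheritParams assess_risk
#' @param summary_variables Variables summarized per category.
#' @return List with \code{counts} (named integer vector over non/low/
#'   medium/high), \code{n}, \code{summary} (data frame of per-category
#'   means and SDs), \code{assessments} (the per-subject frame).
#' @export
stratify_cohort <- function(subjects, model, ruleset = NULL,
                            summary_variables = c("age", "bmi", "waist",
                                                  "glu", "chol", "tg", "hdl",
                                                  "sbp", "dbp")) {
  a <- assess_risk(subjects, model, ruleset)
  keep <- !a$prevalent_diabetes
  counts <- table(a$category[keep])
  sub <- subjects[keep, , drop = FALSE]
  cats <- levels(a$category)
  summ <- lapply(cats, function(cc) {
    sel <- a$category[keep] == cc
    row <- data.frame(category = cc, n = sum(sel), stringsAsFactors = FALSE)
    for (v in intersect(summary_variables, names(sub))) {
      row[[paste0(v, "_mean")]] <- if (any(sel)) mean(sub[[v]][sel]) else NA_real_
      row[[paste0(v, "_sd")]] <- if (sum(sel) > 1) sd(sub[[v]][sel]) else NA_real_
    }
    if ("psh" %in% names(sub))
      row$psh_pct <- if (any(sel)) 100 * mean(sub$psh[sel]) else NA_real_
    row
  })
  list(counts = setNames(as.integer(counts), names(counts)),
       n = sum(keep), summary = do.call(rbind, summ), assessments = a)
}
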