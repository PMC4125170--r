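# Cluster-conditional risk model ----------------------------------------
#
# One multivariate logistic model per cluster gives each subject an onset
# probability P_k. Non-diabetic subjects are gridded into 24 age-sex groups
# per cluster (12 five-year bins x 2 sexes); the cluster logit evaluated at
# each group's mean covariate vector is the reference probability P_0, and
# a subject's relative risk is RR = P_k / P_0 of the matching cell.

#' Fit one logistic model per cluster
#'
#' @param cohort Data frame including the outcome column.
#' @param assignments Integer cluster index per row of \code{cohort}.
#' @param variables Model variables (default [default_risk_variables()]).
#' @param outcome Binary outcome column name.
#' @param hl_groups Number of Hosmer-Lemeshow risk groups.
#' @return Object of class \code{cluster_logits}: a list (one element per
#'   cluster) of lists with \code{cluster}, \code{coefficients} (named
#'   vector, intercept first), \code{se}, \code{p}, \code{hl}
#'   (statistic/dof/p.value), \code{n}, \code{n_events}.
#' @export
fit_cluster_logits <- function(cohort, assignments,
                               variables = default_risk_variables(),
                               outcome = "diabetes", hl_groups = 10) {
  ks <- sort(unique(assignments))
  out <- lapply(ks, function(k) {
    dat <- cohort[assignments == k, , drop = FALSE]
    y <- dat[[outcome]]
    if (length(unique(y)) < 2)
      stop_domain("cluster %d has a single outcome class; cannot fit", k)
    # a variable that is constant within the cluster (e.g. a binary
    # variable the partition separated on) carries no information there:
    # it is dropped from this cluster's fit and given coefficient zero
    use <- variables[vapply(variables, function(v)
      length(unique(dat[[v]])) > 1, TRUE)]
    dropped <- setdiff(variables, use)
    if (length(dropped))
      message("cluster ", k, ": constant variable(s) dropped from logit: ",
              paste(dropped, collapse = ", "))
    fit <- fit_multivariate_logit(dat, use, outcome)
    if (length(dropped)) {
      cf0 <- fit$coefficients
      add <- data.frame(variable = dropped, beta = 0, se = NA_real_,
                        z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      cf0 <- rbind(cf0, add)
      cf0 <- cf0[match(c("(Intercept)", variables), cf0$variable), ]
      fit$coefficients <- cf0
    }
    pr <- as.numeric(predict(fit$fit, type = "response"))
    hl <- tryCatch(hosmer_lemeshow(pr, y, groups = hl_groups),
                   error = function(e) list(statistic = NA_real_,
                                            dof = NA_integer_,
                                            p.value = NA_real_))
    cf <- fit$coefficients
    list(cluster = k,
         coefficients = setNames(cf$beta, cf$variable),
         se = setNames(cf$se, cf$variable),
         p = setNames(cf$p, cf$variable),
         hl = hl, n = nrow(dat), n_events = sum(y))
  })
  names(out) <- as.character(ks)
  class(out) <- "cluster_logits"
  out
}

logit_linear_predictor <- function(coefficients, data, variables) {
  x <- cbind(`(Intercept)` = 1, as.matrix(data[variables]))
  drop(x %*% coefficients[c("(Intercept)", variables)])
}

#' Evaluate a cluster logit as a probability
#'
#' @param logit One element of a \code{cluster_logits} object.
#' @param data Data frame of subjects.
#' @param variables Model variables in the order used at fit time.
#' @return Vector of probabilities.
#' @export
predict_cluster_logit <- function(logit, data, variables) {
  plogis(logit_linear_predictor(logit$coefficients, data, variables))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into \code{groups} risk strata by quantiles of the
#' predicted probability (deciles of risk by default) and compares observed
#' with expected event counts: the statistic is
#' \code{sum((O - E)^2 / (E (1 - E/n_g)))} over groups, referred to a
#' chi-squared distribution with \code{groups - 2} degrees of freedom.
#' Strata whose expected count vanishes are merged with their neighbour
#' (with a message).
#'
#' @param probabilities Predicted probabilities in (0, 1).
#' @param outcomes Binary outcomes.
#' @param groups Number of risk groups (>= 3).
#' @return List with \code{statistic}, \code{dof}, \code{p.value},
#'   \code{table} (per-group n, observed, expected).
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, groups = 10) {
  if (groups < 3) stop_domain("need at least 3 groups")
  if (any(probabilities <= 0 | probabilities >= 1))
    stop_domain("probabilities must lie strictly in (0, 1)")
  y <- as.integer(outcomes)
  br <- unique(quantile(probabilities, probs = seq(0, 1, length.out = groups + 1)))
  if (length(br) < 3) stop_domain("predicted probabilities are too concentrated to group")
  g <- cut(probabilities, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(n = as.vector(tapply(y, g, length)),
                    observed = as.vector(tapply(y, g, sum)),
                    expected = as.vector(tapply(probabilities, g, sum)),
                    pbar = as.vector(tapply(probabilities, g, mean)))
  # merge degenerate strata into the neighbour above
  while (nrow(tab) > 3 && any(tab$expected < 1e-10 |
                              (tab$n - tab$expected) < 1e-10)) {
    i <- which(tab$expected < 1e-10 | (tab$n - tab$expected) < 1e-10)[1]
    j <- if (i < nrow(tab)) i + 1 else i - 1
    message("hosmer_lemeshow: merging a degenerate risk stratum")
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$pbar[j] <- tab$expected[j] / tab$n[j]
    tab <- tab[-i, , drop = FALSE]
  }
  denom <- tab$n * tab$pbar * (1 - tab$pbar)
  stat <- sum((tab$observed - tab$expected)^2 / denom)
  dof <- nrow(tab) - 2L
  list(statistic = stat, dof = dof,
       p.value = pchisq(stat, dof, lower.tail = FALSE), table = tab)
}

#' Build the age-sex reference grid of average onset probabilities
#'
#' Non-diabetic subjects are partitioned, within each cluster, into 24
#' groups (12 five-year age bins crossed with sex). The cluster's logistic
#' model evaluated at the group's mean covariate vector gives the group's
#' average onset probability P_0 (the logit-at-mean-covariates convention;
#' this is not the mean of the individual probabilities).
#'
#' @param cohort Data frame (full cohort; diabetics are excluded internally).
#' @param assignments Cluster index per row of \code{cohort}.
#' @param logits A \code{cluster_logits} object.
#' @param variables Model variables.
#' @param outcome Prevalence column used to exclude diabetics.
#' @return Object of class \code{reference_grid}: data frame with columns
#'   \code{cluster}, \code{sex}, \code{age_bin}, \code{age_label}, \code{n},
#'   \code{p0}, and the group mean of each model variable (prefix
#'   \code{mean_}). Empty cells carry \code{n = 0} and \code{p0 = NA}.
#' @export
build_reference_grid <- function(cohort, assignments, logits,
                                 variables = default_risk_variables(),
                                 outcome = "diabetes") {
  keep <- cohort[[outcome]] == 0
  sub <- cohort[keep, , drop = FALSE]
  asg <- assignments[keep]
  if (!nrow(sub)) stop_domain("no non-diabetic subjects for the reference grid")
  bins <- age_bin(sub$age)
  labs <- age_bin_labels()
  ks <- sort(unique(as.integer(names(logits))))
  rows <- list()
  for (k in ks) {
    any_cell <- FALSE
    for (sx in c(1, 0)) for (b in 1:12) {
      sel <- asg == k & sub$sex == sx & bins == b
      n <- sum(sel)
      mv <- rep(NA_real_, length(variables))
      p0 <- NA_real_
      if (n > 0) {
        any_cell <- TRUE
        mv <- colMeans(sub[sel, variables, drop = FALSE])
        p0 <- plogis(sum(logits[[as.character(k)]]$coefficients *
                           c(1, mv[variables])))
      }
      row <- data.frame(cluster = k, sex = sx, age_bin = b,
                        age_label = labs[b], n = n, p0 = p0,
                        stringsAsFactors = FALSE)
      row[paste0("mean_", variables)] <- as.list(unname(mv))
      rows[[length(rows) + 1L]] <- row
    }
    if (!any_cell) stop_domain("cluster %d has no populated reference cells", k)
  }
  grid <- do.call(rbind, rows)
  attr(grid, "variables") <- variables
  class(grid) <- c("reference_grid", "data.frame")
  grid
}

# P_0 lookup with the nearest-populated-bin fallback (same cluster and sex;
# distance in bin index, ties toward the younger bin).
lookup_p0 <- function(grid, cluster, sex, bin) {
  sub <- grid[grid$cluster == cluster & grid$sex == sex, , drop = FALSE]
  hit <- sub[sub$age_bin == bin, , drop = FALSE]
  if (nrow(hit) && hit$n[1] > 0) return(hit$p0[1])
  pop <- sub[sub$n > 0, , drop = FALSE]
  if (!nrow(pop))
    stop_domain("no populated reference cell for cluster %d, sex %d", cluster, sex)
  d <- abs(pop$age_bin - bin)
  pop <- pop[order(d, pop$age_bin), , drop = FALSE]
  pop$p0[1]
}

#' Relative risk of each subject
#'
#' Each subject is assigned to the nearest cluster centroid, scored with
#' that cluster's logistic model (P_k), matched to the reference probability
#' of their cluster-sex-age cell (P_0, with nearest-bin fallback for empty
#' cells), and given the relative risk RR = P_k / P_0.
#'
#' @param subjects Data frame of subjects (age >= 20 required).
#' @param cluster_model A \code{cluster_model}.
#' @param logits A \code{cluster_logits}.
#' @param grid A \code{reference_grid}.
#' @param assignments Optional precomputed cluster assignments; by default
#'   subjects are assigned to the nearest centroid.
#' @return Data frame with \code{id}, \code{cluster}, \code{p_individual},
#'   \code{p_reference}, \code{rr}, \code{prevalent_diabetes}.
#' @export
compute_rr <- function(subjects, cluster_model, logits, grid,
                       assignments = NULL) {
  if (!nrow(subjects))
    return(data.frame(id = character(), cluster = integer(),
                      p_individual = numeric(), p_reference = numeric(),
                      rr = numeric(), prevalent_diabetes = logical(),
                      stringsAsFactors = FALSE))
  variables <- attr(grid, "variables") %||% cluster_model$variables
  bins <- age_bin(subjects$age)
  cl <- assignments %||% assign_cluster(cluster_model, subjects)
  pk <- numeric(nrow(subjects))
  for (k in sort(unique(cl))) {
    sel <- cl == k
    pk[sel] <- predict_cluster_logit(logits[[as.character(k)]],
                                     subjects[sel, , drop = FALSE], variables)
  }
  p0 <- mapply(function(k, sx, b) lookup_p0(grid, k, sx, b),
               cl, subjects$sex, bins)
  data.frame(id = if ("id" %in% names(subjects)) subjects$id
             else as.character(seq_len(nrow(subjects))),
             cluster = cl, p_individual = pk, p_reference = p0,
             rr = pk / p0,
             prevalent_diabetes = if ("diabetes" %in% names(subjects))
               subjects$diabetes == 1 else rep(FALSE, nrow(subjects)),
             stringsAsFactors = FALSE)
}
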