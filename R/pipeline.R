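# Pipeline orchestration and persistence --------------------------------

#' Pipeline configuration
#'
#' One object carrying every tunable of the training pipeline. Defaults are
#' the shipped study configuration: the nine risk variables, three
#' clusters (selection over 2-7 available via \code{k = NULL}), glycemia
#' cutoff 5.85 mmol/L, RR cutoff trained by ROC (falling back to 2.2), and
#' data-derived cluster rules with the published first-cluster criteria.
#'
#' @param variables Model/clustering variables.
#' @param k Number of clusters; \code{NULL} selects over \code{k_range} by
#'   the CCC/R-squared-increment rule.
#' @param k_range Candidate cluster numbers.
#' @param seed Integer seed (clustering initialization, fold assignment).
#' @param glu_cutoff Absolute glycemia cutoff (mmol/L).
#' @param rr_cutoff RR cutoff used when \code{select_cutoff} is FALSE.
#' @param select_cutoff Choose the RR cutoff from the training ROC curve
#'   (closest to the (0,1) corner)?
#' @param run_selection Run tree/logistic variable selection and attach the
#'   report (the model still uses \code{variables})?
#' @param freq_threshold Tree-frequency threshold of the selection step.
#' @param p_cutoff Wald significance cutoff of the selection step.
#' @param ruleset_prob Quantile for derived cluster rules.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(variables = default_risk_variables(),
                            k = 3, k_range = 2:7, seed = 1,
                            glu_cutoff = 5.85, rr_cutoff = 2.2,
                            select_cutoff = TRUE, run_selection = FALSE,
                            freq_threshold = 4, p_cutoff = 0.05,
                            ruleset_prob = 0.75, hl_groups = 10) {
  stopifnot(glu_cutoff > 0, rr_cutoff > 0,
            all(k_range >= 2), all(k_range <= 7))
  structure(list(variables = variables, k = k, k_range = k_range,
                 seed = as.integer(seed), glu_cutoff = glu_cutoff,
                 rr_cutoff = rr_cutoff, select_cutoff = select_cutoff,
                 run_selection = run_selection,
                 freq_threshold = freq_threshold, p_cutoff = p_cutoff,
                 ruleset_prob = ruleset_prob, hl_groups = hl_groups),
            class = "pipeline_config")
}

#' Run variable selection on a cohort
#'
#' Grows unpruned C4.5 trees on the five sub-cohorts (10 cross-validation
#' folds each), counts variable occurrences in the first eight levels, fits
#' the multivariate logistic screen, intersects the two sets (plus expert
#' overrides) and extracts the glycemia cutoff from the tree thresholds.
#'
#' @param cohort Training cohort.
#' @param predictors Candidate variable pool (default: every cohort column
#'   except id and the outcome).
#' @param config A [pipeline_config()].
#' @param control A [c45_control()].
#' @param overrides Expert overrides (see [select_risk_variables()]).
#' @return A \code{selection_report} (with the tree list attached as
#'   attribute \code{"trees"}).
#' @export
run_variable_selection <- function(cohort,
                                   predictors = setdiff(names(cohort),
                                                        c("id", "diabetes")),
                                   config = pipeline_config(),
                                   control = c45_control(),
                                   overrides = default_overrides()) {
  subs <- build_sub_cohorts(cohort)
  trees <- list()
  for (i in seq_along(subs)) {
    nm <- names(subs)[i]
    if (nrow(subs[[i]]) < 20) next
    trees[[nm]] <- cv_trees(subs[[i]], "diabetes", predictors, folds = 10,
                            seed = config$seed + i, control = control)
  }
  all_trees <- unlist(trees, recursive = FALSE)
  freq <- count_tree_frequencies(all_trees, max_level = 8,
                                 variables = predictors)
  lr <- fit_multivariate_logit(cohort, predictors)
  glu_cut <- extract_glycemia_cutoff(all_trees)
  if (is.na(glu_cut)) glu_cut <- config$glu_cutoff
  report <- select_risk_variables(freq, lr,
                                  freq_threshold = config$freq_threshold,
                                  p_cutoff = config$p_cutoff,
                                  overrides = overrides,
                                  glycemia_cutoff = glu_cut)
  attr(report, "trees") <- all_trees
  report
}

#' Train the full risk assessment model
#'
#' Executes the construction pipeline on a cohort: (optional) variable
#' selection, standardization and k-means partition, one logistic model per
#' cluster, the 24-cell age-sex reference grid, relative risks and the
#' ROC-chosen RR cutoff, and the cluster rule set. The returned bundle is
#' everything needed to assess new subjects.
#'
#' @param cohort Training cohort (baseline; includes prevalent diabetics).
#' @param config A [pipeline_config()].
#' @return Object of class \code{t2d_model}: list with \code{variables},
#'   \code{cluster_model}, \code{logits}, \code{grid}, \code{roc} (summary),
#'   \code{ruleset}, \code{selection} (report or NULL), \code{manifest}.
#' @export
train_risk_model <- function(cohort, config = pipeline_config()) {
  if (!nrow(cohort)) stop_domain("training cohort is empty")
  selection <- NULL
  if (config$run_selection)
    selection <- run_variable_selection(cohort, config = config)
  variables <- config$variables
  cm <- cluster_cohort(cohort, variables, k = config$k,
                       k_range = config$k_range, seed = config$seed)
  logits <- fit_cluster_logits(cohort, cm$assignments, variables,
                               hl_groups = config$hl_groups)
  grid <- build_reference_grid(cohort, cm$assignments, logits, variables)
  rr <- compute_rr(cohort, cm, logits, grid, assignments = cm$assignments)
  roc <- roc_curve(rr$rr, cohort$diabetes)
  cut <- closest_to_01_cutoff(roc)
  rr_cutoff <- if (config$select_cutoff) cut$cutoff else config$rr_cutoff
  glu_cutoff <- if (!is.null(selection)) selection$glycemia_cutoff
                else config$glu_cutoff
  ruleset <- derive_ruleset(cohort, cm$assignments,
                            prob = config$ruleset_prob,
                            glu_cutoff = glu_cutoff, rr_cutoff = rr_cutoff)
  model <- list(variables = variables, cluster_model = cm, logits = logits,
                grid = grid,
                roc = list(auc = roc$auc, cutoff = cut$cutoff,
                           sensitivity = cut$sensitivity,
                           specificity = cut$specificity),
                ruleset = ruleset, selection = selection,
                manifest = list(package_version = tryCatch(
                                  as.character(utils::packageVersion("diabrisk")),
                                  error = function(e) "dev"),
                                seed = config$seed,
                                n_training = nrow(cohort),
                                config = unclass(config)))
  class(model) <- "t2d_model"
  model
}

#' @export
print.t2d_model <- function(x, ...) {
  cat("Type 2 diabetes risk assessment model\n")
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat("  clusters:", x$cluster_model$k,
      "(sizes:", paste(table(x$cluster_model$assignments), collapse = "/"), ")\n")
  cat(sprintf("  training ROC: AUC %.3f, RR cutoff %.3g (sens %.3f, spec %.3f)\n",
              x$roc$auc, x$roc$cutoff, x$roc$sensitivity, x$roc$specificity))
  cat("  cutoffs: GLU >", x$ruleset$glu_cutoff, "mmol/L; RR >",
      signif(x$ruleset$rr_cutoff, 4), "\n")
  invisible(x)
}

# --- cohort CSV I/O -----------------------------------------------------

#' Write a cohort (or follow-up) table as CSV
#'
#' RFC-4180 CSV, UTF-8, "." decimal separator; sex coded 1 = male /
#' 0 = female, psh and diabetes coded 1/0.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_cohort <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the documented schema (columns \code{id, age, sex, bmi, waist,
#' sbp, dbp, glu, chol, tg, hdl, ldl, psh, diabetes}), rejects rows that
#' violate the record invariants (age < 20, non-positive measurements,
#' unparseable numerics) with row-numbered messages, and reports
#' missingness.
#'
#' @param path CSV path.
#' @param tolerant Drop offending rows (with a warning) instead of erroring.
#' @return Data frame of typed records.
#' @export
read_cohort <- function(path, tolerant = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(COHORT_COLS, names(raw))
  if (length(missing_cols))
    stop_domain("schema error: missing column(s) %s",
                paste(sQuote(missing_cols), collapse = ", "))
  num_cols <- setdiff(COHORT_COLS, "id")
  out <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  bad <- character()
  for (v in num_cols) {
    val <- suppressWarnings(as.numeric(raw[[v]]))
    broke <- which(is.na(val) & !is.na(raw[[v]]) & nzchar(raw[[v]]))
    if (length(broke))
      bad <- c(bad, sprintf("row %d: unparseable %s value '%s'",
                            broke, v, raw[[v]][broke]))
    out[[v]] <- val
  }
  viol <- which(out$age < 20 |
                  apply(out[setdiff(CONT_VARS, "age")], 1, function(r)
                    any(!is.na(r) & r <= 0)))
  if (length(viol))
    bad <- c(bad, sprintf("row %d: record invariant violated", viol))
  incomplete <- which(!complete.cases(out))
  drop_rows <- sort(unique(c(viol, incomplete)))
  if (length(bad)) {
    msg <- paste(bad, collapse = "; ")
    if (!tolerant) stop_domain("invalid cohort rows: %s", msg)
    warning("dropping ", length(drop_rows), " invalid row(s): ", msg)
  }
  if (length(drop_rows)) out <- out[-drop_rows, , drop = FALSE]
  n_missing <- sum(!complete.cases(out))
  message(sprintf("read_cohort: %d records loaded from %s (%d incomplete)",
                  nrow(out), basename(path), n_missing))
  out$sex <- as.integer(out$sex); out$psh <- as.integer(out$psh)
  out$diabetes <- as.integer(out$diabetes)
  rownames(out) <- NULL
  out
}

# --- model persistence --------------------------------------------------

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Persist a trained model as a directory of JSON/YAML files
#'
#' Writes \code{clustermodel.json}, \code{logits.json}, \code{grid.json},
#' \code{ruleset.yaml} and \code{manifest.json}. Together these files fully
#' define the trained model; [load_model()] restores it.
#'
#' @param model A \code{t2d_model}.
#' @param dir Target directory (created if absent).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- model$cluster_model
  json_write(list(variables = cm$variables, k = cm$k,
                  params = cm$params, centroids = as.data.frame(cm$centroids),
                  diagnostics = cm$diagnostics, seed = cm$seed),
             file.path(dir, "clustermodel.json"))
  json_write(lapply(unclass(model$logits), function(l)
    list(cluster = l$cluster, coefficients = as.list(l$coefficients),
         se = as.list(l$se), p = as.list(l$p), hl = l$hl[c("statistic", "dof", "p.value")],
         n = l$n, n_events = l$n_events)),
    file.path(dir, "logits.json"))
  json_write(list(variables = attr(model$grid, "variables"),
                  cells = as.data.frame(model$grid),
                  roc = model$roc),
             file.path(dir, "grid.json"))
  rs <- unclass(model$ruleset)
  rs$degree_map <- as.list(rs$degree_map)   # keep the degree keys in YAML
  yaml::write_yaml(rs, file.path(dir, "ruleset.yaml"))
  json_write(model$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Restore a trained model saved with [save_model()]
#'
#' @param dir Model directory.
#' @return A \code{t2d_model} (without the training selection report).
#' @export
load_model <- function(dir) {
  cmj <- jsonlite::read_json(file.path(dir, "clustermodel.json"),
                             simplifyVector = TRUE)
  cm <- list(params = cmj$params, variables = cmj$variables, k = cmj$k,
             centroids = as.matrix(cmj$centroids),
             diagnostics = cmj$diagnostics, seed = cmj$seed)
  colnames(cm$centroids) <- cm$variables
  class(cm) <- "cluster_model"
  lj <- jsonlite::read_json(file.path(dir, "logits.json"), simplifyVector = FALSE)
  logits <- lapply(lj, function(l)
    list(cluster = l$cluster,
         coefficients = unlist(l$coefficients),
         se = unlist(l$se), p = unlist(l$p),
         hl = list(statistic = l$hl$statistic %||% NA_real_,
                   dof = l$hl$dof %||% NA_integer_,
                   p.value = l$hl$p.value %||% NA_real_),
         n = l$n, n_events = l$n_events))
  names(logits) <- vapply(logits, function(l) as.character(l$cluster), "")
  class(logits) <- "cluster_logits"
  gj <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  grid <- gj$cells
  attr(grid, "variables") <- gj$variables
  class(grid) <- c("reference_grid", "data.frame")
  rs <- yaml::read_yaml(file.path(dir, "ruleset.yaml"))
  ruleset <- ccra_ruleset(rs$rules, rs$glu_cutoff, rs$rr_cutoff,
                          degree_map = unlist(rs$degree_map),
                          source = rs$source %||% "published")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  model <- list(variables = cm$variables, cluster_model = cm, logits = logits,
                grid = grid, roc = as.list(gj$roc), ruleset = ruleset,
                selection = NULL, manifest = manifest)
  class(model) <- "t2d_model"
  model
}
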