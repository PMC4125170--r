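# Risk-variable selection ------------------------------------------------
#
# Dual-evidence selection: unpruned C4.5 trees grown on five sub-cohorts
# under 10-fold cross-validation provide frequency evidence (occurrences of
# a variable in the first eight tree levels), a multivariate logistic model
# provides Wald significance; the final risk set is the intersection plus
# declared expert overrides. Tree split thresholds on fasting glucose also
# yield the absolute glycemia cutoff.

#' Split a cohort into the five training sub-cohorts
#'
#' Returns the five overlapping training sets on which decision trees are
#' grown: everyone, each sex, and the two age strata. The age boundary is a
#' half-open partition: "under 50" is age < 50, "over 50" is age >= 50.
#'
#' @param cohort Data frame with at least \code{age} and \code{sex} columns.
#' @return Named list of data frames:
#'   \code{all}, \code{males}, \code{females}, \code{under50}, \code{over50}.
#' @export
build_sub_cohorts <- function(cohort) {
  if (!all(c("age", "sex") %in% names(cohort)))
    stop_domain("cohort must contain 'age' and 'sex' columns")
  list(all     = cohort,
       males   = cohort[cohort$sex == 1, , drop = FALSE],
       females = cohort[cohort$sex == 0, , drop = FALSE],
       under50 = cohort[cohort$age < 50, , drop = FALSE],
       over50  = cohort[cohort$age >= 50, , drop = FALSE])
}

#' Growth control for C4.5 trees
#'
#' @param min_leaf Minimum number of records in each child of a split.
#' @param max_depth Maximum depth (root = depth 1).
#' @return List of class \code{c45_control}.
#' @export
c45_control <- function(min_leaf = 25, max_depth = 12) {
  structure(list(min_leaf = min_leaf, max_depth = max_depth),
            class = "c45_control")
}

entropy_counts <- function(n1, n) {
  # binary class entropy (bits) from positive count n1 of n
  p <- n1 / n
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

# Best binary split of one numeric predictor by gain ratio.
# Candidate thresholds are midpoints between sorted distinct values; a split
# is admissible when both children have >= min_leaf records and the
# information gain is positive. Returns NULL when no admissible split.
best_split_var <- function(x, y, min_leaf) {
  n <- length(y)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  cum1 <- cumsum(ys)
  # cut after position i  <=>  threshold midpoint(xs[i], xs[i+1])
  cuts <- which(xs[-n] < xs[-1])
  cuts <- cuts[cuts >= min_leaf & (n - cuts) >= min_leaf]
  if (!length(cuts)) return(NULL)
  nl <- cuts; nr <- n - cuts
  n1l <- cum1[cuts]; n1r <- cum1[n] - n1l
  h_parent <- entropy_counts(cum1[n], n)
  h_children <- (nl * entropy_counts(n1l, nl) + nr * entropy_counts(n1r, nr)) / n
  gain <- h_parent - h_children
  iv <- -(nl / n * log2(nl / n) + nr / n * log2(nr / n))
  gr <- ifelse(iv > 0, gain / iv, 0)
  keep <- which(gain > 1e-12)
  if (!length(keep)) return(NULL)
  best <- keep[which.max(gr[keep])]          # ties: smaller threshold wins
  # which.max returns the first maximum; enforce tolerance-based tie-break
  tied <- keep[gr[keep] >= gr[best] - 1e-12]
  best <- tied[1]
  list(threshold = (xs[cuts[best]] + xs[cuts[best] + 1]) / 2,
       gain_ratio = gr[best], gain = gain[best])
}

#' Grow an unpruned C4.5 decision tree
#'
#' Binary gain-ratio splits on numeric predictors (binary 0/1 predictors are
#' handled as numeric, splitting at 0.5), thresholds at midpoints between
#' sorted distinct values, no pruning. Growth stops on class purity, the
#' minimum-leaf-size constraint, the depth limit, or when no split has
#' positive information gain. Gain-ratio ties are broken by predictor name
#' order and then by the smaller threshold, so trees are reproducible.
#'
#' @param data Data frame of training records.
#' @param outcome Name of the binary (0/1) class column.
#' @param predictors Character vector of predictor column names.
#' @param control A [c45_control()].
#' @return Nested-list tree of class \code{c45_tree}; internal nodes carry
#'   \code{variable}, \code{threshold}, \code{left}, \code{right}; leaves
#'   carry \code{label}. Every node carries \code{depth} and \code{n}.
#' @export
build_c45_tree <- function(data, outcome = "diabetes",
                           predictors = setdiff(names(data), c("id", outcome)),
                           control = c45_control()) {
  if (!nrow(data)) stop_domain("cannot grow a tree from zero records")
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop_domain("outcome must be binary 0/1")
  predictors <- sort(predictors)             # name-order tie-breaking
  xmat <- as.matrix(data[predictors])
  grow <- function(idx, depth) {
    yi <- y[idx]
    n1 <- sum(yi)
    # majority label; exact tie goes to class 0 (documented convention)
    make_leaf <- function() list(type = "leaf",
                                 label = as.integer(n1 * 2 > length(yi)),
                                 n = length(yi), depth = depth)
    if (n1 == 0 || n1 == length(yi) || depth >= control$max_depth ||
        length(yi) < 2 * control$min_leaf)
      return(make_leaf())
    best <- NULL; best_var <- NULL
    for (v in predictors) {
      sp <- best_split_var(xmat[idx, v], yi, control$min_leaf)
      if (is.null(sp)) next
      if (is.null(best) || sp$gain_ratio > best$gain_ratio + 1e-12) {
        best <- sp; best_var <- v
      }
    }
    if (is.null(best)) return(make_leaf())
    go_left <- xmat[idx, best_var] <= best$threshold
    list(type = "node", variable = best_var, threshold = best$threshold,
         gain_ratio = best$gain_ratio, n = length(yi), depth = depth,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  tree <- grow(seq_len(nrow(data)), 1L)
  class(tree) <- "c45_tree"
  tree
}

tree_nodes <- function(tree) {
  # flatten to a data frame of internal nodes
  acc <- list()
  walk <- function(node) {
    if (node$type == "node") {
      acc[[length(acc) + 1L]] <<- data.frame(variable = node$variable,
                                             threshold = node$threshold,
                                             depth = node$depth, n = node$n,
                                             stringsAsFactors = FALSE)
      walk(node$left); walk(node$right)
    }
  }
  walk(tree)
  if (!length(acc))
    return(data.frame(variable = character(), threshold = numeric(),
                      depth = integer(), n = integer(), stringsAsFactors = FALSE))
  do.call(rbind, acc)
}

#' @export
format.c45_tree <- function(x, ...) {
  lines <- character()
  walk <- function(node, pad) {
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf("%sleaf: class %d (n=%d)", pad, node$label, node$n))
    } else {
      lines <<- c(lines, sprintf("%s%s <= %.6g (n=%d)", pad, node$variable,
                                 node$threshold, node$n))
      walk(node$left, paste0(pad, "  "))
      lines <<- c(lines, sprintf("%s%s > %.6g", pad, node$variable, node$threshold))
      walk(node$right, paste0(pad, "  "))
    }
  }
  walk(x, "")
  paste(lines, collapse = "\n")
}

#' @export
print.c45_tree <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Grow one tree per cross-validation training fold
#'
#' Records are dealt into \code{folds} folds at random; one unpruned tree is
#' grown on each training complement (so 10 folds give 10 trees). This is
#' the reading of "10-fold cross validation without pruning" used for
#' frequency counting; see the methods vignette.
#'
#' @inheritParams build_c45_tree
#' @param folds Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return List of \code{c45_tree} objects, one per fold.
#' @export
cv_trees <- function(data, outcome = "diabetes",
                     predictors = setdiff(names(data), c("id", outcome)),
                     folds = 10, seed = 1, control = c45_control()) {
  n <- nrow(data)
  if (n < folds) stop_domain("need at least %d records for %d folds", folds, folds)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  lapply(seq_len(folds), function(f)
    build_c45_tree(data[fold != f, , drop = FALSE], outcome, predictors, control))
}

#' Count variable occurrences in the shallow levels of a tree set
#'
#' @param trees List of \code{c45_tree} objects (typically 5 sub-cohorts x
#'   10 folds).
#' @param max_level Deepest level counted (root = level 1).
#' @param variables Optional variable pool; ensures zero counts are reported.
#' @return Named integer vector of occurrence counts.
#' @export
count_tree_frequencies <- function(trees, max_level = 8, variables = NULL) {
  if (inherits(trees, "c45_tree")) trees <- list(trees)
  nodes <- do.call(rbind, lapply(trees, tree_nodes))
  nodes <- nodes[nodes$depth <= max_level, , drop = FALSE]
  counts <- table(factor(nodes$variable,
                         levels = variables %||% sort(unique(nodes$variable))))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Fit the multivariate logistic screening model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of the
#' diabetes label on a set of candidate variables, with Wald standard errors
#' and p-values per coefficient. Perfect separation is flagged as an error
#' naming the offending variable.
#'
#' @param data Data frame.
#' @param variables Predictor names.
#' @param outcome Binary outcome column name.
#' @param epsilon IRLS convergence tolerance on the deviance.
#' @return Object of class \code{risk_logit}: list with \code{coefficients}
#'   (data frame: variable, beta, se, z, p), \code{fit} (the glm object),
#'   \code{converged}.
#' @export
fit_multivariate_logit <- function(data, variables, outcome = "diabetes",
                                   epsilon = 1e-8) {
  for (v in variables)
    if (length(unique(data[[v]])) < 2)
      stop_domain("variable '%s' is constant", v)
  fml <- stats::reformulate(variables, response = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = data, family = binomial(),
        control = list(epsilon = epsilon, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  if (sep_warn && any(abs(cf[-1, 1]) > 15)) {
    worst <- rownames(cf)[-1][which.max(abs(cf[-1, 1]))]
    stop_domain("perfect separation detected; variable '%s' separates the outcome",
                worst)
  }
  if (!fit$converged) stop_domain("logistic fit did not converge")
  out <- list(coefficients = data.frame(variable = rownames(cf),
                                        beta = cf[, 1], se = cf[, 2],
                                        z = cf[, 3], p = cf[, 4],
                                        row.names = NULL,
                                        stringsAsFactors = FALSE),
              fit = fit, converged = fit$converged)
  class(out) <- "risk_logit"
  out
}

#' Default expert overrides of the dual selection
#'
#' HDL is retained even when its Wald p-value exceeds the cutoff (it is a
#' well-established protective factor and is strongly suggested by the
#' trees), and a CHOL-by-sex product term is offered as an additional
#' screening variable.
#'
#' @return List of override descriptors (variable, rationale).
#' @export
default_overrides <- function() {
  list(list(variable = "hdl",
            rationale = "protective factor; strongly suggested by the decision trees"),
       list(variable = "chol_sex",
            rationale = "cholesterol is empirically relevant in women around age 50"))
}

#' Intersect tree and logistic evidence into the final risk-variable set
#'
#' @param tree_frequency Named counts from [count_tree_frequencies()].
#' @param logit A \code{risk_logit} from [fit_multivariate_logit()].
#' @param freq_threshold Variables with tree frequency strictly greater than
#'   this are tree-selected (default 4).
#' @param p_cutoff Wald significance cutoff (default 0.05).
#' @param overrides List of override descriptors as in [default_overrides()],
#'   or \code{NULL} for none.
#' @param exclude Variables barred from the final set however strong their
#'   evidence; by default the glycemia variable, which is reserved for the
#'   absolute criterion of the stratifier rather than the probability model.
#' @param glycemia_cutoff Glycemia cutoff carried on the report (mmol/L).
#' @return Object of class \code{selection_report}.
#' @export
select_risk_variables <- function(tree_frequency, logit,
                                  freq_threshold = 4, p_cutoff = 0.05,
                                  overrides = default_overrides(),
                                  exclude = "glu",
                                  glycemia_cutoff = 5.85) {
  tree_selected <- names(tree_frequency)[tree_frequency > freq_threshold]
  cf <- logit$coefficients
  cf <- cf[cf$variable != "(Intercept)", , drop = FALSE]
  lr_selected <- cf$variable[cf$p < p_cutoff]
  final <- setdiff(intersect(tree_selected, lr_selected), exclude)
  applied <- list()
  for (ov in overrides %||% list()) {
    if (!ov$variable %in% final) {
      final <- c(final, ov$variable)
      applied <- c(applied, list(ov))
    }
  }
  if (!length(final))
    warning("empty intersection and no overrides: no risk variables selected")
  out <- list(tree_frequency = tree_frequency,
              lr_coefficients = logit$coefficients,
              tree_selected = sort(tree_selected),
              lr_selected = sort(lr_selected),
              overrides_applied = applied,
              final_variables = sort(final),
              freq_threshold = freq_threshold, p_cutoff = p_cutoff,
              glycemia_cutoff = glycemia_cutoff)
  class(out) <- "selection_report"
  out
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Risk-variable selection report\n")
  cat("  tree-selected (freq > ", x$freq_threshold, "): ",
      paste(x$tree_selected, collapse = ", "), "\n", sep = "")
  cat("  LR-selected   (p < ", x$p_cutoff, "): ",
      paste(x$lr_selected, collapse = ", "), "\n", sep = "")
  for (ov in x$overrides_applied)
    cat("  override: ", ov$variable, " (", ov$rationale, ")\n", sep = "")
  cat("  final: ", paste(x$final_variables, collapse = ", "), "\n", sep = "")
  cat("  glycemia cutoff: ", x$glycemia_cutoff, " mmol/L\n", sep = "")
  invisible(x)
}

#' Extract the absolute glycemia cutoff from tree thresholds
#'
#' Collects every split on the glycemia variable within the first
#' \code{max_level} levels of the supplied trees, bins the thresholds to
#' \code{bin} mmol/L, and returns the modal bin value. Ties are broken
#' toward the bin containing the shallowest split, then toward the smaller
#' threshold. When no glycemia split exists the function returns \code{NA}
#' and callers fall back to the configured default (5.85 mmol/L).
#'
#' @param trees List of \code{c45_tree} objects.
#' @param variable Name of the glycemia column.
#' @param bin Bin width in mmol/L.
#' @param max_level Deepest level considered.
#' @return Cutoff in mmol/L, or \code{NA_real_} when absent.
#' @export
extract_glycemia_cutoff <- function(trees, variable = "glu", bin = 0.05,
                                    max_level = 8) {
  if (inherits(trees, "c45_tree")) trees <- list(trees)
  nodes <- do.call(rbind, lapply(trees, tree_nodes))
  nodes <- nodes[nodes$variable == variable & nodes$depth <= max_level, ,
                 drop = FALSE]
  if (!nrow(nodes)) return(NA_real_)
  nodes$bin <- round(nodes$threshold / bin) * bin
  agg <- aggregate(cbind(count = threshold) ~ bin, data = nodes, FUN = length)
  mind <- aggregate(depth ~ bin, data = nodes, FUN = min)
  agg <- merge(agg, mind, by = "bin")
  agg <- agg[order(-agg$count, agg$depth, agg$bin), , drop = FALSE]
  agg$bin[1]
}
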