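# Shared fixtures, all generated in code.

small_spec <- function(n = 1500, seed = 99, ...) {
  cohort_spec(n_subjects = n, seed = seed, ...)
}

# one trained model reused across test files in this session
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(small_spec(2500, seed = 314))
      cache <<- list(cohort = co,
                     model = train_risk_model(co, pipeline_config(seed = 314)))
    }
    cache
  }
})

# tiny deterministic two-variable dataset with a known best split
toy_split_data <- function() {
  data.frame(x = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
}

# exhaustive gain-ratio maximizer over all variables and midpoint
# thresholds: the independent oracle for the C4.5 root split
oracle_root_split <- function(data, outcome, predictors, min_leaf = 1) {
  y <- data[[outcome]]
  n <- length(y)
  ent <- function(k, m) {
    if (m == 0) return(0)
    p <- k / m
    if (p <= 0 || p >= 1) return(0)
    -(p * log2(p) + (1 - p) * log2(1 - p))
  }
  best <- NULL
  for (v in sort(predictors)) {
    x <- data[[v]]
    ux <- sort(unique(x))
    if (length(ux) < 2) next
    for (i in seq_len(length(ux) - 1)) {
      th <- (ux[i] + ux[i + 1]) / 2
      l <- x <= th
      nl <- sum(l); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      gain <- ent(sum(y), n) -
        (nl * ent(sum(y[l]), nl) + nr * ent(sum(y[!l]), nr)) / n
      if (gain <= 1e-12) next
      iv <- -(nl / n * log2(nl / n) + nr / n * log2(nr / n))
      gr <- gain / iv
      if (is.null(best) || gr > best$gain_ratio + 1e-12) {
        best <- list(variable = v, threshold = th, gain_ratio = gr)
      }
    }
  }
  best
}

# brute-force AUC as the concordant-pair fraction with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

digest_file <- function(f) unname(tools::md5sum(f))

# A hand-built trained model whose RR is easy to reason about: one cluster,
# a logit weighing bmi and waist (waist is not a rule variable, so RR can be
# elevated at degree 0), and a flat reference grid with
# P0 = plogis(-12 + 0.2*24 + 0.05*80) ~ 0.039.
toy_model <- function(rr_cutoff = 2.2) {
  variables <- c("bmi", "waist", "chol", "tg")
  params <- data.frame(variable = variables, mean = c(24, 80, 5, 1.5),
                       sd = c(3, 9, 1, 1))
  cm <- structure(list(params = params, variables = variables, k = 1L,
                       centroids = matrix(0, 1, 4,
                                          dimnames = list(NULL, variables)),
                       assignments = integer(), diagnostics = NULL, seed = 1L),
                  class = "cluster_model")
  lg <- list(`1` = list(cluster = 1,
                        coefficients = c(`(Intercept)` = -12, bmi = 0.2,
                                         waist = 0.05, chol = 0, tg = 0)))
  class(lg) <- "cluster_logits"
  rows <- expand.grid(sex = c(1, 0), age_bin = 1:12)
  grid <- data.frame(cluster = 1, sex = rows$sex, age_bin = rows$age_bin,
                     age_label = age_bin_labels()[rows$age_bin], n = 10,
                     p0 = stats::plogis(-12 + 0.2 * 24 + 0.05 * 80),
                     mean_bmi = 24, mean_waist = 80, mean_chol = 5,
                     mean_tg = 1.5)
  attr(grid, "variables") <- variables
  class(grid) <- c("reference_grid", "data.frame")
  list(variables = variables, cluster_model = cm, logits = lg, grid = grid,
       ruleset = default_ruleset(1, rr_cutoff = rr_cutoff))
}

subject <- function(bmi, chol, tg, glu = 4.8, waist = 80, age = 40, sex = 1,
                    diabetes = 0) {
  data.frame(id = "s", age = age, sex = sex, bmi = bmi, waist = waist,
             chol = chol, tg = tg, glu = glu, diabetes = diabetes)
}
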