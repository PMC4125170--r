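# Cohort partitioning ----------------------------------------------------
#
# The cohort is standardized on the nine risk variables and partitioned by
# k-means (Lloyd iteration, k-means++ or nested-refinement seeding). The
# number of clusters is chosen over a candidate range from R-squared
# increments subject to the cubic clustering criterion rule CCC >= 10.

#' Standardize cohort variables
#'
#' Centres and scales each variable to mean 0, SD 1 (sample SD, n-1
#' denominator) and retains the parameters so new subjects can be projected
#' into the same standardized space.
#'
#' @param cohort Data frame.
#' @param variables Variables to standardize.
#' @return List with \code{x} (matrix) and \code{params} (data frame:
#'   variable, mean, sd).
#' @export
standardize_cohort <- function(cohort, variables) {
  miss <- setdiff(variables, names(cohort))
  if (length(miss)) stop_domain("missing variables: %s", paste(miss, collapse = ", "))
  x <- as.matrix(cohort[variables])
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  bad <- variables[sdv <= 0 | !is.finite(sdv)]
  if (length(bad)) stop_domain("zero variance in variable '%s'", bad[1])
  list(x = scale(x, center = mu, scale = sdv)[, , drop = FALSE],
       params = data.frame(variable = variables, mean = unname(mu),
                           sd = unname(sdv), stringsAsFactors = FALSE))
}

#' Project subjects with stored standardization parameters
#'
#' @param cohort Data frame of subjects.
#' @param params Parameter frame from [standardize_cohort()].
#' @return Standardized matrix.
#' @export
apply_standardization <- function(cohort, params) {
  x <- as.matrix(cohort[params$variable])
  scale(x, center = params$mean, scale = params$sd)[, , drop = FALSE]
}

#' Invert a standardization
#'
#' @param x Standardized matrix with columns matching \code{params$variable}.
#' @param params Parameter frame from [standardize_cohort()].
#' @return Matrix in original units.
#' @export
destandardize <- function(x, params) {
  sweep(sweep(as.matrix(x), 2, params$sd, "*"), 2, params$mean, "+")
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1)) {
    pick <- if (sum(d2) <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ], "-")^2))
  }
  centers
}

#' Partition standardized data by k-means
#'
#' Lloyd iteration from a k-means++ seeding (default) or from supplied
#' centres; the \code{"nested"} initialization refines a previous solution
#' by adding the point farthest from its centroid as the new centre, which
#' guarantees the between-cluster R-squared is non-decreasing in k. Empty
#' clusters arising during iteration are re-seeded from the farthest point.
#'
#' @param x Numeric matrix (rows = subjects).
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed for the initialization.
#' @param init \code{"kmeanspp"} or \code{"nested"}.
#' @param previous For \code{init = "nested"}: the previous
#'   \code{kmeans_partition} result at k - 1.
#' @param nstart Number of k-means++ restarts (best within-SS solution
#'   kept); ignored for nested initialization.
#' @return List with \code{assignments}, \code{centroids}, \code{r_squared},
#'   \code{ss_within}, \code{ss_total}, \code{k}.
#' @export
kmeans_partition <- function(x, k, seed = 1, init = c("kmeanspp", "nested"),
                             previous = NULL, nstart = 5) {
  init <- match.arg(init)
  x <- as.matrix(x)
  if (k < 2) stop_domain("k must be >= 2")
  if (nrow(unique(x)) < k) stop_domain("need at least k = %d distinct points", k)
  set.seed(seed)
  run_lloyd <- function(centers) {
    km <- NULL
    for (attempt in 1:10) {
      km <- tryCatch(
        withCallingHandlers(
          kmeans(x, centers = centers, iter.max = 200, algorithm = "Lloyd"),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(km, "kmeans")) return(km)
      # empty cluster: re-seed one centre from the point farthest from its
      # current nearest centre
      d2m <- sapply(seq_len(k), function(j) rowSums(sweep(x, 2, centers[j, ], "-")^2))
      d2m <- matrix(d2m, nrow = nrow(x))
      nearest <- max.col(-d2m, ties.method = "first")
      far <- which.max(d2m[cbind(seq_len(nrow(x)), nearest)])
      centers[((attempt - 1) %% k) + 1, ] <- x[far, ] + rnorm(ncol(x), sd = 1e-8)
    }
    stop_domain("k-means failed to converge")
  }
  km <- if (init == "nested") {
    if (is.null(previous)) stop_domain("nested initialization needs 'previous'")
    d2 <- rowSums((x - previous$centroids[previous$assignments, , drop = FALSE])^2)
    run_lloyd(rbind(previous$centroids, x[which.max(d2), ]))
  } else {
    best <- NULL
    for (s in seq_len(max(1, nstart))) {
      cand <- run_lloyd(kmeanspp_centers(x, k))
      if (is.null(best) || cand$tot.withinss < best$tot.withinss) best <- cand
    }
    best
  }
  list(assignments = km$cluster, centroids = km$centers,
       r_squared = km$betweenss / km$totss,
       ss_within = km$tot.withinss, ss_total = km$totss, k = k)
}

#' Cubic clustering criterion
#'
#' Sarle's CCC: a variance-stabilized comparison of the observed
#' between-cluster R-squared with its expectation under a uniform null over
#' the data's principal-component hyperbox (the published hyperbox
#' approximation). Large values (>= 10 in the selection rule used here)
#' indicate strong clustering.
#'
#' @param x Numeric data matrix.
#' @param assignments Integer cluster assignments (>= 2 non-empty clusters).
#' @return CCC value (scalar).
#' @export
cubic_clustering_criterion <- function(x, assignments) {
  x <- as.matrix(x)
  cl <- as.integer(factor(assignments))
  q <- length(unique(cl))
  if (q < 2) stop_domain("CCC is undefined for a single cluster")
  n <- nrow(x); p <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  tss <- sum(xc^2)
  wss <- 0
  for (g in seq_len(q)) {
    xg <- xc[cl == g, , drop = FALSE]
    wss <- wss + sum(scale(xg, center = TRUE, scale = FALSE)^2)
  }
  r2 <- 1 - wss / tss
  ev <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  s <- sqrt(pmax(ev, 0))
  s <- s[s > 1e-12]
  p_eff <- length(s)
  pstar <- 1; cstar <- s[1] / q
  for (j in p_eff:1) {
    cst <- (prod(s[1:j]) / q)^(1 / j)
    if (s[j] >= cst) { pstar <- j; cstar <- cst; break }
  }
  u <- s / cstar
  num <- sum(1 / (n + u[1:pstar]))
  if (pstar < p_eff)
    num <- num + sum(u[(pstar + 1):p_eff]^2 / (n + u[(pstar + 1):p_eff]))
  er2 <- 1 - (num / sum(u^2)) * ((n - q)^2 / n) * (1 + 4 / n)
  log((1 - er2) / (1 - r2)) * sqrt(n * pstar / 2) / (0.001 + er2)^1.2
}

#' Choose the number of clusters
#'
#' Among candidate k whose CCC is at least \code{ccc_min}, returns the
#' smallest k whose R-squared increment over k - 1 is maximal (the increment
#' of the smallest candidate is its R-squared itself, i.e. the gain over the
#' single-cluster solution). When no candidate reaches \code{ccc_min} the k
#' with maximal CCC is returned with a warning.
#'
#' @param diagnostics Data frame with columns \code{k}, \code{r_squared},
#'   \code{ccc}.
#' @param ccc_min CCC admission threshold (default 10).
#' @return The chosen k (integer).
#' @export
choose_k <- function(diagnostics, ccc_min = 10) {
  if (!nrow(diagnostics)) stop_domain("empty diagnostics")
  d <- diagnostics[order(diagnostics$k), , drop = FALSE]
  d$increment <- c(d$r_squared[1], diff(d$r_squared))
  ok <- d$ccc >= ccc_min
  if (!any(ok)) {
    warning("no candidate k reached CCC >= ", ccc_min,
            "; returning k with maximal CCC")
    return(d$k[which.max(d$ccc)])
  }
  dd <- d[ok, , drop = FALSE]
  dd$k[which.max(dd$increment)]   # first max = smallest such k
}

#' Standardize, partition and diagnose a cohort
#'
#' Runs the full partition stage: standardization on the risk variables,
#' k-means for each candidate k (nested-refinement seeding so R-squared is
#' monotone in k), CCC diagnostics, and either the selection rule of
#' [choose_k()] or a fixed k. Cluster labels are relabelled in decreasing
#' cluster size, so cluster 1 is always the largest ("general") group.
#'
#' @param cohort Data frame.
#' @param variables Clustering variables (default [default_risk_variables()]).
#' @param k Fixed number of clusters, or \code{NULL} to select over
#'   \code{k_range}.
#' @param k_range Candidate range when \code{k} is \code{NULL}.
#' @param seed Integer seed.
#' @return Object of class \code{cluster_model}: list with \code{params},
#'   \code{variables}, \code{k}, \code{centroids}, \code{assignments},
#'   \code{diagnostics}, \code{seed}.
#' @export
cluster_cohort <- function(cohort, variables = default_risk_variables(),
                           k = 3, k_range = 2:7, seed = 1) {
  st <- standardize_cohort(cohort, variables)
  ks <- if (is.null(k)) sort(unique(k_range)) else k
  fits <- list(); prev <- NULL
  diags <- data.frame(k = integer(), r_squared = numeric(), ccc = numeric())
  for (kk in ks) {
    fit <- kmeans_partition(st$x, kk, seed = seed)
    if (!is.null(prev)) {
      # nested refinement of the previous solution guarantees monotone R2;
      # keep whichever of the two fits explains more variance
      nested <- kmeans_partition(st$x, kk, seed = seed, init = "nested",
                                 previous = prev)
      if (nested$r_squared > fit$r_squared) fit <- nested
    }
    fits[[as.character(kk)]] <- fit
    diags <- rbind(diags, data.frame(
      k = kk, r_squared = fit$r_squared,
      ccc = cubic_clustering_criterion(st$x, fit$assignments)))
    prev <- fit
  }
  k_use <- if (is.null(k)) choose_k(diags) else k
  fit <- fits[[as.character(k_use)]]
  # relabel clusters by decreasing size
  sizes <- table(fit$assignments)
  relab <- setNames(seq_len(k_use), names(sort(sizes, decreasing = TRUE)))
  assignments <- unname(relab[as.character(fit$assignments)])
  centroids <- fit$centroids[as.integer(names(sort(sizes, decreasing = TRUE))), ,
                             drop = FALSE]
  rownames(centroids) <- NULL
  out <- list(params = st$params, variables = variables, k = k_use,
              centroids = centroids, assignments = assignments,
              diagnostics = diags, seed = as.integer(seed))
  class(out) <- "cluster_model"
  out
}

#' Assign subjects to the nearest cluster centroid
#'
#' New subjects are projected with the stored standardization parameters and
#' assigned to the nearest centroid under Euclidean distance.
#'
#' @param model A \code{cluster_model}.
#' @param cohort Data frame of subjects.
#' @return Integer vector of cluster indices.
#' @export
assign_cluster <- function(model, cohort) {
  z <- apply_standardization(cohort, model$params)
  d2 <- sapply(seq_len(model$k), function(j)
    rowSums(sweep(z, 2, model$centroids[j, ], "-")^2))
  d2 <- matrix(d2, nrow = nrow(z))
  max.col(-d2, ties.method = "first")
}
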