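make_logits <- function(coef_list, variables) {
  out <- lapply(seq_along(coef_list), function(i)
    list(cluster = i, coefficients = coef_list[[i]],
         se = coef_list[[i]] * 0, p = coef_list[[i]] * 0,
         hl = list(statistic = NA, dof = NA, p.value = NA),
         n = 0, n_events = 0))
  names(out) <- as.character(seq_along(coef_list))
  class(out) <- "cluster_logits"
  out
}

test_that("per-cluster logistic fits recover the generating coefficients", {
  set.seed(101)
  n <- 20000
  d <- data.frame(age = stats::rnorm(n, 50, 10), bmi = stats::rnorm(n, 24, 3))
  lp <- -8 + 0.08 * d$age + 0.12 * d$bmi
  d$diabetes <- stats::rbinom(n, 1, stats::plogis(lp))
  fits <- fit_cluster_logits(d, rep(1L, n), c("age", "bmi"))
  cf <- fits[["1"]]$coefficients
  se <- fits[["1"]]$se
  truth <- c(`(Intercept)` = -8, age = 0.08, bmi = 0.12)
  for (v in names(truth))
    expect_lt(abs(cf[[v]] - truth[[v]]), 2 * se[[v]])
  # duplicated clusters give identical coefficient vectors
  d2 <- rbind(d, d)
  fits2 <- fit_cluster_logits(d2, rep(1:2, each = n), c("age", "bmi"))
  expect_equal(fits2[["1"]]$coefficients, fits2[["2"]]$coefficients)
  # single-class cluster errors with the cluster index
  d3 <- d; d3$diabetes[1:100] <- 0
  asg <- rep(1L, n); asg[1:100] <- 2L
  d3$diabetes[asg == 2] <- 0
  expect_error(fit_cluster_logits(d3, asg, c("age", "bmi")), "cluster 2")
})

test_that("Hosmer-Lemeshow has the documented dof and calibrated-null behaviour", {
  set.seed(202)
  n <- 10000
  p <- stats::runif(n, 0.05, 0.6)
  y <- stats::rbinom(n, 1, p)
  hl <- hosmer_lemeshow(p, y, groups = 10)
  expect_equal(hl$dof, 8L)
  expect_error(hosmer_lemeshow(p, y, groups = 2), "3 groups")
  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)), "strictly")

  # near-equal probabilities with a matching outcome rate: the statistic is
  # pure binomial noise, bounded by the chi-squared(10) tail referred to
  # 8 dof (theoretical rejection ~0.115), so rejections stay rare
  reject <- replicate(40, {
    yy <- stats::rbinom(5000, 1, 0.2)
    h <- hosmer_lemeshow(rep(0.2, 5000) + stats::runif(5000, -1e-6, 1e-6), yy)
    h$p.value < 0.05
  })
  expect_lt(mean(reject), 0.25)
})

test_that("the reference grid has 24 cells per cluster and sane P0", {
  fx <- trained_fixture()
  grid <- fx$model$grid
  for (k in 1:fx$model$cluster_model$k) {
    sub <- grid[grid$cluster == k, ]
    expect_equal(nrow(sub), 24)
    expect_equal(sort(unique(sub$age_bin)), 1:12)
    expect_setequal(unique(sub$sex), c(0, 1))
    pop <- sub[sub$n > 0, ]
    expect_true(all(pop$p0 > 0 & pop$p0 < 1))
  }
  # every non-diabetic subject maps to exactly one cell
  nd <- fx$cohort$diabetes == 0
  cells <- table(fx$model$cluster_model$assignments[nd],
                 fx$cohort$sex[nd], age_bin(fx$cohort$age[nd]))
  expect_equal(sum(grid$n), sum(nd))
  expect_equal(sum(cells), sum(nd))
})

test_that("P0 of a one-subject cell equals that subject's own probability", {
  beta <- c(`(Intercept)` = -2, x = 0.5)
  d <- data.frame(age = c(rep(32, 4), 47), sex = 1,
                  x = c(-1, 0, 1, 2, 1.3), diabetes = 0)
  lg <- make_logits(list(beta), "x")
  grid <- build_reference_grid(d, rep(1L, 5), lg, "x")
  cell <- grid[grid$n == 1, ]
  expect_equal(nrow(cell), 1)
  expect_equal(cell$age_bin, age_bin(47))
  expect_equal(cell$p0, stats::plogis(-2 + 0.5 * 1.3), tolerance = 1e-12)
})

test_that("P0 uses logit-at-mean-covariates, not the mean of probabilities", {
  beta <- c(`(Intercept)` = -4, x = 1)
  xs <- c(-3, -1, 0, 1, 3)
  at_mean <- stats::plogis(-4 + 1 * mean(xs))
  mean_of <- mean(stats::plogis(-4 + xs))
  expect_false(isTRUE(all.equal(at_mean, mean_of)))  # the Jensen gap
  d <- data.frame(age = rep(30, 5), sex = 1, x = xs, diabetes = 0)
  lg <- make_logits(list(beta), "x")
  grid <- build_reference_grid(d, rep(1L, 5), lg, "x")
  cell <- grid[grid$n == 5, ]
  expect_equal(cell$p0, at_mean, tolerance = 1e-12)
})

test_that("relative risk is the exact probability ratio with matched-cell anchoring", {
  fx <- trained_fixture()
  rr <- compute_rr(fx$cohort, fx$model$cluster_model, fx$model$logits,
                   fx$model$grid)
  expect_true(all(rr$rr >= 0))
  expect_equal(rr$rr, rr$p_individual / rr$p_reference, tolerance = 1e-12)

  # a subject whose covariates are the matched cell's means has RR = 1
  grid <- fx$model$grid
  vars <- fx$model$variables
  pop <- grid[grid$n >= 5, ][1, ]
  subj <- data.frame(id = "X", age = 20 + 5 * (pop$age_bin - 1) + 2,
                     sex = pop$sex, diabetes = 0)
  for (v in vars) if (!v %in% names(subj))
    subj[[v]] <- pop[[paste0("mean_", v)]]
  subj$age <- pop$mean_age  # exact mean vector, including age
  subj$sex <- pop$mean_sex
  rr1 <- compute_rr(subj, fx$model$cluster_model, fx$model$logits, grid,
                    assignments = pop$cluster)
  expect_equal(rr1$rr, 1, tolerance = 1e-9)

  expect_error(compute_rr(data.frame(id = "a", age = 15, sex = 1),
                          fx$model$cluster_model, fx$model$logits, grid),
               "age")
})

test_that("RR increases with a positively weighted covariate", {
  fx <- trained_fixture()
  lg <- fx$model$logits
  k <- "1"
  stopifnot(lg[[k]]$coefficients[["bmi"]] != 0)
  sgn <- sign(lg[[k]]$coefficients[["bmi"]])
  base <- fx$cohort[1, ]
  bumped <- base; bumped$bmi <- base$bmi + 2 * sgn
  rr0 <- compute_rr(base, fx$model$cluster_model, lg, fx$model$grid,
                    assignments = 1L)
  rr1 <- compute_rr(bumped, fx$model$cluster_model, lg, fx$model$grid,
                    assignments = 1L)
  expect_gt(rr1$rr, rr0$rr)
})

test_that("RR is invariant under affine recoding of a covariate", {
  co <- generate_cohort(small_spec(800, seed = 61))
  # continuous variables only: at this size the partition can isolate the
  # binary variables, which makes their within-cluster fits degenerate
  vars <- c("age", "bmi", "waist", "chol", "tg", "hdl", "dbp")
  cm <- cluster_cohort(co, variables = vars, k = 2, seed = 61)
  lg <- fit_cluster_logits(co, cm$assignments, cm$variables)
  grid <- build_reference_grid(co, cm$assignments, lg, cm$variables)
  rr_orig <- compute_rr(co, cm, lg, grid, assignments = cm$assignments)
  # recode bmi -> (bmi - 20) / 5 and transform coefficients accordingly
  co2 <- co; co2$bmi <- (co$bmi - 20) / 5
  lg2 <- lg
  for (k in names(lg2)) {
    b <- lg2[[k]]$coefficients
    b[["(Intercept)"]] <- b[["(Intercept)"]] + 20 * b[["bmi"]]
    b[["bmi"]] <- 5 * b[["bmi"]]
    lg2[[k]]$coefficients <- b
  }
  grid2 <- build_reference_grid(co2, cm$assignments, lg2, cm$variables)
  rr_rec <- compute_rr(co2, cm, lg2, grid2, assignments = cm$assignments)
  expect_equal(rr_rec$rr, rr_orig$rr, tolerance = 1e-8)
})

test_that("logit evaluation matches the fitting module's predictions", {
  co <- generate_cohort(small_spec(800, seed = 62))
  fit <- fit_multivariate_logit(co, c("age", "bmi", "glu"))
  cf <- setNames(fit$coefficients$beta, fit$coefficients$variable)
  lg <- list(cluster = 1, coefficients = cf)
  ours <- predict_cluster_logit(lg, co, c("age", "bmi", "glu"))
  glmp <- as.numeric(predict(fit$fit, type = "response"))
  expect_equal(ours, glmp, tolerance = 1e-12)
})
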