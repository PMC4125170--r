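test_that("sub-cohorts partition the cohort with the documented age boundary", {
  co <- generate_cohort(small_spec(300, seed = 41))
  co$age[1] <- 50  # exact boundary
  subs <- build_sub_cohorts(co)
  expect_equal(nrow(subs$males) + nrow(subs$females), nrow(subs$all))
  expect_equal(nrow(subs$under50) + nrow(subs$over50), nrow(subs$all))
  expect_true(co$id[1] %in% subs$over50$id)
  expect_false(co$id[1] %in% subs$under50$id)

  men <- co[co$sex == 1 & co$age < 50, ]
  subs2 <- build_sub_cohorts(men)
  expect_equal(nrow(subs2$males), nrow(men))
  expect_equal(nrow(subs2$females), 0)
  expect_equal(nrow(subs2$under50), nrow(men))
  expect_error(build_sub_cohorts(data.frame(x = 1)), "age")
})

test_that("C4.5 splits match the worked examples", {
  t1 <- build_c45_tree(toy_split_data(), "y", "x",
                       c45_control(min_leaf = 1, max_depth = 5))
  expect_equal(t1$variable, "x")
  expect_equal(t1$threshold, 2.5)
  expect_equal(t1$left$label, 0)
  expect_equal(t1$right$label, 1)

  pure <- data.frame(x = 1:6, y = 0)
  t2 <- build_c45_tree(pure, "y", "x", c45_control(min_leaf = 1))
  expect_equal(t2$type, "leaf")
  expect_equal(t2$label, 0)
  expect_equal(t2$depth, 1)

  set.seed(1)
  d3 <- data.frame(x1 = rep(c(0, 1), each = 10), x2 = rnorm(20),
                   y = rep(c(0, 1), each = 10))
  t3 <- build_c45_tree(d3, "y", c("x1", "x2"), c45_control(min_leaf = 2))
  expect_equal(t3$variable, "x1")
  expect_error(build_c45_tree(d3[0, ], "y"), "zero records")
})

test_that("root split equals the exhaustive gain-ratio maximizer", {
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    p <- sample(1:3, 1)
    d <- as.data.frame(matrix(round(stats::rnorm(n * p), 1), n, p))
    names(d) <- paste0("v", seq_len(p))
    d$y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(d$y)) < 2) next
    oracle <- oracle_root_split(d, "y", paste0("v", seq_len(p)))
    tree <- build_c45_tree(d, "y", paste0("v", seq_len(p)),
                           c45_control(min_leaf = 1, max_depth = 2))
    if (is.null(oracle)) {
      expect_equal(tree$type, "leaf")
    } else {
      expect_equal(tree$variable, oracle$variable)
      expect_equal(tree$threshold, oracle$threshold)
    }
  }
})

test_that("trees are deterministic given data and fold seed", {
  co <- generate_cohort(small_spec(400, seed = 43))
  a <- cv_trees(co, "diabetes", c("age", "bmi", "glu"), folds = 5, seed = 9,
                control = c45_control(min_leaf = 10, max_depth = 4))
  b <- cv_trees(co, "diabetes", c("age", "bmi", "glu"), folds = 5, seed = 9,
                control = c45_control(min_leaf = 10, max_depth = 4))
  expect_identical(a, b)
})

test_that("tree frequencies count internal nodes within the level cut", {
  leaf <- function(depth) list(type = "leaf", label = 0, n = 1, depth = depth)
  node <- function(v, depth, l, r)
    list(type = "node", variable = v, threshold = 1, depth = depth,
         n = 2, left = l, right = r)
  tree <- node("x1", 1,
               node("x2", 2, leaf(3), leaf(3)),
               node("x2", 2, leaf(3), leaf(3)))
  class(tree) <- "c45_tree"
  expect_equal(count_tree_frequencies(list(tree)), c(x1 = 1L, x2 = 2L))

  deep <- Reduce(function(acc, d) node("deepvar", d, acc, leaf(d + 1)),
                 9:1, accumulate = FALSE,
                 init = leaf(10))
  class(deep) <- "c45_tree"
  fr <- count_tree_frequencies(list(deep), max_level = 8)
  expect_equal(unname(fr["deepvar"]), 8L)  # depths 1..8 only
  fr9 <- count_tree_frequencies(list(deep), max_level = 12)
  expect_equal(unname(fr9["deepvar"]), 9L)
})

test_that("logistic screening recovers known coefficients and flags separation", {
  set.seed(77)
  n <- 20000
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-3 + 0.8 * x))
  d <- data.frame(x = x, diabetes = y)
  fit <- fit_multivariate_logit(d, "x")
  cf <- fit$coefficients
  expect_lt(abs(cf$beta[cf$variable == "x"] - 0.8),
            2 * cf$se[cf$variable == "x"])
  expect_lt(abs(cf$beta[cf$variable == "(Intercept)"] + 3),
            2 * cf$se[cf$variable == "(Intercept)"])

  d0 <- data.frame(x = rep(1, 10), diabetes = rep(0:1, 5))
  expect_error(fit_multivariate_logit(d0, "x"), "constant")

  dsep <- data.frame(x = c(1:10), diabetes = rep(c(0, 1), each = 5))
  expect_error(fit_multivariate_logit(dsep, "x"), "separation.*x")
})

test_that("logistic estimates agree with an independent reference fit", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 300
    d <- data.frame(a = stats::rnorm(n), b = stats::runif(n))
    d$diabetes <- stats::rbinom(n, 1, stats::plogis(-1 + d$a - 0.5 * d$b))
    ours <- fit_multivariate_logit(d, c("a", "b"))
    ref <- stats::glm.fit(cbind(1, d$a, d$b), d$diabetes,
                          family = stats::binomial())
    expect_equal(unname(ours$coefficients$beta), unname(ref$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("selection intersects evidence and honors overrides", {
  freq <- c(AGE = 10, BMI = 7, TG = 6, SBP = 1)
  lr <- list(coefficients = data.frame(
    variable = c("(Intercept)", "BMI", "TG", "SBP"),
    beta = 0, se = 1, z = 0, p = c(0.5, 0.01, 0.02, 0.03),
    stringsAsFactors = FALSE))
  class(lr) <- "risk_logit"
  rep0 <- select_risk_variables(freq, lr, overrides = NULL, exclude = NULL)
  expect_setequal(rep0$final_variables, c("BMI", "TG"))

  # an override adds without removing intersected variables
  rep1 <- select_risk_variables(freq, lr, exclude = NULL,
                                overrides = list(list(variable = "HDL",
                                                      rationale = "protective factor")))
  expect_true(all(c("BMI", "TG") %in% rep1$final_variables))
  expect_true("HDL" %in% rep1$final_variables)
  expect_equal(rep1$overrides_applied[[1]]$variable, "HDL")

  expect_warning(select_risk_variables(c(A = 10), lr, overrides = NULL,
                                       exclude = NULL),
                 "empty")
})

test_that("the shipped default risk-variable set is the published nine", {
  expect_setequal(default_risk_variables(),
                  c("age", "sex", "bmi", "waist", "chol", "tg", "hdl",
                    "dbp", "psh"))
})

test_that("glycemia cutoff extraction picks the modal bin with fallbacks", {
  fake <- function(th, depth) {
    structure(list(type = "node", variable = "glu", threshold = th,
                   depth = depth, n = 10,
                   left = list(type = "leaf", label = 0, n = 5, depth = depth + 1),
                   right = list(type = "leaf", label = 1, n = 5, depth = depth + 1)),
              class = "c45_tree")
  }
  expect_equal(extract_glycemia_cutoff(list(fake(5.84, 2), fake(5.86, 3),
                                            fake(5.85, 2), fake(6.4, 1))),
               5.85, tolerance = 1e-9)
  expect_equal(extract_glycemia_cutoff(list(fake(5.9, 3))), 5.9,
               tolerance = 1e-9)
  # a split at level 9 is out of scope
  expect_true(is.na(extract_glycemia_cutoff(list(fake(5.9, 9)))))
  # tie between bins: the shallower split wins
  expect_equal(extract_glycemia_cutoff(list(fake(6.4, 2), fake(5.85, 3)),
                                       max_level = 8),
               6.4, tolerance = 1e-9)
})
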