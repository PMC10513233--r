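test_that("IRLS agrees with the reference GLM fit to high precision", {
  set.seed(14)
  for (i in 1:5) {
    n <- 200
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    eta <- 0.3 + X %*% c(0.8, -0.5, 0)
    y <- rbinom(n, 1, plogis(eta))
    ours <- fit_logistic(X, y)
    # run the reference fit to full precision so the comparison tests our
    # optimum rather than glm's looser default stopping rule
    ref <- glm(y ~ X, family = binomial(),
               control = glm.control(epsilon = 1e-13, maxit = 200))
    expect_true(ours$converged)
    expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(ours$se),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-6)
    expect_equal(unname(ours$p),
                 unname(summary(ref)$coefficients[, "Pr(>|z|)"]),
                 tolerance = 1e-6)
  }
})

test_that("labels independent of the features give near-zero slopes", {
  set.seed(3)
  n <- 2000
  X <- matrix(runif(n * 5, 0, 300), n,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(n, 1, 0.5) # shuffled labels, no dependence on X
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  # slope scale: features span ~300 units, so |beta| < 0.05 is a loose null
  expect_true(all(abs(fit$beta[-1]) < 0.05))
  expect_gt(min(fit$p[-1]), 0.001)
})

test_that("IRLS finds the maximum-likelihood optimum on small data", {
  set.seed(8)
  n <- 12
  X <- matrix(rnorm(n * 2), n)
  y <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 0)
  fit <- suppressWarnings(fit_logistic(X, y))
  ll_opt <- logistic_loglik(X, y, fit$beta)
  for (i in 1:1000) {
    ll_rand <- logistic_loglik(X, y, rnorm(3, sd = 2))
    expect_lte(ll_rand, ll_opt + 1e-9)
  }
})

test_that("adding a constant to one feature shifts only the intercept", {
  set.seed(5)
  n <- 300
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(0.2 + X %*% c(1, -1, 0.5)))
  f0 <- fit_logistic(X, y)
  X2 <- X
  X2[, 2] <- X2[, 2] + 10
  f1 <- fit_logistic(X2, y)
  expect_equal(unname(f1$beta[-1]), unname(f0$beta[-1]), tolerance = 1e-6)
  expect_equal(unname(f1$beta[1]),
               unname(f0$beta[1] - 10 * f0$beta["b"]), tolerance = 1e-6)
})

test_that("flipping the labels negates every coefficient", {
  set.seed(6)
  n <- 150
  X <- matrix(rnorm(n * 4), n)
  y <- rbinom(n, 1, plogis(X %*% c(0.5, -0.5, 0.2, 0)))
  f0 <- fit_logistic(X, y)
  f1 <- fit_logistic(X, 1 - y)
  expect_equal(unname(f1$beta), -unname(f0$beta), tolerance = 1e-6)
  expect_equal(unname(f1$se), unname(f0$se), tolerance = 1e-6)
})

test_that("degenerate labels and separation are reported, not hidden", {
  X <- matrix(rnorm(20), 10)
  expect_error(fit_logistic(X, rep(1, 10)), "one class")

  # perfectly separated feature
  Xs <- matrix(c(1:10), 10)
  ys <- c(rep(0, 5), rep(1, 5))
  expect_warning(fit <- fit_logistic(Xs, ys), "separation")
  expect_false(fit$converged)
})

test_that("coefficient table preserves order and full precision through CSV", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60,
              dimnames = list(NULL, bin_scheme()$labels))
  y <- rbinom(60, 1, 0.5)
  fit <- fit_logistic(X, y)
  tab <- coefficient_table(fit)
  expect_equal(tab$term, c("(Intercept)", bin_scheme()$labels))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$estimate, tab$estimate, tolerance = 1e-12)
  expect_equal(back$p, tab$p, tolerance = 1e-12)
})
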