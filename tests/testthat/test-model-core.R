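# Cumulative-link model: probabilities, likelihood, MLE, Wald inference.

test_that("cumulative probabilities follow the probit convention", {
  expect_equal(cum_prob(0, beta = 0, x = 3.7, level = 1), 0.5)
  expect_equal(cum_prob(1, beta = 1, x = 1, level = 1), 0.5)
  expect_equal(cum_prob(c(-1, 1), beta = 0.5, x = 2, level = 2), pnorm(0))
  expect_equal(cum_prob(c(-1, 1), beta = 0.5, x = 2, level = 1), pnorm(-2))
  # monotone nondecreasing in the level index at fixed x
  p <- vapply(1:3, function(i) cum_prob(c(-1, 0, 2), 1.2, x = 0.4, level = i),
              numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_error(cum_prob(c(1, -1), 0, 0, 1), "increasing")
})

test_that("negative log-likelihood matches direct Gaussian-CDF summation", {
  # single sample, two levels, alpha = 0, beta = 0, lowest grade
  expect_equal(ordreg_nll(0, 0, x = 0.3, grades = 0L), log(2))
  # 4-sample toy against a hand-summed oracle
  x <- c(-1, 0, 1, 2); y <- c(0L, 0L, 1L, 1L)
  oracle <- -(log(pnorm(0.2 + 0.9)) + log(pnorm(0.2)) +
                log(1 - pnorm(0.2 - 0.9)) + log(1 - pnorm(0.2 - 1.8)))
  expect_equal(ordreg_nll(0.2, 0.9, x, y), oracle, tolerance = 1e-10)
  # k = 1 is binary probit regression on the same data
  set.seed(4)
  xb <- rnorm(25); yb <- as.integer(runif(25) < pnorm(-0.3 + 0.8 * xb))
  expect_equal(ordreg_nll(-0.3, -0.8, xb, yb),
               binary_probit_nll(-0.3, -0.8, xb, yb), tolerance = 1e-12)
  # zero-probability observation gives +Inf, not an error
  expect_identical(ordreg_nll(0, 1, x = 45, grades = 0L), Inf)
})

test_that("category probabilities are normalized for arbitrary parameters", {
  set.seed(9)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    alphas <- sort(rnorm(k, sd = 2)); alphas <- alphas + 1e-3 * seq_len(k)
    beta <- rnorm(1, sd = 2)
    x <- rnorm(5)
    cp <- cbind(0, vapply(seq_len(k), function(i)
      cum_prob(alphas, beta, x, i), numeric(5)), 1)
    probs <- t(apply(cp, 1, diff))
    expect_true(all(probs >= 0))
    expect_equal(rowSums(probs), rep(1, 5))
    # P(Y <= i | x) nonincreasing in x when beta > 0
    if (beta > 0) {
      xs <- sort(rnorm(6))
      expect_true(all(diff(cum_prob(alphas, beta, xs, 1)) <= 0))
    }
  }
})

test_that("grade-symmetric balanced data force a zero slope", {
  x <- rep(c(-1, 0, 1), each = 3)
  y <- rep(c(0L, 1L, 2L), times = 3)
  fit <- ordreg_fit(x, y)
  expect_lt(abs(fit$beta), 1e-6)
})

test_that("the k = 1 fit agrees with binary probit regression", {
  set.seed(21)
  x <- rnorm(80)
  y <- as.integer(runif(80) < pnorm(-0.4 + 1.1 * x))
  fit <- ordreg_fit(x, y)
  g <- suppressWarnings(glm(y ~ x, family = binomial("probit"),
                            control = glm.control(epsilon = 1e-14)))
  # P(Y = 1 | x) = Phi(b0 + b1 x) maps to alpha = -b0, beta = b1
  expect_equal(fit$beta, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(unname(fit$alphas), -unname(coef(g)[1]), tolerance = 1e-6)
})

test_that("the MLE beats a dense grid-search oracle on a small instance", {
  set.seed(33)
  sim <- simulate_ordinal_cohort(1, n_samples = 60, n_levels = 3,
                                 pag_fraction = 1, beta_range = c(1, 1),
                                 mean_range = c(0, 0), seed = 33)
  x <- sim$expr[1, ]; y <- sim$phenotype$grades
  fit <- ordreg_fit(x, y)
  nll_mle <- ordreg_nll(fit$alphas, fit$beta, x, y)
  grid <- expand.grid(a1 = fit$alphas[1] + seq(-0.1, 0.1, by = 0.01),
                      gap = diff(fit$alphas) + seq(-0.1, 0.1, by = 0.01),
                      b = fit$beta + seq(-0.1, 0.1, by = 0.01))
  grid <- grid[grid$gap > 0, ]
  nll_grid <- mapply(function(a1, gap, b)
    ordreg_nll(c(a1, a1 + gap), b, x, y), grid$a1, grid$gap, grid$b)
  expect_lte(nll_mle, min(nll_grid) + 1e-6)
})

test_that("the fit matches or beats the reference polr optimizer", {
  skip_if_not_installed("MASS")
  set.seed(55)
  sim <- simulate_ordinal_cohort(1, n_samples = 200, pag_fraction = 1,
                                 beta_range = c(1.5, 1.5), seed = 55)
  x <- sim$expr[1, ]; y <- sim$phenotype$grades
  fit <- ordreg_fit(x, y)
  pol <- MASS::polr(factor(y, ordered = TRUE) ~ x, method = "probit")
  expect_equal(fit$beta, unname(pol$coefficients), tolerance = 1e-3)
  expect_equal(unname(fit$alphas), unname(pol$zeta), tolerance = 1e-3)
  # our solution is at least as good in likelihood
  expect_lte(ordreg_nll(fit$alphas, fit$beta, x, y),
             ordreg_nll(pol$zeta, pol$coefficients, x, y) + 1e-8)
})

test_that("the slope is recovered within Wald uncertainty at n = 1000", {
  sim <- simulate_ordinal_cohort(1, n_samples = 1000, pag_fraction = 1,
                                 beta_range = c(1.5, 1.5), seed = 77)
  x <- sim$expr[1, ]; y <- sim$phenotype$grades
  beta_true <- sim$truth$beta[1]
  fit <- ordreg_fit(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - beta_true), 3 * fit$se_beta)
  # implied intercepts are recovered too
  expect_equal(unname(fit$alphas), attr(sim$truth, "alphas")[1, ],
               tolerance = 0.2)
})

test_that("degenerate inputs are refused with clear errors", {
  expect_error(ordreg_fit(rep(1, 10), rep(0:1, 5)), "constant")
  expect_error(ordreg_fit(rnorm(10), rep(0L, 10)), "2 observed")
})

test_that("the formula interface and S3 methods are coherent", {
  sim <- simulate_ordinal_cohort(1, n_samples = 150, pag_fraction = 1,
                                 seed = 8)
  d <- data.frame(grade = factor(sim$phenotype$grades, ordered = TRUE),
                  expr = sim$expr[1, ])
  fit <- ordreg(grade ~ expr, d)
  expect_s3_class(fit, "ordreg")
  expect_named(coef(fit), c("alpha1", "alpha2", "alpha3", "beta"))
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(c(fit$se_alphas, fit$se_beta)))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  s <- summary(fit)
  expect_true(all(s$coefficients[, "Pr(>|z|)"] >= 0 &
                    s$coefficients[, "Pr(>|z|)"] <= 1))
  pr <- predict(fit, newdata = c(7, 9, 11), type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 3))
  sims <- simulate(fit, nsim = 2, seed = 1, newdata = sim$expr[1, ])
  expect_true(all(unlist(sims) %in% 0:3))
  expect_output(print(fit), "proportional-odds")
})
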