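test_that("a perfectly balanced symmetric design gives exactly zero coefficients", {
  fit <- fit_logistic(c(0, 1, 0, 1), c(-1, -1, 1, 1))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), c(0, 0))
})

test_that("IRLS matches the brute-force likelihood grid and stats::glm", {
  withr::with_seed(11, {
    x <- rnorm(20)
    y <- rbinom(20, 1, plogis(-1 + 0.5 * x))
  })
  fit <- fit_logistic(y, x)
  grid <- oracle_logistic_grid(y, x)
  expect_lt(max(abs(unname(fit$coefficients) - grid)), 1e-4)

  # stats::glm stops on a deviance criterion, ours on coefficient change,
  # so agreement is limited by glm's own tolerance
  ref <- stats::glm(y ~ x, family = binomial())
  expect_lt(max(abs(unname(fit$coefficients) - unname(coef(ref)))), 1e-5)
  expect_lt(max(abs(unname(fit$standard_errors) -
                      unname(summary(ref)$coefficients[, 2]))), 1e-5)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
})

test_that("single-class outcomes are refused as separation", {
  expect_error(fit_logistic(rep(1, 10), rnorm(10)), "separation")
  expect_error(fit_logistic(rep(0, 10), rnorm(10)), "separation")
})

test_that("the score vector vanishes at the fitted coefficients", {
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      x <- rnorm(40, sd = 2)
      y <- rbinom(40, 1, plogis(0.3 - 0.4 * x))
    })
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(y, x)
    mu <- plogis(fit$coefficients[1] + fit$coefficients[2] * x)
    score <- c(sum(y - mu), sum((y - mu) * x))
    expect_lt(max(abs(score)), 1e-6)
  }
})

test_that("logistic fit is order-invariant and equivariant to affine rescaling", {
  withr::with_seed(21, {
    x <- rnorm(60, mean = 73, sd = 5)
    y <- rbinom(60, 1, plogis(0.2 * (x - 73)))
  })
  fit <- fit_logistic(y, x)
  perm <- withr::with_seed(22, sample(60))
  fit_perm <- fit_logistic(y[perm], x[perm])
  expect_equal(fit$coefficients, fit_perm$coefficients, tolerance = 1e-9)

  a <- 2.5; c0 <- -10
  fit_resc <- fit_logistic(y, a * x + c0)
  expect_equal(unname(fit_resc$coefficients[2]),
               unname(fit$coefficients[2]) / a, tolerance = 1e-6)
  expect_equal(unname(fit_resc$coefficients[1]),
               unname(fit$coefficients[1]) -
                 unname(fit$coefficients[2]) * c0 / a,
               tolerance = 1e-6)
})

test_that("under a true null slope the Wald z rejects at the nominal rate", {
  # 1000 cohorts of the study's size with outcome independent of mass
  n_cohorts <- 1000
  rejected <- withr::with_seed(3030, {
    vapply(seq_len(n_cohorts), function(i) {
      mass <- runif(171, 60.5, 86.3)
      y <- rbinom(171, 1, 89 / 171)
      if (length(unique(y)) < 2) return(NA)
      fit <- fit_logistic(y, mass)
      abs(fit$z_values[["slope"]]) > qnorm(0.975)
    }, logical(1))
  })
  rate <- mean(rejected, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("OLS recovers an exact line and matches the matrix closed form", {
  x <- 1:5
  fit <- fit_ols(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  for (s in 1:5) {
    withr::with_seed(200 + s, {
      xr <- rnorm(30, 200, 60)
      yr <- 70 + 0.02 * xr + rnorm(30, sd = 6)
    })
    fit <- fit_ols(xr, yr)
    orc <- oracle_ols_matrix(xr, yr)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$slope_se, orc$slope_se, tolerance = 1e-10)
    ref <- stats::lm(yr ~ xr)
    expect_equal(fit$p_value, summary(ref)$coefficients[2, 4],
                 tolerance = 1e-10)
  }
})

test_that("degenerate OLS designs are refused", {
  expect_error(fit_ols(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_ols(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Wald test matches the reference distributions and refuses bad fits", {
  fit <- fit_logistic(c(0, 1, 0, 1), c(-1, -1, 1, 1))
  w <- wald_test(fit, 2)
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1)

  # z at the 97.5% normal quantile gives p ~= 0.05
  fake <- fit
  fake$coefficients[2] <- 1.959964
  fake$standard_errors[2] <- 1
  expect_equal(wald_test(fake, 2)$p, 0.05, tolerance = 1e-6)

  ofit <- fit_ols(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(wald_test(ofit)$statistic, ofit$t_value)
  zero_t <- fit_ols(c(-1, -1, 1, 1), c(0, 1, 0, 1))
  expect_equal(wald_test(zero_t)$p, 1)

  bad <- fit
  bad$converged <- FALSE
  expect_error(wald_test(bad), "converge")
})

test_that("RPM is prey over predator mass, only for successful ingestions", {
  rpm <- compute_rpm(list(outcome = "INGESTED", prey_mass_g = 71.9,
                          predator_mass_g = 90))
  expect_equal(round(100 * rpm, 1), 79.9)
  expect_equal(compute_rpm(list(outcome = "INGESTED", prey_mass_g = 100,
                                predator_mass_g = 100)), 1)
  # double meal: summed prey mass over one predator
  expect_equal(compute_rpm(list(outcome = "INGESTED", prey_mass_g = 60,
                                predator_mass_g = 100)), 0.6)
  expect_error(compute_rpm(list(outcome = "SLIMED", prey_mass_g = 70,
                                predator_mass_g = NA)), "SLIMED")
  expect_error(compute_rpm(list(outcome = "INGESTED", prey_mass_g = 70,
                                predator_mass_g = NA)), "missing")
})

test_that("RPM summaries match a direct recomputation and handle exclusions", {
  events <- data.frame(
    bird_ids = c("a", "b", "c;d", "e"),
    prey_mass_g = c(70, 80, 140, 75),
    outcome = c("INGESTED", "INGESTED", "INGESTED", "SLIMED"),
    snake_event_id = c("e1", "e2", "e3", NA),
    predator_mass_g = c(350, 200, 210, NA)
  )
  s <- rpm_summary(events)
  vals <- c(70 / 350, 80 / 200, 140 / 210)
  expect_equal(s$values, vals)
  expect_equal(s$mean, mean(vals))
  expect_equal(s$se, sd(vals) / sqrt(3))
  expect_equal(s$min, min(vals))
  expect_equal(s$max, max(vals))

  # dropping the double meal changes n by exactly one
  s2 <- rpm_summary(events, exclude_multi_prey = TRUE)
  expect_equal(s$n - s2$n, 1)
  expect_equal(s2$n_multi_prey_excluded, 1)
  expect_true(all(s$values > 0))

  one <- rpm_summary(events[1, ])
  expect_equal(one$mean, 0.2)
  expect_equal(one$n, 1)
  expect_true(is.na(one$se))

  expect_error(rpm_summary(events[4, ]), "no eligible")
})
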