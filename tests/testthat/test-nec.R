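test_that("threshold mean function matches hand evaluations", {
  expect_equal(nec_model_mean(-3, 1, 1, 0, 0), 1)
  expect_equal(nec_model_mean(0, 1, 1, 0, 0), 1)   # indicator off at x = gamma
  expect_equal(nec_model_mean(1, 1, 1, 0, 0), exp(-1), tolerance = 1e-12)
  expect_equal(nec_model_mean(5, 2, 0, 1, 0.3), 1.7) # beta = 0: flat
  expect_equal(nec_model_mean(0.5, 1.2, 2, 0.5, 0.1), 1.1) # alpha - delta at gamma
})

test_that("threshold mean is continuous at gamma and non-increasing", {
  set.seed(51)
  for (k in 1:25) {
    alpha <- runif(1, 0.5, 2)
    beta <- runif(1, 0, 4)
    gamma <- runif(1, -2, 3)
    delta <- runif(1, -0.3, 0.3)
    eps <- 1e-9
    expect_equal(nec_model_mean(gamma - eps, alpha, beta, gamma, delta),
                 nec_model_mean(gamma + eps, alpha, beta, gamma, delta),
                 tolerance = 1e-6)
    x <- sort(runif(40, -3, 5))
    mu <- nec_model_mean(x, alpha, beta, gamma, delta)
    expect_true(all(diff(mu) <= 1e-12))
  }
})

test_that("sampler likelihood agrees with an independent gaussian log-density", {
  nd <- simulate_from_nec(list(alpha = 1, beta = 1.5, gamma = log(10),
                               delta = 0, sigma = 0.05),
                          log(10^seq(0, 2, length.out = 7)), 5, seed = 52)
  set.seed(53)
  for (k in 1:10) {
    p <- list(alpha = runif(1, 0.5, 1.5), beta = runif(1, 0.1, 3),
              gamma = runif(1, 0, 4), delta = runif(1, -0.2, 0.2),
              sigma = runif(1, 0.01, 0.3))
    mu <- p$alpha * exp(-p$beta * pmax(nd$x - p$gamma, 0)) - p$delta
    direct <- sum(-0.5 * log(2 * pi) - log(p$sigma) -
                    (nd$y - mu)^2 / (2 * p$sigma^2))
    expect_equal(nec_loglik(p, nd), direct, tolerance = 1e-9)
  }
})

test_that("design matrix converts inhibition and places controls a decade below", {
  ds <- make_assay(seed = 54)
  tbl <- endpoint_table(ds)
  nd <- nec_design_matrix(tbl, "sgr")
  reps <- merge(tbl$replicates, tbl$treatments[c("treatment", "twa_conc")],
                by = "treatment")
  reps <- reps[reps$role != "reference", ]
  expect_length(nd$x, nrow(reps))
  # y = 1 - inhibition/100
  i <- which(!nd$is_control)[1]
  test_reps <- reps[reps$role == "test", ]
  expect_setequal(round(nd$y[!nd$is_control], 10),
                  round(1 - test_reps$sgr_inhibition / 100, 10))
  # control placement: one decade below the lowest treatment TWA
  low <- min(reps$twa_conc[reps$role == "test"])
  expect_equal(unique(nd$x[nd$is_control]), log(low / 10), tolerance = 1e-12)
  expect_match(nd$control_x_policy, "10")
  # half-decade policy option
  nd2 <- nec_design_matrix(tbl, "sgr", control_decades = 0.5)
  expect_equal(unique(nd2$x[nd2$is_control]), log(low / 10^0.5),
               tolerance = 1e-12)
  # inhibition 0 maps to y = 1, inhibition 50 to y = 0.5
  expect_equal(1 - 0 / 100, 1)
  expect_equal(mean(nd$y[nd$is_control]), 1, tolerance = 0.05)
})

test_that("posterior recovers a known threshold and is seed-deterministic", {
  params <- list(alpha = 1, beta = 1.5, gamma = log(10), delta = 0,
                 sigma = 0.02)
  nd <- simulate_from_nec(params, log(10^seq(0, 2, length.out = 7)), 5,
                          seed = 7)
  fit <- suppressWarnings(fit_nec(nd, chains = 2, iter = 4000,
                                  burnin = 2000, seed = 3))
  expect_gt(fit$nec_value, 8)
  expect_lt(fit$nec_value, 12.5)
  expect_true(fit$nec_ci[1] <= fit$nec_value &&
                fit$nec_value <= fit$nec_ci[2])
  fit2 <- suppressWarnings(fit_nec(nd, chains = 2, iter = 4000,
                                   burnin = 2000, seed = 3))
  expect_identical(fit$draws, fit2$draws)
  expect_identical(fit$nec_value, fit2$nec_value)
  fit3 <- suppressWarnings(fit_nec(nd, chains = 2, iter = 4000,
                                   burnin = 2000, seed = 4))
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("default chains converge by R-hat and ESS", {
  params <- list(alpha = 1, beta = 1.5, gamma = log(10), delta = 0,
                 sigma = 0.02)
  nd <- simulate_from_nec(params, log(10^seq(0, 2, length.out = 7)), 5,
                          seed = 8)
  fit <- fit_nec(nd, seed = 5)
  expect_true(fit$convergence_ok)
  expect_true(all(fit$diagnostics$rhat <= 1.05))
  expect_true(all(fit$diagnostics$ess >= 400))
})

test_that("posterior predictive mean at control x is self-consistent", {
  params <- list(alpha = 1, beta = 1.5, gamma = log(10), delta = 0,
                 sigma = 0.02)
  nd <- simulate_from_nec(params, log(10^seq(0, 2, length.out = 7)), 5,
                          seed = 9)
  fit <- suppressWarnings(fit_nec(nd, chains = 2, iter = 4000,
                                  burnin = 2000, seed = 6))
  x0 <- min(nd$x)
  expect_equal(predict(fit, x0),
               mean(fit$draws[, "alpha"] - fit$draws[, "delta"]),
               tolerance = 1e-9)
})

test_that("NEC summary reduces the exp(gamma) draws correctly", {
  stub <- function(gamma_draws) {
    draws <- cbind(alpha = 1, beta = 1, gamma = gamma_draws, delta = 0,
                   sigma = 0.1)
    nec <- exp(gamma_draws)
    qs <- quantile(nec, c(0.025, 0.5, 0.975), names = FALSE)
    structure(list(draws = draws, nec_value = qs[2],
                   nec_ci = c(qs[1], qs[3]), censored = FALSE,
                   max_conc = 100), class = "nec_fit")
  }
  s1 <- nec_summary(stub(rep(log(5), 100)))
  expect_equal(s1$nec_value, 5)
  expect_equal(s1$nec_ci, c(5, 5))
  # uniform grid in log space: median is the geometric midpoint (up to the
  # interpolation between the two central order statistics)
  s2 <- nec_summary(stub(seq(log(1), log(100), length.out = 100)))
  expect_equal(s2$nec_value, 10, tolerance = 1e-3)

  cen <- censored_nec(4570)
  s3 <- nec_summary(cen)
  expect_true(s3$censored)
  expect_identical(s3$display, "> 4570")
})

test_that("simulate_from_nec honours sigma and the indicator", {
  params <- list(alpha = 1, beta = 1, gamma = log(10), delta = 0, sigma = 0)
  nd <- simulate_from_nec(params, log(c(1, 2, 5, 10)), 3, seed = 10)
  expect_equal(nd$y, rep(1, 12), tolerance = 1e-12) # all x <= gamma, no noise
  params$sigma <- 0.05
  nd2 <- simulate_from_nec(params, log(c(1, 2, 5)), 20, seed = 11)
  expect_lt(abs(mean(nd2$y) - 1), 3 * 0.05 / sqrt(60))
})
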