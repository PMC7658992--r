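test_that("noiseless 4PL curves are recovered to near machine precision", {
  truth <- c(bottom = 0, top = 100, hill = 1, log_ec50 = 1)
  conc <- 10^seq(0, 2, length.out = 7)
  y <- fourpl_response(conc, truth["bottom"], truth["top"], truth["hill"],
                       truth["log_ec50"])
  fit <- fit_4pl(rep(conc, each = 5), rep(y, each = 5))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[c("top", "hill", "log_ec50")]),
               unname(truth[c("top", "hill", "log_ec50")]),
               tolerance = 1e-6)
  expect_lt(abs(coef(fit)[["bottom"]]), 1e-4) # relative error undefined at 0
  expect_equal(10^coef(fit)[["log_ec50"]], 10, tolerance = 1e-6)

  # steeper curve with a nonzero floor
  truth2 <- c(bottom = 5, top = 95, hill = 2.5, log_ec50 = 0.5)
  y2 <- fourpl_response(conc, truth2["bottom"], truth2["top"],
                        truth2["hill"], truth2["log_ec50"])
  fit2 <- fit_4pl(conc, y2)
  expect_equal(unname(coef(fit2)), unname(truth2), tolerance = 1e-6)
})

test_that("fit matches a brute-force SSE grid search oracle", {
  set.seed(41)
  conc <- c(1, 5, 25, 125)
  truth <- c(bottom = 0, top = 100, hill = 1, log_ec50 = 1)
  y <- fourpl_response(rep(conc, each = 3), truth["bottom"], truth["top"],
                       truth["hill"], truth["log_ec50"]) + rnorm(12, 0, 3)
  x <- rep(conc, each = 3)
  fit <- fit_4pl(x, y)

  grid <- expand.grid(bottom = seq(-10, 10, 1),
                      top = seq(85, 115, 1),
                      hill = seq(0.4, 2, 0.1),
                      log_ec50 = seq(0, 2, 0.05))
  sse <- apply(grid, 1, function(p) {
    sum((y - fourpl_response(x, p[1], p[2], p[3], p[4]))^2)
  })
  best <- grid[which.min(sse), ]
  # optimizer must be at least as good as the best grid point
  expect_lte(fit$sse, min(sse) + 1e-9)
  # and land near the grid optimum (asymptotes share a shallow ridge, so
  # allow two grid steps there; midpoint and slope are well identified)
  expect_lt(abs(coef(fit)[["bottom"]] - best$bottom), 2)
  expect_lt(abs(coef(fit)[["top"]] - best$top), 2)
  expect_lt(abs(coef(fit)[["hill"]] - best$hill), 0.2)
  expect_lt(abs(coef(fit)[["log_ec50"]] - best$log_ec50), 0.1)
})

test_that("fit is invariant to replicate order and concentration rescaling", {
  ds <- make_assay(seed = 42)
  tbl <- endpoint_table(ds)
  reps <- merge(tbl$replicates, tbl$treatments[c("treatment", "twa_conc")],
                by = "treatment")
  tr <- reps[reps$role == "test", ]
  fit <- fit_4pl(tr$twa_conc, tr$sgr_inhibition)
  set.seed(1)
  perm <- sample(nrow(tr))
  fit_perm <- fit_4pl(tr$twa_conc[perm], tr$sgr_inhibition[perm])
  expect_equal(coef(fit), coef(fit_perm), tolerance = 1e-5)
  # ng/L instead of ug/L: ECx rescales by 1000, shape unchanged
  fit_ng <- fit_4pl(tr$twa_conc * 1000, tr$sgr_inhibition)
  expect_equal(coef(fit_ng)[["hill"]], coef(fit)[["hill"]], tolerance = 1e-6)
  expect_equal(ec_x(fit_ng, 50)$value, 1000 * ec_x(fit, 50)$value,
               tolerance = 1e-6)
})

test_that("design errors are raised for deficient inputs", {
  expect_error(fit_4pl(c(1, 2, 3), c(10, 20, 30)), "4 distinct")
  expect_warning(fit_4pl(c(0, 1, 2, 4, 8, 16), c(0, 5, 10, 30, 60, 90)),
                 "concentration <= 0")
})

test_that("ec_x inverts the closed-form Hill expression", {
  mk <- function(bottom, top, hill, log_ec50, max_tested = 1e6) {
    structure(list(coefficients = c(bottom = bottom, top = top, hill = hill,
                                    log_ec50 = log_ec50),
                   converged = TRUE, max_tested = max_tested),
              class = "fourpl_fit")
  }
  expect_equal(ec_x(mk(0, 100, 1, 1), 50)$value, 10, tolerance = 1e-12)
  expect_equal(ec_x(mk(0, 100, 1, 1), 10)$value, 10 * (10 / 90)^(1),
               tolerance = 1e-9)
  expect_equal(ec_x(mk(0, 100, 2, 1), 10)$value, 10 * (1 / 9)^(1 / 2),
               tolerance = 1e-9)

  # evaluating the curve at ec_x(level) returns level, 100 random models
  set.seed(43)
  for (k in 1:100) {
    bottom <- runif(1, -20, 20)
    top <- runif(1, 60, 120)
    hill <- runif(1, 0.3, 5)
    le <- runif(1, -1, 3)
    lev <- runif(1, bottom + 1, top - 1)
    f <- mk(bottom, top, hill, le)
    e <- ec_x(f, lev)
    expect_false(e$censored)
    expect_equal(fourpl_response(e$value, bottom, top, hill, le), lev,
                 tolerance = 1e-9)
  }
})

test_that("ECx ordering and censoring rules hold", {
  mk <- function(..., max_tested = 1e6) {
    structure(list(coefficients = c(...), converged = TRUE,
                   max_tested = max_tested), class = "fourpl_fit")
  }
  f <- mk(bottom = 0, top = 100, hill = 1.3, log_ec50 = 1)
  expect_lt(ec_x(f, 10)$value, ec_x(f, 50)$value)
  # level above the top asymptote: censored at max tested, not an error
  f2 <- mk(bottom = 0, top = 40.0001, hill = 1, log_ec50 = 1,
           max_tested = 500)
  e <- ec_x(f2, 50)
  expect_true(e$censored)
  expect_equal(e$value, 500)
  # solution beyond the tested range: censored
  f3 <- mk(bottom = 0, top = 100, hill = 1, log_ec50 = 4, max_tested = 100)
  expect_true(ec_x(f3, 50)$censored)
})

test_that("bootstrap intervals are deterministic and degenerate at zero noise", {
  conc <- 10^seq(0, 2, length.out = 7)
  y <- fourpl_response(conc, 0, 100, 1, 1)
  x5 <- rep(conc, each = 5)
  y5 <- rep(y, each = 5)
  ci <- bootstrap_ci(x5, y5, level = 50, n_boot = 50, seed = 7)
  expect_equal(ci$ci_low, ci$value, tolerance = 1e-6)
  expect_equal(ci$ci_high, ci$value, tolerance = 1e-6)

  set.seed(44)
  yn <- y5 + rnorm(length(y5), 0, 5)
  ci1 <- bootstrap_ci(x5, yn, level = 50, n_boot = 100, seed = 11)
  ci2 <- bootstrap_ci(x5, yn, level = 50, n_boot = 100, seed = 11)
  expect_identical(ci1[c("ci_low", "ci_high")], ci2[c("ci_low", "ci_high")])
  ci3 <- bootstrap_ci(x5, yn, level = 50, n_boot = 100, seed = 12)
  expect_false(identical(ci1$ci_low, ci3$ci_low))
  expect_true(ci1$ci_low <= ci1$value && ci1$value <= ci1$ci_high)
})

test_that("one-way ANOVA matches hand and aov computations", {
  # identical groups: no between-group signal
  t1 <- fake_endpoint_table(c(1, 2, 3, 1, 2, 3),
                            rep(c("A", "B"), each = 3),
                            c(A = 0, B = 10), roles = rep(c("control", "test"),
                                                          each = 3))
  a1 <- nonresponse_anova(t1, "sgr")
  expect_equal(a1$f_statistic, 0)
  expect_equal(a1$p_value, 1)

  # clear separation with tiny jitter
  set.seed(45)
  vals <- c(1, 1, 1, 2, 2, 2) + rnorm(6, 0, 1e-4)
  t2 <- fake_endpoint_table(vals, rep(c("A", "B"), each = 3),
                            c(A = 0, B = 10),
                            roles = rep(c("control", "test"), each = 3))
  expect_lt(nonresponse_anova(t2, "sgr")$p_value, 1e-3)

  # three groups {0,1},{1,2},{2,3}: F = 4 on (2,3) df (aov oracle)
  t3 <- fake_endpoint_table(c(0, 1, 1, 2, 2, 3),
                            rep(c("A", "B", "C"), each = 2),
                            c(A = 0, B = 1, C = 2),
                            roles = rep(c("control", "test", "test"),
                                        each = 2))
  a3 <- nonresponse_anova(t3, "sgr")
  expect_equal(a3$df_between, 2)
  expect_equal(a3$df_within, 3)
  expect_equal(a3$f_statistic, 4, tolerance = 1e-12)

  # exact separation with zero within-group variance
  t4 <- fake_endpoint_table(c(1, 1, 1, 2, 2, 2),
                            rep(c("A", "B"), each = 3),
                            c(A = 0, B = 10),
                            roles = rep(c("control", "test"), each = 3))
  a4 <- nonresponse_anova(t4, "sgr")
  expect_equal(a4$p_value, 0)
  expect_match(a4$note, "separation")
})

test_that("response classification requires both censoring conditions", {
  # flat assay: nonresponsive
  flat <- make_flat_assay(seed = 46)
  tf <- endpoint_table(flat)
  cf <- classify_response(tf, "sgr")
  expect_false(cf$responsive)

  # sigmoid assay: responsive
  resp <- make_assay(seed = 47)
  cr <- classify_response(endpoint_table(resp), "sgr")
  expect_true(cr$responsive)

  # significant ANOVA overrides a small top-concentration inhibition
  set.seed(48)
  concs <- c(control = 0, T1 = 1, T2 = 2, T3 = 4, T4 = 8)
  vals <- c(rnorm(5, 1.5, 0.005),        # control
            rnorm(5, 1.56, 0.005),       # weak stimulation, significant
            rnorm(5, 1.44, 0.005),
            rnorm(5, 1.55, 0.005),
            rnorm(5, 1.47, 0.005))       # top: ~2% inhibition only
  tb <- fake_endpoint_table(vals, rep(names(concs), each = 5), concs,
                            roles = rep(c("control", rep("test", 4)),
                                        each = 5))
  cls <- classify_response(tb, "sgr")
  expect_lt(cls$p_value, 0.05)
  expect_lt(cls$top_inhibition, 10)
  expect_true(cls$responsive)
})
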