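test_that("specific growth rate matches hand evaluations", {
  expect_equal(specific_growth_rate(1000, 1000, 0, 3), 0)
  expect_equal(specific_growth_rate(1000, 2000, 0, 1), log(2))
  expect_equal(specific_growth_rate(3000, 2.0e5, 0, 3), 1.400,
               tolerance = 1e-3)
  expect_lt(specific_growth_rate(2000, 1000, 0, 1), 0) # decline allowed
  expect_error(specific_growth_rate(0, 1000, 0, 3), "positive")
  expect_error(specific_growth_rate(1000, 1000, 3, 3), "t_j")
})

test_that("growth rate over [0,3] is the time-weighted mean of sub-interval rates", {
  x0 <- 3000
  x1 <- 7000
  x3 <- 1.9e5
  r01 <- specific_growth_rate(x0, x1, 0, 1)
  r13 <- specific_growth_rate(x1, x3, 1, 3)
  r03 <- specific_growth_rate(x0, x3, 0, 3)
  expect_equal(r03, (1 * r01 + 2 * r13) / 3, tolerance = 1e-12)
})

test_that("effective quantum yield matches hand evaluations and bounds", {
  expect_equal(effective_quantum_yield(500, 500), 0)
  expect_equal(effective_quantum_yield(0, 500), 1)
  expect_equal(effective_quantum_yield(261, 500), 0.478)
  expect_error(effective_quantum_yield(501, 500), "F must")
  expect_error(effective_quantum_yield(10, 0), "Fm")
})

test_that("percent inhibition is exact, unclipped, affine and scale-invariant", {
  expect_equal(percent_inhibition(1.68, 1.68), 0)
  expect_equal(percent_inhibition(1.68, 0), 100)
  expect_equal(percent_inhibition(1.68, 0.84), 50)
  expect_equal(percent_inhibition(1.5, 1.8), -20) # stimulation preserved
  expect_error(percent_inhibition(0, 1), "zero")
  # affine in treatment, invariant under common rescaling
  set.seed(5)
  for (k in 1:20) {
    xc <- runif(1, 0.5, 2)
    xt <- runif(2, 0, 2)
    w <- runif(1, 0.2, 0.8)
    mix <- percent_inhibition(xc, w * xt[1] + (1 - w) * xt[2])
    expect_equal(mix, w * percent_inhibition(xc, xt[1]) +
                   (1 - w) * percent_inhibition(xc, xt[2]),
                 tolerance = 1e-12)
    s <- runif(1, 0.1, 10)
    expect_equal(percent_inhibition(s * xc, s * xt[1]),
                 percent_inhibition(xc, xt[1]), tolerance = 1e-12)
  }
})

test_that("TWA is the geometric mean, below the arithmetic mean", {
  expect_equal(twa_concentration(10, 2.5), 5)
  expect_equal(twa_concentration(12, 3), 6)
  expect_equal(twa_concentration(7.3, 7.3), 7.3)
  expect_error(twa_concentration(0, 5), "positive")
  set.seed(6)
  cs <- runif(50, 0.01, 100)
  ce <- runif(50, 0.01, 100)
  expect_true(all(twa_concentration(cs, ce) <= (cs + ce) / 2 + 1e-12))
  expect_equal(twa_concentration(cs, cs), cs, tolerance = 1e-12)
})

test_that("noiseless synthetic assay round-trips the truth curve exactly", {
  ds <- make_assay(seed = 21, noise = FALSE)
  tbl <- endpoint_table(ds)
  truth <- truth_model(curve = list(bottom = 0, top = 100, hill = 1,
                                    ec50 = 10))
  tr <- tbl$treatments[tbl$treatments$role == "test", ]
  agg <- aggregate(sgr_inhibition ~ treatment, tbl$replicates, mean)
  obs <- agg$sgr_inhibition[match(tr$treatment, agg$treatment)]
  expected <- truth_inhibition(truth, tr$twa_conc, "sgr")
  expect_equal(obs, expected, tolerance = 1e-10)
  # yield endpoint recovers the shifted curve
  aggy <- aggregate(yield_inhibition ~ treatment, tbl$replicates, mean)
  obsy <- aggy$yield_inhibition[match(tr$treatment, aggy$treatment)]
  expect_equal(obsy, truth_inhibition(truth, tr$twa_conc, "yield"),
               tolerance = 1e-8)
  # control inhibition is 0 by construction
  ctrl <- tbl$replicates$role == "control"
  expect_equal(mean(tbl$replicates$sgr_inhibition[ctrl]), 0,
               tolerance = 1e-12)
})

test_that("exposure metric uses measured TWA with flagged nominal fallback", {
  ds <- make_assay(seed = 22)
  tbl <- endpoint_table(ds)
  tr <- tbl$treatments
  i <- which(tr$role == "test")[1]
  rows <- ds$data$treatment == tr$treatment[i]
  expect_equal(tr$twa_conc[i],
               twa_concentration(ds$data$measured_conc_start[rows][1],
                                 ds$data$measured_conc_end[rows][1]))
  expect_identical(tr$conc_source[i], "measured")

  ds2 <- ds
  ds2$data$measured_conc_start <- NULL
  ds2$data$measured_conc_end <- NULL
  tbl2 <- endpoint_table(ds2)
  tr2 <- tbl2$treatments
  expect_identical(unique(tr2$conc_source[tr2$role == "test"]),
                   "nominal_fallback")
  expect_equal(tr2$twa_conc[tr2$role == "test"],
               tr2$nominal_conc[tr2$role == "test"])
})

test_that("below-LOQ measurements are substituted at half the LOQ", {
  ds <- make_assay(seed = 23)
  low <- ds$data$treatment == "T1"
  ds$data$measured_conc_start[low] <- 0.04
  ds$data$measured_conc_end[low] <- 0.01
  tbl <- endpoint_table(ds, loq = 0.05)
  tr <- tbl$treatments
  expect_equal(tr$twa_conc[tr$treatment == "T1"],
               twa_concentration(0.025, 0.025))
})

test_that("control means agree with realistic control magnitudes", {
  ds <- make_assay(seed = 24)
  tbl <- endpoint_table(ds)
  expect_gt(tbl$control_mean_sgr, 1.41)
  expect_lt(tbl$control_mean_sgr, 1.68)
  expect_gt(tbl$control_mean_yield, 0.40)
  expect_lt(tbl$control_mean_yield, 0.50)
})
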