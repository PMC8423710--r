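test_that("exclusion filters catch the three screening patterns exactly", {
  vals <- rbind(
    c(20, 15, 11, 9, 8, 7, 6),     # declining from a high baseline
    c(5, 7, 9, 8, 7, 6, 5),        # ordinary responder
    c(0, 0, 0, 0, 0, 0, 0),        # all-zero series
    c(6, 6, 7, 8, 7, 6, 6)         # ordinary
  )
  panel <- toy_panel(vals)
  res <- apply_exclusions(panel, "cortisol")
  expect_setequal(
    paste(res$report$participant_id, res$report$rule),
    c("P1 prior_responder", "P3 all_zero", "P3 prior_responder")
  )
  kept <- unique(res$panel$participant_id)
  expect_setequal(kept, c("P2", "P4"))
  # retained participants' rows are untouched
  expect_identical(res$panel[res$panel$participant_id == "P2", ],
                   panel[panel$participant_id == "P2", ])
})

test_that("3-SD rule excludes exactly the constructed outlier, idempotently", {
  set.seed(42)
  n <- 20
  base <- matrix(rnorm(n * 7, mean = 10, sd = 1), n, 7)
  base <- base - rowMeans(base) + rnorm(n, 10, 1)   # person means ~ N(10, 1)
  vals <- rbind(base, matrix(50 + rnorm(7, sd = 0.1), 1, 7))
  # make sure no series is monotinically declining by accident
  vals[, 2] <- vals[, 1] + abs(vals[, 2] - vals[, 1])
  panel <- toy_panel(vals)
  pm <- rowMeans(vals)
  expect_true(pm[21] > mean(pm) + 3 * sd(pm))   # direct computation
  res <- apply_exclusions(panel, "cortisol", rules = "outlier_3sd")
  expect_identical(res$report$participant_id, "P21")
  res2 <- apply_exclusions(res$panel, "cortisol", rules = "outlier_3sd")
  expect_identical(res2$panel, res$panel)
  expect_identical(nrow(res2$report), 0L)
})

test_that("exclusions validate their inputs", {
  panel <- toy_panel(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_error(apply_exclusions(panel, "amylase"), "not present")
  expect_error(apply_exclusions(panel[0, ], "cortisol"), "no rows")
})

test_that("AUC-I matches hand-computed examples and its sign contract", {
  expect_identical(auc_increase(c(5, 5, 5, 5), c(0, 7, 19, 30)), 0)
  expect_equal(auc_increase(c(2, 4, 6), c(0, 10, 20)), 40)
  expect_equal(auc_increase(c(10, 6, 2), c(0, 10, 20)), -80)
  expect_error(auc_increase(c(1, 2), c(0, 10, 20)), "lengths differ")
  expect_error(auc_increase(c(1, 2, 3), c(0, 10, 10)), "strictly increasing")
  expect_error(auc_increase(5, 0), "at least two")
})

test_that("AUC-I is shift-invariant and agrees with an integration oracle", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (i in 1:200) {
    m <- sample(3:9, 1)
    v <- rnorm(m, 10, 4)
    tm <- cumsum(runif(m, 5, 15))
    a <- auc_increase(v, tm)
    expect_equal(auc_increase(v + 3.7, tm), a, tolerance = 1e-9)
    # oracle: numerical integral of the baseline-anchored series
    expect_equal(a, pracma::trapz(tm, v - v[1]), tolerance = 1e-9)
  }
})

test_that("covariate screening selects true correlates and is calibrated", {
  sim <- simulate_panel(sim_config(n_groups = 30), seed = 9)
  pm <- tapply(sim$panel$value[sim$panel$analyte == "cortisol"],
               sim$panel$participant_id[sim$panel$analyte == "cortisol"],
               mean)
  ros <- sim$roster
  ros$self <- as.numeric(pm[ros$participant_id])
  scr <- screen_covariates(sim$panel, ros, "cortisol",
                           c("self", "time_of_day"))
  expect_equal(scr$estimate[scr$covariate == "self"], 1, tolerance = 1e-12)
  expect_true(scr$selected[scr$covariate == "self"])

  ros$flat <- 1
  expect_warning(
    scr2 <- screen_covariates(sim$panel, ros, "cortisol", "flat"),
    "zero variance")
  expect_false(scr2$selected)

  expect_error(screen_covariates(sim$panel, ros, "cortisol", "nope"),
               "absent from roster")

  # type-I rate of the null screen (pure correlation test, fast)
  set.seed(31)
  alpha <- 0.05
  hits <- replicate(1000, {
    outcome <- rnorm(200)
    cov <- rnorm(200)
    cor.test(cov, outcome)$p.value < alpha
  })
  expect_lt(abs(mean(hits) - alpha), 0.015)
})

test_that("a negative BMI effect on amylase is screened in at the oracle power", {
  cfg <- sim_config(n_groups = 44, analytes = list(
    amylase = channel_config(baseline_mean = 80, baseline_sd = 9,
                             t0 = 15, amplitude = 60, theta = 8, delta = -0.1,
                             rho = 0.4, gamma = 0.3, gamma_mod = 0.01,
                             eta = 5, sigma_e = 15,
                             covariate_effects = c(bmi = -1.5),
                             clamp = c(0, Inf))))
  set.seed(17)
  reps <- replicate(60, {
    sim <- simulate_panel(cfg, seed = sample.int(1e6, 1))
    scr <- screen_covariates(sim$panel, sim$roster, "amylase", "bmi")
    n <- length(unique(sim$roster$participant_id))
    c(pick = scr$selected && scr$estimate < 0, r = scr$estimate, n = n)
  })
  rate <- mean(reps["pick", ])
  # oracle: power of the Pearson test at the generator-implied correlation
  # (Fisher z approximation at the realised r and sample size)
  r_true <- mean(reps["r", ])
  n_bar <- mean(reps["n", ])
  power <- stats::pnorm(abs(atanh(r_true)) * sqrt(n_bar - 3) -
                          qnorm(0.975))
  expect_lt(abs(rate - power), 0.12)   # binomial error at 60 replicates
  expect_gt(rate, 0.5)                 # far above the 5% null rate
  expect_lt(r_true, 0)                 # direction: higher BMI, lower amylase
})

test_that("roster descriptives reproduce counts and ratios", {
  r <- study_roster()
  s <- summarize_roster(r)
  expect_identical(s$n_participants, 138L)
  expect_identical(s$n_groups, 44L)
  expect_equal(round(s$mean_group_size, 2), 3.14)
  expect_equal(round(s$pct_female, 1), 47.1)
  expect_equal(round(unname(s$pct_per_condition[["1"]]), 1), 54.3)

  small <- tibble::tibble(participant_id = c("A", "B"), group_id = "G",
                          condition = c(0L, 0L))
  expect_equal(summarize_roster(small)$mean_group_size, 2)
  expect_error(summarize_roster(small[0, ]), "empty")
})
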