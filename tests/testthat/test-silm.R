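make_dyads <- function(n_groups = 10, seed = 1, ...) {
  sim <- simulate_panel(flat_study(n_groups = n_groups, ...), seed = seed)
  build_dyad_table(sim$panel, "cortisol", k = 1, roster = sim$roster)
}

test_that("design construction: intercept, raw powers, Table-style width", {
  dy <- make_dyads(4)
  des0 <- build_design(dy, silm_spec(fixed = character(0), random = NULL))
  expect_identical(ncol(des0$X), 1L)
  expect_true(all(des0$X[, 1] == 1))

  des <- build_design(dy, silm_spec(fixed = c("minute", "minute2", "minute3"),
                                    random = NULL))
  expect_identical(unname(des$X[, "minute2"]), dy$time_minutes^2)
  expect_identical(unname(des$X[, "minute3"]), dy$time_minutes^3)

  full <- silm_spec(fixed = silm_terms_full("time_of_day"),
                    random = c("intercept", "minute", "minute2", "minute3"))
  desf <- build_design(dy, full)
  expect_identical(ncol(desf$X), 31L)   # intercept + 30 predictors

  # aliased columns are named in the rank error
  dy$dup <- dy$time_minutes
  expect_error(build_design(dy, silm_spec(fixed = c("minute", "dup"),
                                          random = NULL)),
               "aliased.*dup")
  expect_error(build_design(dy, silm_spec(fixed = "nope", random = NULL)),
               "unknown model variable")
  expect_error(silm_spec(random = "minute"), "random intercept")
})

test_that("balanced random-intercept fit returns the grand mean", {
  set.seed(5)
  d <- data.frame(receiver_id = rep(sprintf("P%02d", 1:12), each = 5))
  d$y <- rep(rnorm(12, 0, 2), each = 5) + rnorm(60)
  f <- fit_lmm(d, silm_spec(fixed = character(0), random = "intercept"))
  expect_equal(f$coefficients$estimate[1], mean(d$y), tolerance = 1e-8)
  expect_identical(f$n_participants, 12L)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(42)
  n <- 20; m <- 7
  d <- data.frame(receiver_id = rep(sprintf("P%02d", 1:n), each = m),
                  minute = rep((0:(m - 1)) * 13, n),
                  x = rnorm(n * m))
  d$y <- 2 + 0.03 * d$minute + 0.5 * d$x +
    rep(rnorm(n, 0, 1.5), each = m) + rnorm(n * m)
  f <- fit_lmm(d, silm_spec(fixed = c("minute", "x"), random = "intercept"),
               estimation = "REML")
  ref <- lme4::lmer(y ~ minute + x + (1 | receiver_id), data = d, REML = TRUE)
  expect_equal(unname(f$coefficients$estimate), unname(lme4::fixef(ref)),
               tolerance = 1e-4)
  expect_equal(sqrt(f$varcomp$psi[1, 1]),
               unname(attr(lme4::VarCorr(ref)$receiver_id, "stddev")),
               tolerance = 1e-4)
  expect_equal(f$varcomp$sigma_e, stats::sigma(ref), tolerance = 1e-4)
})

test_that("optimised likelihood dominates the likelihood at the truth", {
  set.seed(11)
  n <- 40; m <- 7
  sig_b <- 1.5; sig_e <- 1; mu <- 3
  b <- rnorm(n, 0, sig_b)
  d <- data.frame(receiver_id = rep(seq_len(n), each = m))
  d$y <- mu + rep(b, each = m) + rnorm(n * m, 0, sig_e)
  f <- fit_lmm(d, silm_spec(fixed = character(0), random = "intercept"),
               estimation = "ML")
  # closed-form Gaussian log-likelihood at the generating parameters
  loglik_truth <- sum(vapply(split(d$y, d$receiver_id), function(yi) {
    V <- sig_b^2 * matrix(1, m, m) + sig_e^2 * diag(m)
    -0.5 * (m * log(2 * pi) + determinant(V)$modulus +
              drop(t(yi - mu) %*% solve(V, yi - mu)))
  }, numeric(1)))
  expect_gte(f$logLik, loglik_truth - 1e-6)
})

test_that("ICC is recovered from intercept-only variance components", {
  set.seed(23)
  n <- 200
  d <- data.frame(receiver_id = rep(seq_len(n), each = 7))
  d$y <- rep(rnorm(n, 0, sqrt(3)), each = 7) + rnorm(n * 7)
  f <- fit_lmm(d, silm_spec(fixed = character(0), random = "intercept"))
  expect_equal(f$icc, 0.75, tolerance = 0.1)
  expect_equal(f$icc,
               f$varcomp$psi[1, 1] / (f$varcomp$psi[1, 1] +
                                        f$varcomp$sigma_e^2),
               tolerance = 1e-12)
})

test_that("model comparison follows the joint LRT + AIC rule", {
  dy <- make_dyads(8, seed = 2, gamma = 0.5)
  base <- silm_spec(fixed = c("minute", "receiver_lagged"),
                    random = "intercept", estimation = "ML")
  f0 <- fit_lmm(dy, base)
  cmp0 <- compare_fits(f0, f0)
  expect_equal(cmp0$lrt, 0)
  expect_identical(cmp0$decision, "keep_simpler")

  richer <- base
  richer$fixed <- c(base$fixed, "sender", "sender_lagged")
  f1 <- fit_lmm(dy, richer)
  cmp <- compare_fits(f0, f1)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$lrt, 2 * (f1$logLik - f0$logLik))
  expect_equal(cmp$delta_aic, f1$AIC - f0$AIC)
  expect_identical(cmp$decision,
                   if (cmp$p < 0.05 && cmp$delta_aic < 0) "adopt_complex"
                   else "keep_simpler")

  other <- silm_spec(fixed = c("minute", "sender"), random = "intercept",
                     estimation = "ML")
  f2 <- fit_lmm(dy, other)
  expect_error(compare_fits(f1, f2), "not nested")
})

test_that("sequential F tests use containment df and square the Wald t", {
  # 132 participants; condition and time_of_day are the two outer terms:
  # their denominator df must be 132 - 2 - 1 = 129
  sim <- simulate_panel(sim_config(n_groups = 44,
                                   group_size_weights = c(`2` = 0, `3` = 1,
                                                          `4` = 0)),
                        seed = 13)
  expect_identical(nrow(sim$roster), 132L)
  dy <- build_dyad_table(sim$panel, "cortisol", roster = sim$roster)
  f <- fit_lmm(dy, silm_spec(
    fixed = c("minute", "condition", "receiver_lagged", "sender_lagged",
              "time_of_day"),
    random = "intercept"))
  ft <- sequential_f_tests(f)
  expect_equal(ft$df_den[ft$term == "condition"], 129)
  expect_equal(ft$df_den[ft$term == "time_of_day"], 129)
  # inner terms: n_obs - n_participants - (number of inner terms beyond the
  # intercept), the two-level convention behind F(1, 1564)-style reporting
  inner_df <- f$n_obs - f$n_participants - 3
  expect_equal(unique(ft$df_den[ft$term %in% c("minute", "receiver_lagged",
                                               "sender_lagged")]),
               inner_df)

  # last-added term: sequential F equals its squared Wald t
  tt <- f$coefficients
  expect_equal(unname(ft$F[ft$term == "time_of_day"]),
               unname(tt$t[tt$term == "time_of_day"]^2), tolerance = 1e-6)
})

test_that("R2 components behave at their limits", {
  # near-deterministic polynomial data: conditional R2 -> 1
  set.seed(3)
  n <- 15; m <- 7
  d <- data.frame(receiver_id = rep(seq_len(n), each = m),
                  minute = rep((0:(m - 1)) * 13, n))
  d$y <- 2 + 0.5 * d$minute - 0.004 * d$minute^2 +
    rep(rnorm(n, 0, 1), each = m) + rnorm(n * m, 0, 1e-4)
  d$minute2 <- d$minute^2
  f <- fit_lmm(d, silm_spec(fixed = c("minute", "minute2"),
                            random = "intercept"))
  expect_gt(f$r2_conditional, 0.999)

  # no fixed effects, random intercept only: marginal R2 ~ 0
  d2 <- data.frame(receiver_id = rep(seq_len(40), each = 5))
  d2$y <- rep(rnorm(40, 0, 2), each = 5) + rnorm(200)
  f2 <- fit_lmm(d2, silm_spec(fixed = character(0), random = "intercept"))
  expect_lt(f2$r2_marginal, 0.02)
  expect_equal(f2$r2_conditional,
               1 - f2$varcomp$sigma_e^2 /
                 (f2$varcomp$psi[1, 1] + f2$varcomp$sigma_e^2 + 0),
               tolerance = 1e-10)
})

test_that("stepwise build adopts what the data support and replays its trail", {
  dy <- make_dyads(16, seed = 4, gamma = 0.5)
  st <- stepwise_build(dy, candidates = silm_candidates("core"))
  expect_true("intercept" %in% st$spec$random)
  expect_true(all(c("sender", "sender_lagged") %in% st$spec$fixed))
  expect_identical(st$fit$model$method, "REML")

  # replaying the adopted candidates from the base spec reproduces the spec
  adopted <- st$trail$candidate[st$trail$decision == "adopt_complex"]
  cands <- silm_candidates("core")
  spec <- silm_spec(fixed = c("minute", "minute2", "minute3"), random = NULL)
  for (cd in cands) {
    if (!cd$label %in% adopted) next
    if (cd$type == "random") {
      spec$random <- union(if (is.null(spec$random)) character(0)
                           else spec$random, cd$terms)
    } else {
      spec$fixed <- c(spec$fixed, cd$terms)
    }
  }
  expect_setequal(spec$fixed, st$spec$fixed)
  expect_setequal(spec$random, st$spec$random)

  # random slopes are skipped while no random intercept is adopted
  st2 <- stepwise_build(dy, candidates = list(
    list(label = "random linear slope", type = "random", terms = "minute")))
  expect_match(st2$trail$decision[1], "skipped")
})

test_that("stepwise recovers a random-intercept-only structure most of the time", {
  # pair groups and rho = 0: in triads every receiver row is duplicated
  # across senders and the duplicate correlation genuinely mimics
  # person-by-time random effects, so slope adoption there is not a false
  # positive; pairs carry each receiver once per occasion
  set.seed(19)
  cands <- silm_candidates("core")[1:2]   # intercept, then linear slope
  res <- replicate(25, {
    cfg <- sim_config(n_groups = 24,
                      group_size_weights = c(`2` = 1, `3` = 0, `4` = 0),
                      analytes = list(cortisol = flat_channel(rho = 0)))
    sim <- simulate_panel(cfg, seed = sample.int(1e6, 1))
    dy <- build_dyad_table(sim$panel, "cortisol", k = 1)
    st <- stepwise_build(dy, candidates = cands)
    c(int = st$trail$decision[1] == "adopt_complex",
      slope = st$trail$decision[2] == "adopt_complex")
  })
  expect_gt(mean(res["int", ]), 0.9)
  expect_lt(mean(res["slope", ]), 0.5)
})
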