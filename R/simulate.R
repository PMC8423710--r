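#' Configure one analyte channel of the synthetic generator
#'
#' Parameterises the generative model for a single analyte. The mean
#' trajectory is condition-specific: controls drift linearly
#' (`baseline + delta * t`), the stress arm shows a single-peaked pulse with
#' delayed onset (`baseline + A * u * exp(1 - u)`, `u = (t - t0) / theta`),
#' peaking at `t0 + theta` with height `A` above baseline. Around that
#' trajectory, person `i` carries a baseline offset `b_i ~ N(0, baseline_sd^2)`
#' plus additive covariate effects; dynamics act on the deviation
#' `d_{t,i} = y_{t,i} - mu(t) - offset_i`:
#' stability `rho * d_{t-1,i}`, within-group coupling
#' `(gamma + gamma_mod * d_{t-1,i}) * mean_{j != i}(d_{t-1,j})`, a shared
#' within-group shock `eta * g_{t}`, and residual noise `sigma_e * e_{t,i}`.
#'
#' @param baseline_mean Mean baseline level, in analyte units.
#' @param baseline_sd SD of the person-specific baseline offset (sigma_b).
#' @param t0 Pulse onset, minutes since the first sample (stress arm only).
#' @param amplitude Pulse peak height above baseline (A), analyte units.
#' @param theta Pulse shape/time-to-peak parameter, minutes; must be > 0.
#' @param delta Control-arm linear drift, analyte units per minute.
#' @param rho Lag-1 stability (autoregression on own deviation), |rho| < 1.
#' @param gamma Lag-1 coupling to the mean deviation of the other group
#'   members.
#' @param gamma_mod Moderation of the coupling by the receiver's own previous
#'   deviation, per analyte unit.
#' @param eta SD of the shared within-group concurrent shock, analyte units.
#' @param sigma_e Residual SD, analyte units.
#' @param amplitude_sd SD of person-level variation in pulse amplitude
#'   (0 disables; trajectory heterogeneity beyond the condition means).
#' @param covariate_effects Named numeric vector of additive slopes on
#'   person-level covariates (e.g. `c(time_of_day = -0.3)`); covariates are
#'   centred at their generator means so `baseline_mean` stays the mean.
#' @param clamp Optional length-2 numeric range to truncate generated values
#'   (e.g. `c(0, 10)` for a visual-analogue scale).
#'
#' @return A list of class `"channel_config"`.
#' @export
channel_config <- function(baseline_mean, baseline_sd,
                           t0 = 15, amplitude = 8, theta = 25, delta = -0.02,
                           rho = 0.5, gamma = 0.3, gamma_mod = 0,
                           eta = 0.5, sigma_e = 1.5,
                           amplitude_sd = 0,
                           covariate_effects = NULL,
                           clamp = NULL) {
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  if (baseline_sd < 0 || eta < 0 || sigma_e < 0 || amplitude_sd < 0) {
    stop("`baseline_sd`, `eta`, `sigma_e`, `amplitude_sd` must be >= 0",
         call. = FALSE)
  }
  if (!is.null(clamp) && (length(clamp) != 2L || clamp[1] >= clamp[2])) {
    stop("`clamp` must be an increasing length-2 range", call. = FALSE)
  }
  structure(list(
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    traj = list(baseline = baseline_mean, t0 = t0, A = amplitude,
                theta = theta, delta = delta),
    rho = rho, gamma = gamma, gamma_mod = gamma_mod,
    eta = eta, sigma_e = sigma_e, amplitude_sd = amplitude_sd,
    covariate_effects = covariate_effects, clamp = clamp
  ), class = "channel_config")
}

#' Configure the synthetic group-stress study
#'
#' Defaults emulate a group stress-induction study: 44 groups of 2--4
#' participants (mean size about 3.1), roughly half the groups assigned to
#' the stress arm, seven saliva samples per participant at 13-minute
#' intervals (the midpoint of a 12--15-minute sampling scheme), and three
#' analyte channels: cortisol (nmol/l, coupled), alpha-amylase (U/ml,
#' coupled with receiver-state moderation), and subjective stress (VAS 0-10,
#' uncoupled, reflecting absent emotional synchrony).
#'
#' @param n_groups Number of groups.
#' @param group_size_weights Named probabilities for group sizes 2, 3, 4.
#' @param p_stress Probability a group is assigned to the stress condition.
#' @param M Samples per participant (measurement occasions).
#' @param interval_minutes Minutes between consecutive samples.
#' @param analytes Named list of [channel_config()] objects.
#' @param covariate_means,covariate_sds Generator means/SDs for the numeric
#'   person covariates `time_of_day` (hours, shared within group, uniform
#'   9-17), `time_since_awakening` (hours) and `bmi` (kg/m2).
#' @param gender_probs Probabilities for `male`,
#'   `female_oc` (hormonal contraceptives), `female_noc`.
#' @param seed Default seed used by [simulate_panel()] when none is given.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_groups = 44,
                       group_size_weights = c(`2` = 0.20, `3` = 0.46, `4` = 0.34),
                       p_stress = 0.5,
                       M = 7,
                       interval_minutes = 13,
                       analytes = list(
                         cortisol = channel_config(
                           baseline_mean = 6, baseline_sd = 2.4,
                           t0 = 15, amplitude = 8, theta = 25, delta = -0.02,
                           rho = 0.5, gamma = 0.3, gamma_mod = 0,
                           eta = 0.5, sigma_e = 1.5,
                           covariate_effects = c(time_of_day = -0.8)),
                         amylase = channel_config(
                           baseline_mean = 80, baseline_sd = 9,
                           t0 = 15, amplitude = 60, theta = 8, delta = -0.1,
                           rho = 0.4, gamma = 0.3, gamma_mod = 0.01,
                           eta = 5, sigma_e = 15,
                           covariate_effects = c(bmi = -1.5),
                           clamp = c(0, Inf)),
                         subjective = channel_config(
                           baseline_mean = 2, baseline_sd = 1,
                           t0 = 15, amplitude = 4, theta = 15, delta = -0.01,
                           rho = 0.4, gamma = 0, gamma_mod = 0,
                           eta = 0, sigma_e = 0.8,
                           clamp = c(0, 10))
                       ),
                       covariate_means = c(time_of_day = 13,
                                           time_since_awakening = 4.5,
                                           bmi = 23.5),
                       covariate_sds = c(time_since_awakening = 1.5,
                                         bmi = 3),
                       gender_probs = c(male = 0.53, female_oc = 0.20,
                                        female_noc = 0.27),
                       seed = NULL) {
  stopifnot(n_groups >= 1, M >= 2, interval_minutes > 0)
  if (abs(sum(group_size_weights) - 1) > 1e-8) {
    stop("`group_size_weights` must sum to 1", call. = FALSE)
  }
  if (p_stress < 0 || p_stress > 1) stop("`p_stress` must be in [0, 1]",
                                         call. = FALSE)
  if (is.null(names(analytes)) || anyDuplicated(names(analytes))) {
    stop("`analytes` must be a uniquely named list", call. = FALSE)
  }
  for (ch in analytes) {
    if (!inherits(ch, "channel_config")) {
      stop("each analyte must be a channel_config()", call. = FALSE)
    }
  }
  structure(list(
    n_groups = n_groups, group_size_weights = group_size_weights,
    p_stress = p_stress, M = M, interval_minutes = interval_minutes,
    analytes = analytes, covariate_means = covariate_means,
    covariate_sds = covariate_sds, gender_probs = gender_probs,
    seed = seed
  ), class = "sim_config")
}

#' Condition-specific mean trajectory
#'
#' Control arm (`condition = 0`): linear drift `baseline + delta * t`.
#' Stress arm (`condition = 1`): flat at baseline until onset `t0`, then a
#' single-peaked pulse `baseline + A * u * exp(1 - u)` with
#' `u = (t - t0) / theta`, maximal (`baseline + A`) at `t = t0 + theta` and
#' returning toward baseline afterwards.
#'
#' @param t_minutes Non-negative time(s) since the first sample, minutes.
#' @param condition 0 (control) or 1 (stress).
#' @param traj List with `baseline`, `t0`, `A`, `theta` (> 0), `delta`.
#' @return Numeric vector of mean analyte values, same length as `t_minutes`.
#' @examples
#' tr <- list(baseline = 6, t0 = 15, A = 8, theta = 25, delta = -0.02)
#' mean_response(0, 1, tr)            # baseline: pulse not yet begun
#' mean_response(15 + 25, 1, tr)      # baseline + A: pulse maximum
#' @export
mean_response <- function(t_minutes, condition, traj) {
  if (any(t_minutes < 0)) stop("`t_minutes` must be >= 0", call. = FALSE)
  if (!condition %in% c(0, 1)) stop("`condition` must be 0 or 1", call. = FALSE)
  if (is.null(traj$theta) || traj$theta <= 0) {
    stop("`traj$theta` must be > 0", call. = FALSE)
  }
  if (condition == 0) {
    traj$baseline + traj$delta * t_minutes
  } else {
    u <- pmax(t_minutes - traj$t0, 0) / traj$theta
    traj$baseline + traj$A * u * exp(1 - u)
  }
}

# Sample the group/participant structure (roster) for one study.
sample_roster <- function(config) {
  sizes <- as.integer(names(config$group_size_weights))
  g_size <- sample(sizes, config$n_groups, replace = TRUE,
                   prob = config$group_size_weights)
  g_cond <- rbinom(config$n_groups, 1, config$p_stress)
  g_tod <- runif(config$n_groups, 9, 17)
  n <- sum(g_size)
  group_id <- rep(sprintf("G%02d", seq_len(config$n_groups)), g_size)
  participant_id <- sprintf("P%03d", seq_len(n))
  gender_oc <- sample(names(config$gender_probs), n, replace = TRUE,
                      prob = config$gender_probs)
  tsa <- pmax(rnorm(n, config$covariate_means[["time_since_awakening"]],
                    config$covariate_sds[["time_since_awakening"]]), 0.5)
  bmi <- rnorm(n, config$covariate_means[["bmi"]], config$covariate_sds[["bmi"]])
  tibble::tibble(
    participant_id = participant_id,
    group_id = group_id,
    condition = rep(g_cond, g_size),
    gender_oc = gender_oc,
    time_of_day = rep(g_tod, g_size),
    time_since_awakening = tsa,
    bmi = bmi,
    group_size = rep(g_size, g_size)
  )
}

# Additive covariate contribution for one channel, centred at generator means.
covariate_offset <- function(channel, roster, covariate_means) {
  off <- numeric(nrow(roster))
  eff <- channel$covariate_effects
  if (is.null(eff)) return(off)
  for (nm in names(eff)) {
    x <- roster[[nm]]
    if (is.null(x)) stop("unknown covariate in covariate_effects: ", nm,
                         call. = FALSE)
    ctr <- if (nm %in% names(covariate_means)) covariate_means[[nm]] else mean(x)
    off <- off + eff[[nm]] * (x - ctr)
  }
  off
}

#' Simulate a group-structured endocrine panel with known ground truth
#'
#' Generates, for every analyte channel in `config`, a long-format panel of
#' `M` measurements per participant following the generative model described
#' in [channel_config()]. Identical `config` and `seed` give identical
#' output. Groups of size 1 are permitted but flagged with a warning, since
#' they yield no dyads downstream.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; falls back to `config$seed`.
#' @return A list of class `"sync_sim"` with elements
#'   \describe{
#'     \item{panel}{tibble with columns `participant_id, group_id, condition,
#'       t, time_minutes, analyte, value`.}
#'     \item{roster}{one row per participant with condition and covariates.}
#'     \item{truth}{the realised ground truth: the config, per-participant
#'       baseline offsets and amplitudes, per-group shock draws, and
#'       covariate offsets, per analyte.}
#'   }
#' @export
simulate_panel <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  roster <- sample_roster(config)
  n <- nrow(roster)
  M <- config$M
  times <- (seq_len(M) - 1) * config$interval_minutes
  if (any(roster$group_size == 1L)) {
    warning("groups of size 1 present: they yield no dyads downstream",
            call. = FALSE)
  }
  group_index <- match(roster$group_id, unique(roster$group_id))
  n_grp <- max(group_index)

  panels <- vector("list", length(config$analytes))
  truth_ch <- vector("list", length(config$analytes))
  names(truth_ch) <- names(config$analytes)

  for (a in seq_along(config$analytes)) {
    ch <- config$analytes[[a]]
    b <- rnorm(n, 0, ch$baseline_sd)
    amp <- ch$traj$A + if (ch$amplitude_sd > 0) rnorm(n, 0, ch$amplitude_sd) else 0
    g_shock <- matrix(rnorm(n_grp * M), n_grp, M)
    e <- matrix(rnorm(n * M), n, M)
    cov_off <- covariate_offset(ch, roster, config$covariate_means)
    offset <- b + cov_off

    # person x time mean trajectories (amplitude may vary by person)
    mu <- matrix(0, n, M)
    for (i in seq_len(n)) {
      tr <- ch$traj
      tr$A <- if (length(amp) > 1) amp[i] else amp
      mu[i, ] <- mean_response(times, roster$condition[i], tr)
    }

    y <- matrix(0, n, M)
    d <- matrix(0, n, M)
    y[, 1] <- mu[, 1] + offset + ch$sigma_e * e[, 1]
    if (!is.null(ch$clamp)) y[, 1] <- pmin(pmax(y[, 1], ch$clamp[1]), ch$clamp[2])
    d[, 1] <- y[, 1] - mu[, 1] - offset
    for (t in 2:M) {
      d_prev <- d[, t - 1L]
      grp_sum <- tapply(d_prev, group_index, sum)[group_index]
      grp_n <- roster$group_size
      mean_others <- ifelse(grp_n > 1L, (grp_sum - d_prev) / (grp_n - 1L), 0)
      y[, t] <- mu[, t] + offset +
        ch$rho * d_prev +
        (ch$gamma + ch$gamma_mod * d_prev) * mean_others +
        ch$eta * g_shock[cbind(group_index, t)] +
        ch$sigma_e * e[, t]
      if (!is.null(ch$clamp)) y[, t] <- pmin(pmax(y[, t], ch$clamp[1]), ch$clamp[2])
      d[, t] <- y[, t] - mu[, t] - offset
    }

    panels[[a]] <- tibble::tibble(
      participant_id = rep(roster$participant_id, each = M),
      group_id = rep(roster$group_id, each = M),
      condition = rep(roster$condition, each = M),
      t = rep.int(0:(M - 1L), n),
      time_minutes = rep.int(times, n),
      analyte = names(config$analytes)[a],
      value = as.vector(t(y))
    )
    truth_ch[[a]] <- list(
      baseline_offsets = setNames(b, roster$participant_id),
      amplitudes = setNames(rep(amp, length.out = n), roster$participant_id),
      covariate_offsets = setNames(cov_off, roster$participant_id),
      group_shocks = g_shock
    )
  }

  structure(list(
    panel = do.call(rbind, panels),
    roster = roster,
    truth = list(config = config, seed = seed, channels = truth_ch)
  ), class = "sync_sim")
}

#' @export
print.sync_sim <- function(x, ...) {
  cat("Synthetic group endocrine study\n")
  cat(sprintf("  %d participants in %d groups; %d samples each\n",
              nrow(x$roster), length(unique(x$roster$group_id)),
              x$truth$config$M))
  cat(sprintf("  analytes: %s\n", paste(unique(x$panel$analyte),
                                        collapse = ", ")))
  invisible(x)
}
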