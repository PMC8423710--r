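# Shared fixtures: trajectory-free channels for calibration studies, and a
# roster matching the published sample composition.

flat_channel <- function(baseline_mean = 6, baseline_sd = 2.4, rho = 0.5,
                         gamma = 0, gamma_mod = 0, eta = 0, sigma_e = 1.5) {
  channel_config(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 amplitude = 0, delta = 0, rho = rho, gamma = gamma,
                 gamma_mod = gamma_mod, eta = eta, sigma_e = sigma_e)
}

# 48 groups of 3, one cortisol-like channel with no mean trajectory.
flat_study <- function(n_groups = 48, ...) {
  sim_config(n_groups = n_groups,
             group_size_weights = c(`2` = 0, `3` = 1, `4` = 0),
             p_stress = 0.5,
             analytes = list(cortisol = flat_channel(...)))
}

# Roster reproducing the published counts: 138 participants (65 female) in
# 44 groups of sizes 2-4, 75 participants in the stress arm.
study_roster <- function() {
  sizes <- c(rep(2L, 6), rep(3L, 26), rep(4L, 12))   # sums to 138
  stopifnot(sum(sizes) == 138L)
  cond <- integer(44)
  cond[7:31] <- 1L                                    # 25 triads -> 75 stressed
  n <- sum(sizes)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    group_id = rep(sprintf("G%02d", seq_len(44)), sizes),
    condition = rep(cond, sizes),
    gender_oc = c(rep("female_noc", 65), rep("male", n - 65))
  )
}

# Minimal hand-built panel: one group, arbitrary value matrix (rows =
# participants, cols = occasions).
toy_panel <- function(values, ids = sprintf("P%d", seq_len(nrow(values))),
                      group = "G1", condition = 1L, interval = 10) {
  M <- ncol(values)
  tibble::tibble(
    participant_id = rep(ids, each = M),
    group_id = group,
    condition = condition,
    t = rep.int(0:(M - 1L), nrow(values)),
    time_minutes = rep.int((0:(M - 1L)) * interval, nrow(values)),
    analyte = "cortisol",
    value = as.vector(t(values))
  )
}

# Independent double-loop CCF oracle (defining sum, n-denominator).
ccf_oracle <- function(x, y, k) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  s <- 0
  for (t in seq_len(n)) {
    if (t + k >= 1 && t + k <= n) s <- s + xc[t] * yc[t + k]
  }
  (s / n) / (sqrt(mean(xc^2)) * sqrt(mean(yc^2)))
}
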