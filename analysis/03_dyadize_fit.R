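#!/usr/bin/env Rscript
# Stage 3: dyad expansion and the stability-and-influence model.
#
# Each filtered panel is expanded into all ordered within-group
# sender-receiver dyads with lag-1 predictors (grand-mean centred), and the
# multilevel growth-curve model is built stepwise: random intercept, random
# time slope, condition and its trajectory interactions, stability
# (receiver's lagged value), sender influence (concurrent + lagged), then
# screened covariates. Adoption requires both a significant likelihood-ratio
# test and an AIC improvement.

library(groupsync)

roster <- tibble::as_tibble(utils::read.csv("results/roster.csv"))

for (analyte in c("cortisol", "amylase", "subjective")) {
  panel <- read_panel(sprintf("results/panel_%s_filtered.csv", analyte))
  ros <- roster[roster$participant_id %in% panel$participant_id, ]
  scr <- utils::read.csv(sprintf("results/covariates_%s.csv", analyte))

  dyads <- build_dyad_table(panel, analyte, k = 1, centering = "grand",
                            roster = ros)
  cands <- silm_candidates("core",
                           covariates = intersect(scr$covariate[scr$selected],
                                                  names(dyads)))
  st <- stepwise_build(dyads, candidates = cands)
  message(sprintf("== %s ==", analyte))
  print(as.data.frame(st$trail), digits = 3)
  print(st$fit)

  utils::write.csv(st$trail, sprintf("results/trail_%s.csv", analyte),
                   row.names = FALSE)
  utils::write.csv(st$fit$coefficients,
                   sprintf("results/coefficients_%s.csv", analyte),
                   row.names = FALSE)
  utils::write.csv(sequential_f_tests(st$fit),
                   sprintf("results/f_tests_%s.csv", analyte),
                   row.names = FALSE)
  jsonlite::write_json(
    list(analyte = analyte,
         n_obs = st$fit$n_obs, n_participants = st$fit$n_participants,
         icc_final = st$fit$icc,
         r2_marginal = st$fit$r2_marginal,
         r2_conditional = st$fit$r2_conditional,
         logLik = st$fit$logLik, AIC = st$fit$AIC, BIC = st$fit$BIC,
         fixed = st$spec$fixed, random = st$spec$random),
    sprintf("results/fit_%s.json", analyte), auto_unbox = TRUE, digits = NA)
}
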