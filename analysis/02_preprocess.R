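#!/usr/bin/env Rscript
# Stage 2: exclusion filters, AUC-I summaries, covariate screening.
#
# Participants are screened per analyte: prior responders (high baseline,
# only declining levels), series more than 3 SD above the mean throughout,
# and all-zero series (an amylase assay artifact). For each retained
# participant the baseline-anchored area under the curve (AUC-I) summarises
# the overall response; candidate covariates are kept when they correlate
# with the person-mean outcome.

library(groupsync)

panel <- read_panel("results/panel.csv")
roster <- tibble::as_tibble(utils::read.csv("results/roster.csv"))
covariates <- c("time_of_day", "gender_oc", "time_since_awakening", "bmi",
                "group_size")

for (analyte in unique(panel$analyte)) {
  excl <- apply_exclusions(panel, analyte)
  message(sprintf("[%s] excluded %d participant(s): %s", analyte,
                  length(unique(excl$report$participant_id)),
                  paste(sprintf("%s (%s)", excl$report$participant_id,
                                excl$report$rule), collapse = ", ")))
  utils::write.csv(excl$report,
                   sprintf("results/exclusions_%s.csv", analyte),
                   row.names = FALSE)

  auc <- auc_increase_panel(excl$panel, analyte)
  utils::write.csv(auc, sprintf("results/auc_%s.csv", analyte),
                   row.names = FALSE)
  message(sprintf("[%s] mean AUC-I stress %.1f vs control %.1f", analyte,
                  mean(auc$auc_i[auc$condition == 1]),
                  mean(auc$auc_i[auc$condition == 0])))

  ros <- roster[roster$participant_id %in% excl$panel$participant_id, ]
  scr <- screen_covariates(excl$panel, ros, analyte, covariates)
  utils::write.csv(scr, sprintf("results/covariates_%s.csv", analyte),
                   row.names = FALSE)
  message(sprintf("[%s] selected covariates: %s", analyte,
                  paste(scr$covariate[scr$selected], collapse = ", ")))
  write_panel(excl$panel[excl$panel$analyte == analyte, ],
              sprintf("results/panel_%s_filtered.csv", analyte))
}
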