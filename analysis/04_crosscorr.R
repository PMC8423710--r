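#!/usr/bin/env Rscript
# Stage 4: pairwise cross-correlation functions.
#
# For every unordered within-group pair, the CCF across lags is compared
# with the conventional significance limit (CCSL = 1.96/sqrt(M)); pairs are
# counted as synchronous (positive) or anti-phase (negative) when any lag
# exceeds the limit.

library(groupsync)

for (analyte in c("cortisol", "amylase", "subjective")) {
  panel <- read_panel(sprintf("results/panel_%s_filtered.csv", analyte))
  cc <- pairwise_ccf(panel, analyte, alpha = 0.05)
  counts <- ccf_counts(cc)
  message(sprintf(
    "[%s] CCSL %.3f | %d pairs: %d positive, %d negative (lag-0 significant: %d)",
    analyte, attr(cc, "ccsl"), counts$pairs[["n_pairs"]],
    counts$pairs[["n_positive_pairs"]], counts$pairs[["n_negative_pairs"]],
    counts$per_lag$n_sig_positive[1] + counts$per_lag$n_sig_negative[1]))
  utils::write.csv(cc, sprintf("results/ccf_%s.csv", analyte),
                   row.names = FALSE)
  utils::write.csv(counts$per_lag,
                   sprintf("results/ccf_counts_%s.csv", analyte),
                   row.names = FALSE)
}
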