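#' Apply participant exclusion filters to a measurement panel
#'
#' Implements the screening rules used before synchrony analysis of salivary
#' stress markers:
#' \describe{
#'   \item{prior_responder}{the first sample is the series maximum and the
#'     series never increases afterwards -- a high baseline with subsequently
#'     only declining levels, suggesting a stress response that began before
#'     the experiment. Non-strict monotonicity tolerates plateaus.}
#'   \item{outlier_3sd}{the participant's mean level across the series
#'     exceeds the grand mean of person-means by more than three standard
#'     deviations of the person-means (very high levels throughout).}
#'   \item{all_zero}{every measurement is exactly zero (seen with
#'     alpha-amylase assays).}
#' }
#' All rules are evaluated on the input panel, so a second application to the
#' filtered panel is a no-op on typical data.
#'
#' @param panel A measurement panel (long format, see [simulate_panel()]).
#' @param analyte Which analyte to screen.
#' @param rules Character subset of
#'   `c("prior_responder", "outlier_3sd", "all_zero")`.
#' @return A list with `panel` (rows of every analyte for the retained
#'   participants) and `report`, a tibble of `(participant_id, rule)` plus a
#'   `counts` attribute (per-rule totals).
#' @export
apply_exclusions <- function(panel, analyte,
                             rules = c("prior_responder", "outlier_3sd",
                                       "all_zero")) {
  validate_panel(panel)
  rules <- match.arg(rules, several.ok = TRUE)
  sub <- panel[panel$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("analyte not present in panel: ", analyte,
                            call. = FALSE)
  sub <- sub[order(sub$participant_id, sub$t), ]
  series <- split(sub$value, sub$participant_id)

  hits <- list()
  if ("prior_responder" %in% rules) {
    flag <- vapply(series, function(v) {
      v[1] == max(v) && all(diff(v) <= 0)
    }, logical(1))
    hits$prior_responder <- names(series)[flag]
  }
  if ("outlier_3sd" %in% rules) {
    pm <- vapply(series, mean, numeric(1))
    if (length(pm) >= 2L) {
      flag <- pm > mean(pm) + 3 * sd(pm)
      hits$outlier_3sd <- names(series)[flag]
    } else {
      hits$outlier_3sd <- character(0)
    }
  }
  if ("all_zero" %in% rules) {
    flag <- vapply(series, function(v) all(v == 0), logical(1))
    hits$all_zero <- names(series)[flag]
  }

  report <- tibble::tibble(
    participant_id = unlist(hits, use.names = FALSE),
    rule = rep(names(hits), lengths(hits))
  )
  excluded <- unique(report$participant_id)
  attr(report, "counts") <- vapply(hits, length, integer(1))
  list(
    panel = panel[!panel$participant_id %in% excluded, , drop = FALSE],
    report = report
  )
}

#' Screen candidate covariates against person-mean analyte levels
#'
#' A covariate is selected for inclusion in the synchrony model when it is
#' significantly correlated with the dependent variable. Correlations are
#' computed against person-mean analyte values (one row per participant, to
#' avoid pseudo-replication of the repeated measures); categorical
#' covariates are dummy-expanded and each dummy screened separately.
#'
#' @param panel Measurement panel.
#' @param roster Participant roster carrying the covariates.
#' @param analyte Analyte defining the dependent variable.
#' @param covariates Character vector of roster column names.
#' @param alpha Two-sided significance level for selection.
#' @return A tibble of class `"covariate_screen"` with columns
#'   `covariate, estimate, p_value, selected`.
#' @export
screen_covariates <- function(panel, roster, analyte, covariates,
                              alpha = 0.05) {
  validate_panel(panel)
  sub <- panel[panel$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("analyte not present in panel: ", analyte,
                            call. = FALSE)
  missing_cov <- setdiff(covariates, names(roster))
  if (length(missing_cov)) {
    stop("covariates absent from roster: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  pm <- tapply(sub$value, sub$participant_id, mean)
  ros <- roster[match(names(pm), roster$participant_id), , drop = FALSE]

  cols <- list()
  for (cv in covariates) {
    x <- ros[[cv]]
    if (is.character(x) || is.factor(x)) {
      mm <- model.matrix(~ x)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, "_", sub("^x", "", colnames(mm)))
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    } else {
      cols[[cv]] <- as.numeric(x)
    }
  }

  out <- lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    if (sd(x) == 0 || anyNA(x)) {
      warning("covariate has zero variance or missing values, not selected: ",
              nm, call. = FALSE)
      return(tibble::tibble(covariate = nm, estimate = NA_real_,
                            p_value = NA_real_, selected = FALSE))
    }
    ct <- suppressWarnings(cor.test(x, as.numeric(pm)))
    tibble::tibble(covariate = nm, estimate = unname(ct$estimate),
                   p_value = ct$p.value,
                   selected = is.finite(ct$p.value) && ct$p.value < alpha)
  })
  res <- do.call(rbind, out)
  class(res) <- c("covariate_screen", class(res))
  attr(res, "alpha") <- alpha
  res
}

#' Area under the curve with respect to increase (AUC-I)
#'
#' Baseline-anchored trapezoidal summary of a repeatedly sampled analyte:
#' the trapezoidal area under the series minus the rectangle at the first
#' (baseline) measurement,
#' `sum((m_i + m_{i+1})/2 * (t_{i+1} - t_i)) - m_1 * (t_M - t_1)`.
#' Positive values indicate an overall increase from the starting point,
#' negative values an overall decrease; a constant series scores 0, and the
#' result is invariant to adding a constant to all values.
#'
#' @param values Analyte values, length >= 2.
#' @param times Sampling times in minutes, strictly increasing, same length.
#' @return Signed area in analyte-units x minutes.
#' @examples
#' auc_increase(c(2, 4, 6), c(0, 10, 20))   #  40
#' auc_increase(c(10, 6, 2), c(0, 10, 20))  # -80
#' @export
auc_increase <- function(values, times) {
  n <- length(values)
  if (n < 2L) stop("need at least two measurements", call. = FALSE)
  if (length(times) != n) stop("`values` and `times` lengths differ",
                               call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)
  dt <- diff(times)
  sum((values[-n] + values[-1]) / 2 * dt) - values[1] * (times[n] - times[1])
}

#' Per-participant AUC-I for one analyte of a panel
#'
#' @param panel Measurement panel.
#' @param analyte Analyte name.
#' @return Tibble `(participant_id, group_id, condition, auc_i)`.
#' @export
auc_increase_panel <- function(panel, analyte) {
  validate_panel(panel)
  sub <- panel[panel$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("analyte not present in panel: ", analyte,
                            call. = FALSE)
  sub <- sub[order(sub$participant_id, sub$t), ]
  ids <- unique(sub$participant_id)
  auc <- vapply(split(seq_len(nrow(sub)), sub$participant_id)[ids],
                function(idx) auc_increase(sub$value[idx],
                                           sub$time_minutes[idx]),
                numeric(1))
  first <- sub[!duplicated(sub$participant_id), ]
  tibble::tibble(participant_id = ids,
                 group_id = first$group_id[match(ids, first$participant_id)],
                 condition = first$condition[match(ids, first$participant_id)],
                 auc_i = unname(auc))
}

#' Descriptive summary of a participant roster
#'
#' @param roster One row per participant with at least `participant_id`,
#'   `group_id`, `condition`; optionally `gender_oc` (categories containing
#'   `"female"` count as female) and `age`.
#' @return A list of class `"roster_summary"`: `n_participants`, `n_groups`,
#'   `mean_group_size`, `pct_female`, `pct_per_condition` (named `%` per
#'   condition level), and `mean_age`/`sd_age` when age is present.
#'   Percentages are raw; the print method rounds to one decimal (group size
#'   to two) for reporting.
#' @export
summarize_roster <- function(roster) {
  if (nrow(roster) == 0L) stop("empty roster", call. = FALSE)
  n <- nrow(roster)
  n_groups <- length(unique(roster$group_id))
  out <- list(
    n_participants = n,
    n_groups = n_groups,
    mean_group_size = n / n_groups,
    pct_female = if (!is.null(roster[["gender_oc"]])) {
      100 * mean(grepl("female", roster[["gender_oc"]]))
    } else {
      NA_real_
    },
    pct_per_condition = 100 * prop.table(table(roster$condition))
  )
  if (!is.null(roster[["age"]])) {
    out$mean_age <- mean(roster[["age"]])
    out$sd_age <- sd(roster[["age"]])
  }
  structure(out, class = "roster_summary")
}

#' @export
print.roster_summary <- function(x, ...) {
  cat(sprintf("%d participants in %d groups (mean group size = %.2f)\n",
              x$n_participants, x$n_groups, x$mean_group_size))
  if (is.finite(x$pct_female)) {
    cat(sprintf("  %.1f%% female\n", x$pct_female))
  }
  pc <- x$pct_per_condition
  cat(sprintf("  condition split: %s\n",
              paste(sprintf("%s = %.1f%%", names(pc), pc), collapse = ", ")))
  if (!is.null(x$mean_age)) {
    cat(sprintf("  age %.2f +/- %.2f\n", x$mean_age, x$sd_age))
  }
  invisible(x)
}

# Shared panel validation; errors name the missing column.
validate_panel <- function(panel) {
  required <- c("participant_id", "group_id", "condition", "t",
                "time_minutes", "analyte", "value")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("panel is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("panel has no rows", call. = FALSE)
  invisible(panel)
}
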