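#' Read and validate a measurement panel from CSV
#'
#' Expects the columns
#' `participant_id, group_id, condition, t, time_minutes, analyte, value`;
#' a malformed header produces a validation error naming the missing
#' column(s).
#'
#' @param path CSV file path.
#' @return Tibble panel.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  panel <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_panel(panel)
  panel
}

#' Write a measurement panel to RFC-4180 CSV
#'
#' @param panel Panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Configure an end-to-end synchrony analysis run
#'
#' Exactly one of `sim` (a [sim_config()]) or `panel_path` (+ `roster_path`)
#' must be supplied.
#'
#' @param sim A [sim_config()] for synthetic input, or `NULL`.
#' @param panel_path,roster_path CSV paths for external input, or `NULL`.
#' @param analytes Analytes to analyse.
#' @param rules Exclusion rules passed to [apply_exclusions()].
#' @param covariates Candidate covariates for [screen_covariates()].
#' @param alpha Significance level (screening, stepwise adoption, CCSL).
#' @param lag Lag size k of the dyadic model.
#' @param candidate_set `"full"` or `"core"` stepwise candidate preset.
#' @param seed Integer seed recorded in all outputs.
#' @param verbose Emit stage-scoped progress messages to stderr.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), panel_path = NULL,
                       roster_path = NULL,
                       analytes = c("cortisol", "amylase", "subjective"),
                       rules = c("prior_responder", "outlier_3sd", "all_zero"),
                       covariates = c("time_of_day", "gender_oc",
                                      "time_since_awakening", "bmi",
                                      "group_size"),
                       alpha = 0.05, lag = 1,
                       candidate_set = c("core", "full"),
                       seed = 1, verbose = TRUE) {
  candidate_set <- match.arg(candidate_set)
  if (is.null(sim) == is.null(panel_path)) {
    stop("exactly one of `sim` or `panel_path` must be set", call. = FALSE)
  }
  structure(list(sim = sim, panel_path = panel_path,
                 roster_path = roster_path, analytes = analytes,
                 rules = rules, covariates = covariates, alpha = alpha,
                 lag = lag, candidate_set = candidate_set, seed = seed,
                 verbose = verbose),
            class = "run_config")
}

stage_msg <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full synchrony analysis pipeline
#'
#' simulate/load -> exclusions -> AUC-I -> covariate screening -> dyad
#' expansion -> stepwise stability-and-influence model -> cross-correlation
#' summary, per analyte. Re-running with an identical config (including
#' seed) reproduces identical numeric content.
#'
#' @param config A [run_config()].
#' @return A list of class `"run_report"` with `config`, `seed`, `roster`,
#'   `roster_summary`, and per-analyte entries carrying the exclusion
#'   report, AUC-I table, covariate screen, stepwise trail, final fit
#'   summary (coefficients, F table, ICC, R2), and CCF counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  if (!is.null(config$sim)) {
    stage_msg(v, "simulate", "generating synthetic study (seed ",
              config$seed, ")")
    sim <- simulate_panel(config$sim, seed = config$seed)
    panel <- sim$panel
    roster <- sim$roster
  } else {
    stage_msg(v, "load", "reading panel from ", config$panel_path)
    panel <- read_panel(config$panel_path)
    roster <- if (!is.null(config$roster_path)) {
      tibble::as_tibble(utils::read.csv(config$roster_path,
                                        stringsAsFactors = FALSE))
    } else {
      panel[!duplicated(panel$participant_id),
            c("participant_id", "group_id", "condition")]
    }
  }

  report <- list(config = config, seed = config$seed, roster = roster,
                 roster_summary = summarize_roster(roster),
                 analytes = list())

  for (analyte in config$analytes) {
    stage_msg(v, "preprocess", analyte, ": exclusion filters")
    excl <- apply_exclusions(panel, analyte, rules = config$rules)
    ros <- roster[roster$participant_id %in%
                    excl$panel$participant_id, , drop = FALSE]

    auc <- auc_increase_panel(excl$panel, analyte)

    covs <- intersect(config$covariates, names(ros))
    screen <- if (length(covs)) {
      screen_covariates(excl$panel, ros, analyte, covs, alpha = config$alpha)
    } else {
      NULL
    }
    selected <- if (!is.null(screen)) screen$covariate[screen$selected]
                else character(0)
    stage_msg(v, "preprocess", analyte, ": selected covariates: ",
              if (length(selected)) paste(selected, collapse = ", ")
              else "(none)")

    stage_msg(v, "dyadize", analyte, ": lag k = ", config$lag)
    dyads <- build_dyad_table(excl$panel, analyte, k = config$lag,
                              centering = "grand", roster = ros)

    stage_msg(v, "fit", analyte, ": stepwise model build (",
              config$candidate_set, " candidates)")
    cands <- silm_candidates(config$candidate_set,
                             covariates = intersect(selected, names(dyads)))
    step <- stepwise_build(dyads, candidates = cands, alpha = config$alpha)
    # ICC at the random-intercept step (the classical between-person share,
    # before random slopes change the meaning of the intercept variance)
    ri <- fit_lmm(dyads, silm_spec(fixed = c("minute", "minute2", "minute3"),
                                   random = "intercept"))
    ftab <- if (inherits(step$fit$model, "lme")) {
      sequential_f_tests(step$fit)
    } else {
      NULL
    }

    stage_msg(v, "ccf", analyte, ": pairwise cross-correlations")
    cc <- pairwise_ccf(excl$panel, analyte, alpha = config$alpha)
    counts <- ccf_counts(cc)

    report$analytes[[analyte]] <- list(
      exclusions = excl$report,
      n_analysed = length(unique(excl$panel$participant_id)),
      auc = auc,
      covariate_screen = screen,
      selected_covariates = selected,
      trail = step$trail,
      spec = step$spec,
      coefficients = step$fit$coefficients,
      f_tests = ftab,
      icc = step$fit$icc,
      icc_intercept_model = ri$icc,
      r2_marginal = step$fit$r2_marginal,
      r2_conditional = step$fit$r2_conditional,
      logLik = step$fit$logLik, AIC = step$fit$AIC, BIC = step$fit$BIC,
      ccf_counts = counts
    )
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Group physiological-synchrony analysis (seed ", x$seed, ")\n", sep = "")
  print(x$roster_summary)
  for (a in names(x$analytes)) {
    r <- x$analytes[[a]]
    cat(sprintf("\n== %s ==\n", a))
    cat(sprintf("  analysed %d participants (%d excluded)\n",
                r$n_analysed, length(unique(r$exclusions$participant_id))))
    cat(sprintf("  covariates: %s\n",
                if (length(r$selected_covariates))
                  paste(r$selected_covariates, collapse = ", ") else "(none)"))
    cat(sprintf("  ICC %.3f; R2 marginal %.3f, conditional %.3f\n",
                r$icc, r$r2_marginal, r$r2_conditional))
    cat(sprintf("  CCF pairs: %d total, %d positive, %d negative\n",
                r$ccf_counts$pairs[["n_pairs"]],
                r$ccf_counts$pairs[["n_positive_pairs"]],
                r$ccf_counts$pairs[["n_negative_pairs"]]))
  }
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' @param report A `"run_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  payload <- list(
    seed = report$seed,
    roster_summary = unclass(report$roster_summary),
    analytes = lapply(report$analytes, function(r) {
      list(
        excluded = r$exclusions,
        n_analysed = r$n_analysed,
        selected_covariates = r$selected_covariates,
        trail = r$trail,
        coefficients = r$coefficients,
        f_tests = r$f_tests,
        icc = r$icc,
        icc_intercept_model = r$icc_intercept_model,
        r2_marginal = r$r2_marginal,
        r2_conditional = r$r2_conditional,
        logLik = r$logLik, AIC = r$AIC, BIC = r$BIC,
        ccf_per_lag = r$ccf_counts$per_lag,
        ccf_pairs = as.list(r$ccf_counts$pairs),
        auc_summary = list(mean = mean(r$auc$auc_i),
                           by_condition = tapply(r$auc$auc_i,
                                                 r$auc$condition, mean))
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
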