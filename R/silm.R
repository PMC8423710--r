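#' Specify a stability-and-influence model
#'
#' Terms are named by what they measure in the dyadic growth-curve model:
#' `minute`, `minute2`, `minute3` (raw, non-orthogonal polynomial time in
#' minutes), `condition` (stress vs control, participant-constant),
#' `receiver_lagged` (the receiver's own lag-k value: the stability portion),
#' `sender` and `sender_lagged` (the sender's concurrent and lag-k values:
#' the influence portion, i.e. physiological synchrony), any covariate
#' column present in the dyad table, and products of these written with
#' `:` (e.g. `"minute2:condition:sender_lagged"`). Random effects are grouped
#' by receiver participant and limited to the intercept and polynomial time
#' slopes; the intercept is required whenever any slope is present.
#'
#' @param fixed Character vector of fixed-effect term names (the intercept is
#'   implicit).
#' @param random Character subset of
#'   `c("intercept", "minute", "minute2", "minute3")`, or `NULL` for a model
#'   with no random effects.
#' @param covariance Random-effects covariance: `"unstructured"` or
#'   `"diagonal"`.
#' @param estimation `"REML"` or `"ML"`.
#' @return A list of class `"silm_spec"`.
#' @export
silm_spec <- function(fixed = c("minute", "minute2", "minute3"),
                      random = "intercept",
                      covariance = c("unstructured", "diagonal"),
                      estimation = c("REML", "ML")) {
  covariance <- match.arg(covariance)
  estimation <- match.arg(estimation)
  allowed_random <- c("intercept", "minute", "minute2", "minute3")
  if (!is.null(random)) {
    bad <- setdiff(random, allowed_random)
    if (length(bad)) stop("unsupported random term(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (length(setdiff(random, "intercept")) && !"intercept" %in% random) {
      stop("random slopes require the random intercept", call. = FALSE)
    }
  }
  structure(list(fixed = unique(fixed), random = unique(random),
                 covariance = covariance, estimation = estimation),
            class = "silm_spec")
}

#' Fixed-term set of the full dyadic influence model
#'
#' The complete fixed-effect term list of the final cortisol-style model:
#' cubic time, condition, stability (receiver lagged), influence (sender
#' concurrent and lagged), all their two- and three-way products with time
#' and condition, the stability-by-lagged-influence product, and any
#' screened covariates. With the implicit intercept this yields 31 design
#' columns when one covariate is supplied.
#'
#' @param covariates Character vector of covariate term names to append.
#' @return Character vector of term names.
#' @export
silm_terms_full <- function(covariates = "time_of_day") {
  pol <- c("minute", "minute2", "minute3")
  c(pol,
    "condition", "receiver_lagged", "sender", "sender_lagged",
    covariates,
    paste0(pol, ":condition"),
    paste0(pol, ":receiver_lagged"),
    "condition:receiver_lagged",
    paste0(pol, ":sender"),
    "condition:sender",
    paste0(pol, ":sender_lagged"),
    "condition:sender_lagged",
    "receiver_lagged:sender_lagged",
    paste0(pol, ":condition:receiver_lagged"),
    paste0(pol, ":condition:sender_lagged"))
}

# Add modelling aliases/powers to a dyad table (or any compatible frame).
prepare_model_data <- function(data) {
  d <- as.data.frame(data)
  if (!"y" %in% names(d)) stop("data must contain a `y` column", call. = FALSE)
  if (!"receiver_id" %in% names(d)) {
    if ("participant_id" %in% names(d)) {
      d$receiver_id <- d$participant_id
    } else {
      stop("data must contain `receiver_id` (or `participant_id`)",
           call. = FALSE)
    }
  }
  if ("time_minutes" %in% names(d) && !"minute" %in% names(d)) {
    d$minute <- d$time_minutes
    d$minute2 <- d$time_minutes^2
    d$minute3 <- d$time_minutes^3
  }
  if ("y_lag" %in% names(d) && !"receiver_lagged" %in% names(d)) {
    d$receiver_lagged <- d$y_lag
  }
  if ("s" %in% names(d) && !"sender" %in% names(d)) d$sender <- d$s
  if ("s_lag" %in% names(d) && !"sender_lagged" %in% names(d)) {
    d$sender_lagged <- d$s_lag
  }
  d
}

#' Build the design matrices for a model specification
#'
#' Expands the term names of a [silm_spec()] over a dyad table into fixed and
#' random design matrices with deterministic column order, checking that all
#' referenced variables exist and that the fixed design has full column rank.
#'
#' @param data A dyad table from [build_dyad_table()] (or any data frame with
#'   `y`, `receiver_id` and the referenced columns).
#' @param spec A [silm_spec()].
#' @return A list with `data` (augmented model frame), `fixed_formula`,
#'   `X` (fixed design), `random` (term names or NULL), and `groups`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "silm_spec"))
  d <- prepare_model_data(data)
  vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  missing <- setdiff(vars, names(d))
  if (length(missing)) {
    stop("unknown model variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  fixed_formula <- as.formula(paste("y ~", rhs))
  X <- model.matrix(fixed_formula, d)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (!is.null(spec$random)) {
    rmiss <- setdiff(setdiff(spec$random, "intercept"), names(d))
    if (length(rmiss)) stop("unknown random term(s): ",
                            paste(rmiss, collapse = ", "), call. = FALSE)
  }
  list(data = d, fixed_formula = fixed_formula, X = X,
       random = spec$random, groups = d$receiver_id)
}

#' Fit a stability-and-influence linear mixed model
#'
#' Maximises the (restricted) Gaussian likelihood of
#' `y = X beta + Z u + e`, with participant-level random effects
#' `u ~ N(0, Psi)` and residuals `e ~ N(0, sigma_e^2 I)`, via [nlme::lme()]
#' (or [nlme::gls()] when the specification has no random effects).
#' Convergence uses a relative log-likelihood tolerance of 1e-8 with at most
#' 500 iterations. A singular unstructured covariance triggers an automatic
#' refit with a diagonal `Psi` and a warning.
#'
#' @param data Dyad table or compatible data frame.
#' @param spec A [silm_spec()].
#' @param estimation Override of `spec$estimation` (`"REML"` or `"ML"`).
#' @return An object of class `"silm_fit"`: list with `model` (the nlme fit),
#'   `spec`, `coefficients` (term, estimate, se, df, t, p), `varcomp`
#'   (random-effect (co)variances and `sigma_e`), `logLik`, `AIC`, `BIC`,
#'   `n_obs`, `n_participants`, `icc`, `r2_marginal`, `r2_conditional`.
#' @export
fit_lmm <- function(data, spec, estimation = spec$estimation) {
  des <- build_design(data, spec)
  d <- des$data
  n_participants <- length(unique(d$receiver_id))
  if (n_participants < 2L) stop("need at least two participants",
                                call. = FALSE)
  if (nrow(d) <= ncol(des$X)) {
    stop("fewer observations than fixed parameters", call. = FALSE)
  }

  if (is.null(spec$random)) {
    model <- nlme::gls(des$fixed_formula, data = d, method = estimation,
                       control = nlme::glsControl(maxIter = 500,
                                                  msMaxIter = 500,
                                                  tolerance = 1e-8))
  } else {
    ctrl <- nlme::lmeControl(maxIter = 500, msMaxIter = 500,
                             tolerance = 1e-8, niterEM = 50,
                             returnObject = FALSE)
    pd_fun <- if (spec$covariance == "diagonal") nlme::pdDiag else nlme::pdSymm
    fit_once <- function(pd) {
      slopes <- setdiff(spec$random, "intercept")
      rhs <- if (length(slopes)) paste(c("1", slopes), collapse = " + ") else "1"
      ran <- list(receiver_id = pd(as.formula(paste("~", rhs))))
      nlme::lme(des$fixed_formula, random = ran, data = d,
                method = estimation, control = ctrl)
    }
    model <- tryCatch(fit_once(pd_fun), error = function(e) e)
    if (inherits(model, "error") && spec$covariance == "unstructured" &&
        length(spec$random) > 1L) {
      warning("unstructured random-effects covariance failed to converge; ",
              "falling back to a diagonal covariance", call. = FALSE)
      model <- tryCatch(fit_once(nlme::pdDiag), error = function(e) e)
    }
    if (inherits(model, "error")) {
      stop("mixed-model fit failed: ", conditionMessage(model), call. = FALSE)
    }
  }

  fit <- new_silm_fit(model, spec, des, n_participants)
  fit
}

new_silm_fit <- function(model, spec, des, n_participants) {
  is_lme <- inherits(model, "lme")
  sm <- summary(model)
  tt <- sm$tTable
  coefs <- tibble::tibble(
    term = rownames(tt),
    estimate = tt[, "Value"],
    se = tt[, "Std.Error"],
    df = if (is_lme) tt[, "DF"] else NA_real_,
    t = tt[, "t-value"],
    p = tt[, "p-value"]
  )
  sigma_e <- model$sigma
  psi <- NULL
  icc <- NA_real_
  if (is_lme) {
    psi <- tryCatch(as.matrix(nlme::getVarCov(model)), error = function(e) NULL)
    if (!is.null(psi) && "(Intercept)" %in% rownames(psi)) {
      icc <- psi["(Intercept)", "(Intercept)"] /
        (psi["(Intercept)", "(Intercept)"] + sigma_e^2)
    }
  }
  ll <- logLik(model)
  fit <- structure(list(
    model = model, spec = spec, design = des,
    coefficients = coefs,
    varcomp = list(psi = psi, sigma_e = sigma_e),
    logLik = as.numeric(ll), df_model = attr(ll, "df"),
    AIC = AIC(model), BIC = BIC(model),
    n_obs = nrow(des$data), n_participants = n_participants,
    icc = icc
  ), class = "silm_fit")
  r2 <- compute_r2(fit)
  fit$r2_marginal <- r2[["r2_marginal"]]
  fit$r2_conditional <- r2[["r2_conditional"]]
  fit
}

#' @export
print.silm_fit <- function(x, ...) {
  cat(sprintf("Stability-and-influence model (%s, %s)\n",
              if (inherits(x$model, "lme")) "lme" else "gls",
              x$model$method))
  cat(sprintf("  %d obs, %d participants; logLik %.3f, AIC %.3f\n",
              x$n_obs, x$n_participants, x$logLik, x$AIC))
  if (is.finite(x$icc)) cat(sprintf("  ICC %.3f;", x$icc))
  cat(sprintf(" R2 marginal %.3f, conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Variance-partition coefficients of determination
#'
#' Marginal R2 is the share of total modelled variance attributable to the
#' fixed effects, `var(X beta) / (var(X beta) + sum(random var) + sigma_e^2)`;
#' conditional R2 adds the random-effect variance (averaged over the
#' observed random design rows) to the numerator.
#'
#' @param fit A `"silm_fit"`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
compute_r2 <- function(fit) {
  stopifnot(inherits(fit, "silm_fit"))
  X <- fit$design$X
  beta <- if (inherits(fit$model, "lme")) nlme::fixef(fit$model) else coef(fit$model)
  var_f <- var(as.vector(X %*% beta[colnames(X)]))
  var_r <- 0
  psi <- fit$varcomp$psi
  if (!is.null(psi)) {
    slopes <- setdiff(fit$spec$random, "intercept")
    Z <- cbind(`(Intercept)` = rep(1, nrow(fit$design$data)))
    for (sl in slopes) Z <- cbind(Z, fit$design$data[[sl]])
    colnames(Z) <- c("(Intercept)", slopes)
    psi <- psi[colnames(Z), colnames(Z), drop = FALSE]
    var_r <- mean(rowSums((Z %*% psi) * Z))
  }
  tot <- var_f + var_r + fit$varcomp$sigma_e^2
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

#' Compare nested model fits by likelihood ratio and AIC
#'
#' The more complex model is adopted when its fit is significantly better
#' than the simpler model's (likelihood-ratio chi-square p < alpha) AND its
#' AIC is lower; ties go to the simpler model. Fixed-effect comparisons must
#' use ML fits; random-structure comparisons (identical fixed effects) may
#' use REML.
#'
#' @param simpler,complex `"silm_fit"` objects on the same data rows, with
#'   the simpler model's terms nested in the complex model's.
#' @param alpha Significance level of the likelihood-ratio test.
#' @return A list of class `"silm_comparison"`: `lrt`, `df`, `p`,
#'   `delta_aic` (complex minus simpler), `decision`
#'   (`"adopt_complex"` or `"keep_simpler"`).
#' @export
compare_fits <- function(simpler, complex, alpha = 0.05) {
  stopifnot(inherits(simpler, "silm_fit"), inherits(complex, "silm_fit"))
  if (simpler$n_obs != complex$n_obs) {
    stop("models were fitted to different numbers of rows", call. = FALSE)
  }
  nested <- all(simpler$spec$fixed %in% complex$spec$fixed) &&
    all(simpler$spec$random %in% union(complex$spec$random, character(0)))
  if (!nested) stop("models are not nested", call. = FALSE)
  same_fixed <- setequal(simpler$spec$fixed, complex$spec$fixed)
  if (simpler$model$method == "REML" && !same_fixed) {
    warning("fixed-effect comparison under REML; refit with ML",
            call. = FALSE)
  }
  df <- complex$df_model - simpler$df_model
  lrt <- 2 * (complex$logLik - simpler$logLik)
  p <- if (df > 0) pchisq(max(lrt, 0), df, lower.tail = FALSE) else NA_real_
  delta_aic <- complex$AIC - simpler$AIC
  decision <- if (!is.na(p) && p < alpha && delta_aic < 0) {
    "adopt_complex"
  } else {
    "keep_simpler"
  }
  structure(list(lrt = lrt, df = df, p = p, delta_aic = delta_aic,
                 decision = decision),
            class = "silm_comparison")
}

#' Default stepwise candidate lists
#'
#' `"full"` follows the final cortisol-model term order: random intercept,
#' random linear/quadratic/cubic time slopes, then fixed blocks (condition,
#' stability, sender influence, their time and condition products, the
#' stability-by-influence product) and finally screened covariates. `"core"`
#' is a short list for compact analyses and simulations: random intercept
#' and linear slope, condition, stability, and the sender influence block
#' (concurrent + lagged as one candidate).
#'
#' @param set `"full"` or `"core"`.
#' @param covariates Covariate term names appended as individual candidates.
#' @return List of candidates, each `list(label, type, terms)` with `type`
#'   `"random"` or `"fixed"`.
#' @export
silm_candidates <- function(set = c("full", "core"),
                            covariates = character()) {
  set <- match.arg(set)
  ran <- function(label, terms) list(label = label, type = "random",
                                     terms = terms)
  fix <- function(label, terms) list(label = label, type = "fixed",
                                     terms = terms)
  pol <- c("minute", "minute2", "minute3")
  cands <- if (set == "full") {
    c(list(
      ran("random intercept", "intercept"),
      ran("random linear slope", "minute"),
      ran("random quadratic slope", "minute2"),
      ran("random cubic slope", "minute3"),
      fix("condition", "condition"),
      fix("stability (receiver lagged)", "receiver_lagged"),
      fix("sender concurrent", "sender"),
      fix("sender lagged", "sender_lagged"),
      fix("time x condition", paste0(pol, ":condition")),
      fix("time x stability", paste0(pol, ":receiver_lagged")),
      fix("condition x stability", "condition:receiver_lagged"),
      fix("time x sender", paste0(pol, ":sender")),
      fix("condition x sender", "condition:sender"),
      fix("time x sender lagged", paste0(pol, ":sender_lagged")),
      fix("condition x sender lagged", "condition:sender_lagged"),
      fix("stability x sender lagged", "receiver_lagged:sender_lagged"),
      fix("time x condition x stability",
          paste0(pol, ":condition:receiver_lagged")),
      fix("time x condition x sender lagged",
          paste0(pol, ":condition:sender_lagged"))
    ))
  } else {
    list(
      ran("random intercept", "intercept"),
      ran("random linear slope", "minute"),
      fix("condition", "condition"),
      # condition-specific trajectory shape; without it, shared mean-curve
      # misfit within a condition masquerades as sender influence
      fix("time x condition", paste0(pol, ":condition")),
      fix("stability (receiver lagged)", "receiver_lagged"),
      fix("sender influence (concurrent + lagged)",
          c("sender", "sender_lagged"))
    )
  }
  c(cands, lapply(covariates, function(cv) fix(paste("covariate", cv), cv)))
}

#' Stepwise model building with LRT/AIC arbitration
#'
#' Starting from a base model with fixed polynomial time only (and no random
#' effects), each candidate random block or fixed block is adopted when the
#' more complex model fits significantly better per [compare_fits()].
#' Random-structure steps are compared under REML (identical fixed effects),
#' fixed-effect steps under ML; the final model is refit with REML for
#' reporting. Random slope candidates are skipped while the random intercept
#' has not been adopted.
#'
#' @param data Dyad table.
#' @param candidates Candidate list, e.g. from [silm_candidates()].
#' @param base Base specification (default: cubic fixed time, no random
#'   effects).
#' @param alpha Significance level for adoption.
#' @return A list of class `"silm_stepwise"`: `fit` (final REML fit),
#'   `spec`, and `trail` (tibble of candidate, type, lrt, df, p, delta_aic,
#'   decision).
#' @export
stepwise_build <- function(data, candidates = silm_candidates("full"),
                           base = silm_spec(fixed = c("minute", "minute2",
                                                      "minute3"),
                                            random = NULL),
                           alpha = 0.05) {
  current <- base
  cache <- list(ML = NULL, REML = NULL)
  get_fit <- function(method) {
    if (is.null(cache[[method]])) {
      cache[[method]] <<- fit_lmm(data, current, estimation = method)
    }
    cache[[method]]
  }
  rows <- list()
  for (cand in candidates) {
    proposed <- current
    if (cand$type == "random") {
      if (!identical(cand$terms, "intercept") &&
          !"intercept" %in% (current$random %||% character(0))) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          candidate = cand$label, type = cand$type, lrt = NA_real_,
          df = NA_real_, p = NA_real_, delta_aic = NA_real_,
          decision = "skipped (no random intercept)")
        next
      }
      proposed$random <- union(current$random %||% character(0), cand$terms)
      method <- "REML"
    } else {
      proposed$fixed <- c(current$fixed, cand$terms)
      method <- "ML"
    }
    simpler <- get_fit(method)
    complex <- tryCatch(fit_lmm(data, proposed, estimation = method),
                        error = function(e) e)
    if (inherits(complex, "error")) {
      trail <- do.call(rbind, rows)
      cond <- simpleError(paste0("stepwise fit failed at candidate '",
                                 cand$label, "': ",
                                 conditionMessage(complex)))
      cond$trail <- trail
      stop(cond)
    }
    cmp <- compare_fits(simpler, complex, alpha = alpha)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      candidate = cand$label, type = cand$type, lrt = cmp$lrt, df = cmp$df,
      p = cmp$p, delta_aic = cmp$delta_aic, decision = cmp$decision)
    if (cmp$decision == "adopt_complex") {
      current <- proposed
      cache <- list(ML = NULL, REML = NULL)
      cache[[method]] <- complex
    }
  }
  current$estimation <- "REML"
  final <- fit_lmm(data, current, estimation = "REML")
  structure(list(fit = final, spec = current, trail = do.call(rbind, rows)),
            class = "silm_stepwise")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.silm_stepwise <- function(x, ...) {
  cat("Stepwise stability-and-influence model build\n")
  print(as.data.frame(x$trail), digits = 3)
  cat("\nFinal model:\n")
  print(x$fit)
  invisible(x)
}

#' Sequential F tests for the fixed effects
#'
#' Sequential (terms-added-in-order) conditional F statistics for the fixed
#' effects of a fitted model, with containment denominator degrees of
#' freedom: terms varying within participant are tested against
#' `n_obs - n_participants - p_inner`, participant-constant terms against
#' `n_participants - p_outer - 1`.
#'
#' @param fit A `"silm_fit"` from a model with random effects.
#' @return Tibble with `term, df_num, df_den, F, p`.
#' @export
sequential_f_tests <- function(fit) {
  stopifnot(inherits(fit, "silm_fit"))
  if (!inherits(fit$model, "lme")) {
    stop("sequential F tests require a model with random effects",
         call. = FALSE)
  }
  a <- anova(fit$model)
  tibble::tibble(term = rownames(a),
                 df_num = a$numDF, df_den = a$denDF,
                 F = a$`F-value`, p = a$`p-value`)
}
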