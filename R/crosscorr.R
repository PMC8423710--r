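#' Sample cross-correlation function of two series
#'
#' Standard sample CCF convention: full-series means and n-denominator
#' standard deviations,
#' `r(k) = [sum_t (x_t - xbar) (y_{t+k} - ybar) / n] / (s_x s_y)`,
#' defined for `-max_lag <= k <= max_lag`. Positive lags mean `x` leads `y`
#' (x's values correlate with y's future values); `r_xy(k) = r_yx(-k)`.
#'
#' @param x,y Numeric series of equal length `n >= 2`, no missing values.
#' @param max_lag Maximum |lag|; must be `< n`.
#' @return Tibble with columns `lag` (`-max_lag ... max_lag`) and `r`.
#' @export
cross_correlation <- function(x, y, max_lag = length(x) - 1L) {
  n <- length(x)
  if (length(y) != n) stop("series lengths differ", call. = FALSE)
  if (n < 2L) stop("need series of length >= 2", call. = FALSE)
  if (max_lag >= n || max_lag < 0) stop("`max_lag` must be in [0, n)",
                                        call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(mean(xc^2))
  sy <- sqrt(mean(yc^2))
  if (sx == 0 || sy == 0) {
    stop("zero-variance series: cross-correlation undefined", call. = FALSE)
  }
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      sum(xc[seq_len(n - k)] * yc[seq_len(n - k) + k])
    } else {
      sum(xc[seq_len(n + k) - k] * yc[seq_len(n + k)])
    }
  }, numeric(1)) / (n * (sx * sy))
  tibble::tibble(lag = lags, r = r)
}

#' Conventional limit for significance of a cross-correlation coefficient
#'
#' The large-sample white-noise bound `z_(1-alpha/2) / sqrt(n)`: a CC
#' coefficient whose absolute value exceeds this limit is deemed
#' significantly different from zero at level `alpha`.
#'
#' @param n Series length (`>= 2`).
#' @param alpha Two-sided significance level.
#' @param multiplier Optional fixed critical multiplier (e.g. 2) used
#'   instead of the normal quantile.
#' @return Positive scalar limit.
#' @examples
#' ccsl(7)  # 1.96 / sqrt(7) ~ 0.741
#' @export
ccsl <- function(n, alpha = 0.05, multiplier = NULL) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  z <- if (is.null(multiplier)) qnorm(1 - alpha / 2) else multiplier
  z / sqrt(n)
}

#' Pairwise cross-correlation functions within groups
#'
#' Computes the CCF for every unordered within-group pair of one analyte's
#' series (directionality is carried by the lag sign: for the pair (a, b)
#' with `id_a < id_b`, positive lags mean a leads b). Each coefficient is
#' compared with the conventional significance limit for the series length.
#' Groups of size 1 are skipped.
#'
#' @param panel Measurement panel.
#' @param analyte Analyte name.
#' @param max_lag Maximum |lag| (default `M - 1`).
#' @param alpha Two-sided level for the significance limit.
#' @param multiplier Optional fixed critical multiplier for [ccsl()].
#' @return Tibble of class `"ccf_table"`: one row per pair and lag with
#'   `group_id, id_a, id_b, lag, r, ccsl, significant, sign`.
#' @export
pairwise_ccf <- function(panel, analyte, max_lag = NULL, alpha = 0.05,
                         multiplier = NULL) {
  validate_panel(panel)
  sub <- panel[panel$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("analyte not present in panel: ", analyte,
                            call. = FALSE)
  sub <- sub[order(sub$participant_id, sub$t), ]
  M <- length(unique(sub$t))
  if (is.null(max_lag)) max_lag <- M - 1L
  limit <- ccsl(M, alpha = alpha, multiplier = multiplier)
  series <- split(sub$value, sub$participant_id)
  info <- sub[!duplicated(sub$participant_id), ]
  groups <- split(info$participant_id, info$group_id)

  pieces <- list()
  for (g in sort(names(groups))) {
    members <- sort(as.character(groups[[g]]))
    if (length(members) < 2L) next
    prs <- combn(members, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      cc <- cross_correlation(series[[a]], series[[b]], max_lag = max_lag)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        group_id = g, id_a = a, id_b = b,
        lag = cc$lag, r = cc$r, ccsl = limit,
        significant = abs(cc$r) > limit,
        sign = ifelse(abs(cc$r) > limit,
                      ifelse(cc$r > 0, "positive", "negative"),
                      NA_character_)
      )
    }
  }
  if (!length(pieces)) stop("no within-group pairs of size >= 2",
                            call. = FALSE)
  out <- do.call(rbind, pieces)
  structure(out, class = c("ccf_table", class(out)),
            analyte = analyte, alpha = alpha, ccsl = limit, M = M)
}

#' Count significant cross-correlations
#'
#' Aggregates a [pairwise_ccf()] table into per-lag counts of significant
#' positive and negative coefficients (non-negative lags) and overall pair
#' counts: a pair counts as positive (negative) when any of its lags shows a
#' significant positive (negative) coefficient.
#'
#' @param ccf_table A `"ccf_table"`.
#' @return List with `per_lag` (tibble `lag, n_pairs, n_sig_positive,
#'   n_sig_negative`) and `pairs` (named counts `n_pairs`,
#'   `n_positive_pairs`, `n_negative_pairs`).
#' @export
ccf_counts <- function(ccf_table) {
  stopifnot(inherits(ccf_table, "ccf_table"))
  nn <- ccf_table[ccf_table$lag >= 0, , drop = FALSE]
  lags <- sort(unique(nn$lag))
  per_lag <- do.call(rbind, lapply(lags, function(k) {
    s <- nn[nn$lag == k, ]
    tibble::tibble(lag = k, n_pairs = nrow(s),
                   n_sig_positive = sum(s$significant & s$r > 0),
                   n_sig_negative = sum(s$significant & s$r < 0))
  }))
  key <- paste(ccf_table$group_id, ccf_table$id_a, ccf_table$id_b)
  pos <- tapply(ccf_table$significant & ccf_table$r > 0, key, any)
  neg <- tapply(ccf_table$significant & ccf_table$r < 0, key, any)
  list(per_lag = per_lag,
       pairs = c(n_pairs = length(pos),
                 n_positive_pairs = sum(pos),
                 n_negative_pairs = sum(neg)))
}
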