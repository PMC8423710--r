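#' Enumerate ordered sender-receiver dyads within a group
#'
#' Every ordered pair without self-pairs, so that each member acts as sender
#' as well as receiver: a group \{A, B, C\} yields A-B, A-C, B-A, B-C, C-A,
#' C-B (g * (g - 1) pairs for group size g). Order is deterministic (sorted
#' by sender, then receiver).
#'
#' @param ids Unique member identifiers.
#' @return Tibble with columns `sender`, `receiver`.
#' @export
enumerate_dyads <- function(ids) {
  if (anyDuplicated(ids)) stop("`ids` must be unique", call. = FALSE)
  ids <- sort(as.character(ids))
  if (length(ids) < 2L) {
    return(tibble::tibble(sender = character(0), receiver = character(0)))
  }
  grid <- expand.grid(receiver = ids, sender = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$sender != grid$receiver, c("sender", "receiver")]
  grid <- grid[order(grid$sender, grid$receiver), ]
  tibble::as_tibble(grid)
}

#' Expand a panel into the stacked dyadic analysis table
#'
#' Builds the long table the stability-and-influence model consumes: one row
#' per ordered within-group sender-receiver dyad and measurement occasion
#' `t in {k, ..., M-1}`, carrying the receiver's current value `y`, the
#' receiver's lag-k value `y_lag`, and the sender's concurrent and lag-k
#' values `s`, `s_lag`. Rows with undefined lags (t < k) are dropped. With
#' `centering = "grand"` the level-1 predictors `y_lag`, `s`, `s_lag` are
#' centred on their grand means across the table (time is left uncentred);
#' the constants are stored in the `centering` attribute so estimates can be
#' back-transformed. Row order is deterministic:
#' (group, receiver, sender, t).
#'
#' @param panel Measurement panel.
#' @param analyte Analyte to model.
#' @param k Lag size (default 1); must satisfy `k < M`.
#' @param centering `"grand"` or `"none"`.
#' @param roster Optional roster; its covariate columns (everything beyond
#'   id/group/condition) are joined onto the receiver rows, with categorical
#'   covariates dummy-expanded.
#' @return A tibble of class `"dyad_table"` with attributes `analyte`, `k`,
#'   `M`, and `centering`.
#' @export
build_dyad_table <- function(panel, analyte, k = 1,
                             centering = c("grand", "none"),
                             roster = NULL) {
  validate_panel(panel)
  centering <- match.arg(centering)
  sub <- panel[panel$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("analyte not present in panel: ", analyte,
                            call. = FALSE)
  M <- length(unique(sub$t))
  if (k >= M) stop("lag `k` must be smaller than the number of occasions M",
                   call. = FALSE)
  sub <- sub[order(sub$participant_id, sub$t), ]
  ids <- unique(sub$participant_id)
  val <- matrix(sub$value, nrow = length(ids), ncol = M, byrow = TRUE,
                dimnames = list(ids, NULL))
  times <- sub$time_minutes[seq_len(M)]
  info <- sub[!duplicated(sub$participant_id),
              c("participant_id", "group_id", "condition")]

  groups <- split(info$participant_id, info$group_id)
  pieces <- vector("list", length(groups))
  gnames <- sort(names(groups))
  for (gi in seq_along(gnames)) {
    g <- gnames[gi]
    members <- groups[[g]]
    dy <- enumerate_dyads(members)
    if (nrow(dy) == 0L) next
    # deterministic (receiver, sender) order within group
    dy <- dy[order(dy$receiver, dy$sender), ]
    tt <- k:(M - 1L)
    nd <- nrow(dy)
    rec <- rep(dy$receiver, each = length(tt))
    sen <- rep(dy$sender, each = length(tt))
    tv <- rep.int(tt, nd)
    rec_i <- match(rec, ids)
    sen_i <- match(sen, ids)
    pieces[[gi]] <- tibble::tibble(
      group_id = g,
      receiver_id = rec,
      sender_id = sen,
      t = tv,
      time_minutes = times[tv + 1L],
      condition = info$condition[match(rec, info$participant_id)],
      y = val[cbind(rec_i, tv + 1L)],
      y_lag = val[cbind(rec_i, tv + 1L - k)],
      s = val[cbind(sen_i, tv + 1L)],
      s_lag = val[cbind(sen_i, tv + 1L - k)]
    )
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    stop("no dyads: every group has fewer than two members", call. = FALSE)
  }

  if (!is.null(roster)) {
    cov_cols <- setdiff(names(roster),
                        c("participant_id", "group_id", "condition"))
    idx <- match(out$receiver_id, roster$participant_id)
    for (cv in cov_cols) {
      x <- roster[[cv]][idx]
      if (is.character(x) || is.factor(x)) {
        mm <- model.matrix(~ x)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, "_", sub("^x", "", colnames(mm)))
        for (j in seq_len(ncol(mm))) out[[colnames(mm)[j]]] <- mm[, j]
      } else {
        out[[cv]] <- as.numeric(x)
      }
    }
  }

  constants <- c(y_lag = 0, s = 0, s_lag = 0)
  if (centering == "grand") {
    for (cl in names(constants)) {
      constants[[cl]] <- mean(out[[cl]])
      out[[cl]] <- out[[cl]] - constants[[cl]]
    }
  }
  structure(out,
            class = c("dyad_table", class(out)),
            analyte = analyte, k = k, M = M,
            centering = list(scheme = centering, constants = constants))
}
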