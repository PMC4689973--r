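#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_effect Incremental effect (QALYs or LYs); must be positive —
#'   non-positive effect differences are dominance cases and are handled by
#'   [frontier()], not by a ratio.
#' @return Cost per unit of effect.
#' @export
icer <- function(delta_cost, delta_effect) {
  if (any(delta_effect <= 0)) {
    stop("delta_effect must be positive; compute dominance instead",
         call. = FALSE)
  }
  delta_cost / delta_effect
}

#' Net monetary benefit
#'
#' `threshold * qalys - cost`.  At a given willingness-to-pay threshold the
#' NMB-maximising strategy is the optimal one; NMB underlies the
#' cost-effectiveness acceptability curve.
#'
#' @param cost Total cost (USD).
#' @param qalys Total QALYs.
#' @param threshold Willingness to pay, USD per QALY (>= 0).
#' @return Net monetary benefit in USD.
#' @export
nmb <- function(cost, qalys, threshold) {
  if (any(threshold < 0)) stop("threshold must be >= 0", call. = FALSE)
  threshold * qalys - cost
}

#' Cost-effectiveness frontier with dominance pruning
#'
#' Strategies are rank-ordered by increasing cost (ties broken by higher
#' QALYs, then name, for determinism).  A strategy is dominated if a
#' cheaper-or-equal strategy achieves at least its QALYs.  ICERs are then
#' computed successively along the surviving frontier.  Extended dominance
#' (a higher ICER than the next frontier member) is flagged; flagged
#' strategies are excluded from the successive-ICER computation only when
#' `exclude_extended = TRUE`.
#'
#' @param totals Data frame with columns `strategy`, `cost`, `qalys` and
#'   optionally `lys` (e.g. from [totals_table()]).
#' @param exclude_extended If `TRUE`, iteratively remove extendedly
#'   dominated strategies and recompute ICERs.
#' @return Data frame of class `osteo_cea_table`, ordered by cost:
#'   `strategy`, `cost`, `lys`, `qalys`, `status` (`reference`,
#'   `on_frontier`, `dominated`, `extendedly_dominated`), incremental
#'   columns and ICERs per QALY and per LY versus the previous frontier
#'   member.
#' @export
frontier <- function(totals, exclude_extended = FALSE) {
  stopifnot(all(c("strategy", "cost", "qalys") %in% names(totals)))
  if (anyDuplicated(totals$strategy)) {
    stop("duplicate strategy names", call. = FALSE)
  }
  if (nrow(totals) < 2L) stop("need at least 2 strategies", call. = FALSE)
  df <- totals[order(totals$cost, -totals$qalys, totals$strategy), ,
               drop = FALSE]
  if (is.null(df$lys)) df$lys <- NA_real_
  n <- nrow(df)
  df$status <- "on_frontier"
  df$inc_cost <- df$inc_qalys <- df$inc_lys <- NA_real_
  df$icer_qaly <- df$icer_ly <- NA_real_

  # simple dominance: anything not strictly improving on the best QALYs of
  # all cheaper (or equally cheap, earlier-ranked) strategies is dominated
  best_q <- -Inf
  for (i in seq_len(n)) {
    if (df$qalys[i] <= best_q) {
      df$status[i] <- "dominated"
    } else {
      best_q <- df$qalys[i]
    }
  }

  compute_icers <- function(df) {
    surv <- which(df$status %in% c("reference", "on_frontier"))
    df$status[surv[1]] <- "reference"
    if (length(surv) > 1L) {
      for (j in seq_along(surv)[-1]) {
        i <- surv[j]; prev <- surv[j - 1L]
        df$inc_cost[i] <- df$cost[i] - df$cost[prev]
        df$inc_qalys[i] <- df$qalys[i] - df$qalys[prev]
        df$inc_lys[i] <- df$lys[i] - df$lys[prev]
        df$icer_qaly[i] <- icer(df$inc_cost[i], df$inc_qalys[i])
        df$icer_ly[i] <- if (!is.na(df$inc_lys[i]) && df$inc_lys[i] > 0) {
          df$inc_cost[i] / df$inc_lys[i]
        } else {
          NA_real_
        }
      }
    }
    df
  }
  df <- compute_icers(df)

  flag_extended <- function(df) {
    surv <- which(df$status %in% c("reference", "on_frontier"))
    flagged <- integer()
    if (length(surv) > 2L) {
      ic <- df$icer_qaly[surv]
      for (j in 2:(length(surv) - 1L)) {
        if (!is.na(ic[j]) && !is.na(ic[j + 1L]) && ic[j] > ic[j + 1L]) {
          flagged <- c(flagged, surv[j])
        }
      }
    }
    flagged
  }

  if (exclude_extended) {
    repeat {
      flagged <- flag_extended(df)
      if (!length(flagged)) break
      df$status[flagged] <- "extendedly_dominated"
      df$inc_cost[flagged] <- df$inc_qalys[flagged] <- NA_real_
      df$inc_lys[flagged] <- NA_real_
      df$icer_qaly[flagged] <- df$icer_ly[flagged] <- NA_real_
      df <- compute_icers(df)
    }
  } else {
    df$extended_dominance_flag <- FALSE
    df$extended_dominance_flag[flag_extended(df)] <- TRUE
  }

  rownames(df) <- NULL
  class(df) <- c("osteo_cea_table", "data.frame")
  df
}

#' @export
print.osteo_cea_table <- function(x, ...) {
  show <- data.frame(
    strategy = x$strategy,
    cost = sprintf("$%.0f", x$cost),
    lys = ifelse(is.na(x$lys), "", sprintf("%.4f", x$lys)),
    qalys = sprintf("%.4f", x$qalys),
    status = x$status,
    icer_per_qaly = ifelse(x$status == "dominated", "dominated",
                    ifelse(is.na(x$icer_qaly), "ref.",
                           sprintf("$%.0f", round_icer(x$icer_qaly))))
  )
  print(show, row.names = FALSE, ...)
  invisible(x)
}
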