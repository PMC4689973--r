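#' Assemble the standard report tables
#'
#' Collects the model outputs into the standard report layout: the CEA
#' table (totals, increments, ICERs), the 10-year fracture-risk table, the
#' disaggregated cost-component table, and optionally a tornado table and
#' CEAC.  Every table cross-foots to the totals computed by the accounting
#' layer; monetary values are stored unrounded (rendering rounds ICERs to
#' the nearest $100).
#'
#' @param cea An `osteo_cea` from [run_cea()] or [scenario()].
#' @param tornado Optional `osteo_tornado` from [one_way_dsa()].
#' @param ceac Optional CEAC data frame from [ceac()].
#' @return Object of class `osteo_report`: a list of data frames
#'   (`cea_table`, `risk_table`, `cost_components`, `tornado`, `ceac`).
#' @export
report_bundle <- function(cea, tornado = NULL, ceac = NULL) {
  tot <- cea$totals
  risk <- tot[c("strategy", "risk10_hip", "risk10_vertebral",
                "risk10_nhnv")]
  comp <- tot[c("strategy", "cost_drug", "cost_admin_monitoring",
                "cost_fracture_year1", "cost_fracture_subsequent",
                "cost_long_term_care", "cost")]
  structure(list(cea_table = cea$frontier, risk_table = risk,
                 cost_components = comp, tornado = tornado, ceac = ceac),
            class = "osteo_report")
}

#' Write report tables to a directory
#'
#' Writes each table as CSV plus a human-readable Markdown summary
#' (`report.md`) in which ICERs are rounded to the nearest $100.
#'
#' @param bundle An `osteo_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("cea_table", "risk_table", "cost_components", "tornado",
              "ceac")
  for (t in tables) {
    if (!is.null(bundle[[t]])) {
      write.csv(bundle[[t]], file.path(dir, paste0(t, ".csv")),
                row.names = FALSE)
    }
  }

  md <- c("# Cost-effectiveness report", "",
          "## Lifetime discounted totals and ICERs", "")
  ft <- bundle$cea_table
  md <- c(md,
          "| Strategy | Cost | LYs | QALYs | Status | ICER/QALY |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | $%.0f | %.4f | %.4f | %s | %s |",
                  ft$strategy, ft$cost, ft$lys, ft$qalys, ft$status,
                  ifelse(is.na(ft$icer_qaly), "--",
                         sprintf("$%.0f", round_icer(ft$icer_qaly)))),
          "", "## 10-year fracture risks", "")
  rt <- bundle$risk_table
  md <- c(md,
          "| Strategy | Hip | Vertebral | NHNV |",
          "|---|---|---|---|",
          sprintf("| %s | %.3f | %.3f | %.3f |", rt$strategy,
                  rt$risk10_hip, rt$risk10_vertebral, rt$risk10_nhnv))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param tornado An `osteo_tornado` from [one_way_dsa()].
#' @param top Number of widest parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 10L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado needs the ggplot2 package", call. = FALSE)
  }
  df <- utils::head(tornado[is.finite(tornado$width), , drop = FALSE], top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base[1]),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity of the pairwise ICER")
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ceac_df Data frame from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ceac needs the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(ceac_df,
                  ggplot2::aes(x = .data$threshold, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves")
}
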