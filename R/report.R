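# Session store and report rendering: one JSON file per session per test
# under a results root; reports aggregate components across sessions into a
# repeatability/stability summary table with tolerance verdicts.

#' Write a session's measurements to a JSON file
#'
#' @param measurements list of [measurement()]s (or a data.frame from
#'   [measurements_df()]).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_session_json <- function(measurements, path) {
  df <- if (is.data.frame(measurements)) measurements
  else measurements_df(measurements)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read every session JSON under a results root
#'
#' @param root directory searched recursively for `.json` session files.
#' @return data.frame `test`, `component`, `units`, `session`, `value`.
#' @export
read_sessions <- function(root) {
  files <- list.files(root, pattern = "\\.json$", full.names = TRUE,
                      recursive = TRUE)
  if (!length(files)) abort_qa(sprintf("no session JSON files under %s", root))
  do.call(rbind, lapply(files, function(f)
    as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE))))
}

#' Render a repeatability/stability report
#'
#' Aggregates measurements per component and phase into the standard QA
#' summary shape: component, reference rule, repeatability mean/SD (n = 3
#' same-day setups), stability mean/SD (n = 12 monthly sessions), with
#' per-component tolerance verdicts on the means. Components with fewer
#' sessions than expected are rendered with their n noted; mixed units
#' within one component are an error.
#'
#' @param sessions data.frame with columns `test`, `component`, `units`,
#'   `session`, `value` and `phase` (`"repeatability"` or `"stability"`).
#' @param tolerances optional [tolerance_spec()].
#' @param out_dir optional output directory for `report.csv` and
#'   `report.json`.
#' @return data.frame, one row per component.
#' @export
render_report <- function(sessions, tolerances = NULL, out_dir = NULL) {
  need <- c("test", "component", "units", "session", "value", "phase")
  if (!all(need %in% names(sessions)))
    abort_qa(sprintf("sessions must have columns: %s",
                     paste(need, collapse = ", ")))
  rows <- lapply(split(sessions, sessions[c("component", "test")], drop = TRUE),
                 function(g) {
    if (length(unique(g$units)) > 1L)
      abort_qa(sprintf("mixed units for component '%s': %s", g$component[1],
                       paste(unique(g$units), collapse = " vs ")))
    phase_stats <- function(phase) {
      v <- g$value[g$phase == phase]
      if (!length(v)) return(list(n = 0L, mean = NA_real_, sd = NA_real_))
      s <- summarize_values(v)
      list(n = s$n, mean = s$mean, sd = s$sd)
    }
    rep <- phase_stats("repeatability"); sta <- phase_stats("stability")
    verdict <- "none"; rule <- "none"
    if (!is.null(tolerances) && g$component[1] %in% names(tolerances$rules)) {
      value <- if (rep$n > 0) rep$mean else sta$mean
      v <- apply_tolerance(value, tolerances, component = g$component[1])
      verdict <- v$verdict; rule <- v$rule
    }
    data.frame(test = g$test[1], component = g$component[1],
               units = g$units[1], reference = rule,
               repeat_n = rep$n, repeat_mean = rep$mean, repeat_sd = rep$sd,
               stability_n = sta$n, stability_mean = sta$mean,
               stability_sd = sta$sd, verdict = verdict)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$test, out$component), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Monthly trend plot for one component
#'
#' Simple longitudinal plot of a component's sessions in order, with the
#' mean as a reference line. Requires the suggested ggplot2 package.
#'
#' @param sessions data.frame as in [render_report()].
#' @param component component label to plot.
#' @return a ggplot object.
#' @export
qa_trend_plot <- function(sessions, component) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_qa("qa_trend_plot requires the ggplot2 package")
  g <- sessions[sessions$component == component, , drop = FALSE]
  if (!nrow(g)) abort_qa(sprintf("no sessions for component '%s'", component))
  g$index <- seq_len(nrow(g))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = mean(g$value), linetype = "dashed") +
    ggplot2::labs(x = "session", y = sprintf("%s [%s]", component, g$units[1]),
                  title = component)
}
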