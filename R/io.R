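#' Export a velocity profile to CSV
#'
#' Long form has columns `time`, `r`, `velocity`; matrix form has the
#' radial grid as the first row, the time grid as the first column and the
#' velocity matrix (time by radius) in the body.
#'
#' @param p A `flow_profile`.
#' @param path Output file path.
#' @param shape `"long"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path, shape = c("long", "matrix")) {
  shape <- match.arg(shape)
  if (shape == "long") {
    utils::write.csv(as.data.frame(p)[c("time", "r", "velocity")], path,
                     row.names = FALSE)
  } else {
    r <- attr(p, "r_grid")
    t <- attr(p, "t_grid")
    U <- t(profile_matrix(p))            # time rows, radius columns
    m <- rbind(c(NA, r), cbind(t, U))
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, na = "")
  }
  invisible(path)
}

#' Export a wall shear stress series to CSV (columns t, tau_w)
#'
#' @param s A `wss_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wss_csv <- function(s, path) {
  df <- data.frame(t = s$time, tau_w = s$wss)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a flow-rate series to CSV (columns t, q)
#'
#' @param q A `flow_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(q, path) {
  utils::write.csv(data.frame(t = q$time, q = q$flow), path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a JSON analysis report
#'
#' Writes the per-method summaries, the method comparison (when present)
#' and a provenance block (package version, configuration echo, seed)
#' sufficient to reproduce the run.
#'
#' @param fit A [wss_analysis()] result.
#' @param path Output file path.
#' @param config Optional configuration list echoed into the report.
#' @param seed Optional integer seed echoed into the report.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(fit, path, config = NULL, seed = NULL) {
  stopifnot(inherits(fit, "wss_fit"))
  report <- list(
    provenance = list(
      package = "pulsewss",
      version = as.character(utils::packageVersion("pulsewss")),
      seed = seed,
      config = config),
    alpha = fit$alpha,
    reynolds = fit$reynolds,
    n_harmonics = fit$n_harmonics,
    summary = fit$summary,
    comparison = fit$comparison)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
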