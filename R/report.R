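#' Envirotype the seasons of a factorial run table
#'
#' Clusters the non-LT stress trajectories attached by
#' `run_factorial(..., keep_trajectories = TRUE)`, names the environments,
#' and joins the per-season E_W label back onto every row of the table
#' (all traits of a site-year-management cell share the label of its
#' non-LT run, which is how the environment classes are defined).
#'
#' @param table a factorial table carrying the `"trajectories"` attribute.
#' @param k_range candidate cluster numbers.
#' @param seed clustering seed.
#' @return the table with an `env_w` column (NA for seasons whose non-LT
#'   run failed); the classification object is attached as attribute
#'   `"envclass"`.
#' @export
envirotype_runs <- function(table, k_range = 2:8, seed = 1L) {
  traj <- attr(table, "trajectories")
  rows <- attr(table, "trajectory_rows")
  if (is.null(traj)) {
    stop("table carries no trajectories; re-run run_factorial() with ",
         "keep_trajectories = TRUE", call. = FALSE)
  }
  cl <- name_environments(cluster_trajectories(traj, k_range, seed), traj)
  key <- c("site", "year", "maturity", "planting")
  lab <- cbind(table[rows, key], env_w = cl$season_env)
  out <- merge(table, lab, by = key, all.x = TRUE, sort = FALSE)
  attr(out, "envclass") <- cl
  out
}

#' Write the analysis report tables
#'
#' Writes each available table as a tidy CSV plus a plain-text summary.
#' Sections whose input is missing are marked absent; regeneration from
#' identical inputs is byte-identical.
#'
#' @param tables named list; recognised names are `runs`,
#'   `relative_change`, `frequencies`, `sensitivity_moisture`,
#'   `sensitivity_cap`, `best_combination`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
report <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("runs", "relative_change", "frequencies",
             "sensitivity_moisture", "sensitivity_cap", "best_combination")
  paths <- character(0)
  lines <- c("Limited-transpiration simulation report", "")
  for (nm in known) {
    tab <- tables[[nm]]
    if (is.null(tab)) {
      lines <- c(lines, sprintf("[%s] absent", nm))
      next
    }
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
    lines <- c(lines, sprintf("[%s] %d rows -> %s", nm, nrow(tab),
                              basename(p)))
    if (nm == "relative_change") {
      lines <- c(lines, utils::capture.output(print(tab, digits = 3)), "")
    }
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(c(paths, file.path(dir, "summary.txt")))
}
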