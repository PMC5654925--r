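## End-to-end orchestration: registration -> frame clipping -> percentile
## displacement -> classification, with per-tree artifacts and a cross-tree
## summary. Used by the numbered analysis scripts; each stage is also
## callable on its own.

#' Run configuration
#'
#' @param output_dir directory for per-tree artifacts and the summary.
#' @param levels percentile levels (default deciles).
#' @param cell_size raster cell size, m.
#' @param config a \code{\link{classification_config}}.
#' @param seed integer seed recorded with the run.
#' @param write_plots write a displacement SVG per tree.
#' @return a \code{run_config} list.
#' @export
run_config <- function(output_dir = "results", levels = default_levels(),
                       cell_size = 0.10, config = classification_config(),
                       seed = 1L, write_plots = TRUE) {
  stopifnot(cell_size > 0)
  structure(list(output_dir = output_dir, levels = levels,
                 cell_size = cell_size, config = config,
                 seed = as.integer(seed), write_plots = write_plots),
            class = "run_config")
}

#' Run the full pipeline over one or more trees
#'
#' Each element of \code{trees} is a list with \code{series} (a
#' \code{scan_series}), \code{frame} (a \code{canopy_frame}), and optionally
#' \code{targets} (data frame \code{scan_id,label,x,y,z}; when present the
#' series is first registered to its fixed first scan). Per tree the function
#' writes a registration report (JSON), a long-format displacement CSV, a
#' classification JSON, and (optionally) a displacement SVG, then returns a
#' cross-tree summary. A failure in one tree is logged into the summary and
#' the remaining trees proceed.
#'
#' @param trees named list of per-tree inputs (see above).
#' @param cfg a \code{\link{run_config}}.
#' @return data frame summary: one row per tree with the primary/secondary
#'   labels, amplitude evidence, max mean tension (mm) and status.
#' @export
run_pipeline <- function(trees, cfg = run_config()) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(trees), function(id) {
    tr <- trees[[id]]
    res <- tryCatch({
      tension_mm <- NA_real_
      series <- tr$series
      if (!is.null(tr$targets)) {
        reg <- register_series(series, tr$targets)
        series <- reg$series
        tension_mm <- reg$report$max_mean_tension * 1000
        write_registration_report(
          reg$report, file.path(cfg$output_dir,
                                sprintf("%s_registration.json", id)))
      }
      ds <- displacement_series(series, tr$frame, cfg$levels)
      cls <- classify_movement(ds, cfg$config)
      write_displacement_csv(
        ds, file.path(cfg$output_dir, sprintf("%s_displacement.csv", id)))
      write_classification_json(
        cls, file.path(cfg$output_dir, sprintf("%s_classification.json", id)))
      if (isTRUE(cfg$write_plots))
        plot_displacement(ds, cls,
                          file.path(cfg$output_dir,
                                    sprintf("%s_displacement.svg", id)))
      data.frame(
        tree_id = id, status = "ok",
        primary_label = cls$primary_label,
        secondary_labels = paste(cls$secondary_labels, collapse = "+"),
        max_abs_mean_displacement_cm =
          max(abs(ds$mean_displacement)) * 100,
        n_valid_levels = sum(ds$valid_levels),
        max_mean_tension_mm = tension_mm,
        error = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(tree_id = id, status = "error", primary_label = NA_character_,
                 secondary_labels = NA_character_,
                 max_abs_mean_displacement_cm = NA_real_,
                 n_valid_levels = NA_integer_, max_mean_tension_mm = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(cfg$output_dir, "summary.csv"),
                   row.names = FALSE)
  summary
}

#' Plot a percentile-displacement series
#'
#' One curve per percentile level versus hours since the first scan
#' (displacement in meters, upward positive); levels excluded from the mean
#' by the narrow-slab rule are drawn in gray, the mean curve is bold. The
#' classification label is shown in the subtitle. Written as SVG (or PNG by
#' extension); rendering is deterministic given the inputs.
#'
#' @param dseries a \code{displacement_series}.
#' @param classification optional \code{movement_classification} for the
#'   subtitle.
#' @param path output file (.svg or .png).
#' @param width,height device size in inches.
#' @return the path, invisibly.
#' @export
plot_displacement <- function(dseries, classification = NULL, path,
                              width = 7, height = 4.5) {
  tab <- displacement_table(dseries)
  tab$level_lab <- sprintf("%d%%", round(tab$level * 100))
  mean_df <- data.frame(time_h = dseries$times_h,
                        displacement_m = dseries$mean_displacement)
  sub <- if (is.null(classification)) NULL else
    sprintf("classified: %s%s", classification$primary_label,
            if (length(classification$secondary_labels))
              paste0(" + ", paste(classification$secondary_labels,
                                  collapse = ", ")) else "")
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = time_h,
                                         y = displacement_m,
                                         group = level_lab)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_line(data = tab[!tab$valid, ], colour = "grey65",
                       linewidth = 0.35) +
    ggplot2::geom_line(data = tab[tab$valid, ],
                       ggplot2::aes(colour = level_lab),
                       linewidth = 0.45) +
    ggplot2::geom_line(data = mean_df,
                       ggplot2::aes(x = time_h, y = displacement_m),
                       inherit.aes = FALSE, colour = "black",
                       linewidth = 1.1) +
    ggplot2::labs(x = "time since first scan (h)", y = "displacement (m)",
                  colour = "percentile",
                  title = sprintf("Height-percentile displacement — %s",
                                  dseries$tree_id),
                  subtitle = sub) +
    ggplot2::theme_minimal(base_size = 10)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  }
  print(p)
  grDevices::dev.off()
  invisible(path)
}
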