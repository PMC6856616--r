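## Result tables and run manifest.  Column schemas are stable contracts;
## mV values are rounded to 2 decimals on write only.

.schemas <- list(
  morphometrics = c("mito_id", "frame", "area_um2", "perimeter_um",
                    "circularity", "aspect_ratio"),
  potentials = c("mito_id", "object_id", "compartment", "frame", "mean_FI",
                 "reference_mode", "delta_psi_mv", "temperature_K"),
  cristae = c("mito_id", "crista_id", "frame", "position_um", "prominence",
              "delta_psi_cr_ibm_mv"),
  events = c("mito_id", "event_id", "kind", "t_start_s", "t_end_s",
             "depth_fraction", "speed_um_per_s", "class")
)

#' Write pipeline result tables
#'
#' Writes one CSV per result category (`morphometrics.csv`,
#' `potentials.csv`, `cristae.csv`, `events.csv`) with a stable column
#' schema, plus `manifest.json` carrying the configuration and package
#' version. Missing categories yield headers-only files so downstream
#' tooling always finds the schema. mV columns are rounded to 2 decimals.
#'
#' @param results Named list with any of `morphometrics`, `potentials`,
#'   `cristae`, `events` data.frames.
#' @param out_dir Output directory (created if needed).
#' @param config The `mv_config` used, echoed into the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_tables <- function(results, out_dir, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(.schemas)) {
    cols <- .schemas[[nm]]
    df <- results[[nm]]
    if (is.null(df) || !nrow(df)) {
      df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                          cols))
    } else {
      missing <- setdiff(cols, names(df))
      for (mc in missing) df[[mc]] <- NA
      df <- df[, cols, drop = FALSE]
      mv_cols <- grep("_mv$|^delta_psi", names(df), value = TRUE)
      for (mc in mv_cols) df[[mc]] <- round(as.numeric(df[[mc]]), 2)
    }
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(package = "mitovolt",
                   version = as.character(utils::packageVersion("mitovolt")),
                   config = unclass(config))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mf))
}
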