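#' Calibrated multi-channel time-lapse container
#'
#' A thin container around a numeric array indexed `(t, channel, y, x)`
#' with pixel size, frame interval and channel names.
#'
#' @param pixels Numeric array of shape `(t, channel, y, x)`; a matrix or
#'   3-d array is promoted with singleton time/channel dimensions.
#' @param pixel_size_nm Pixel size in nm. If missing a default of 40 nm is
#'   used with a warning.
#' @param frame_interval_s Frame interval in seconds (default 1 with
#'   warning when missing).
#' @param channel_names Character vector, one per channel.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, pixel_size_nm = NULL, frame_interval_s = NULL,
                        channel_names = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, 1L, nrow(pixels), ncol(pixels)))
  } else if (length(dim(pixels)) == 3L) {
    d <- dim(pixels)
    pixels <- array(pixels, dim = c(d[1L], 1L, d[2L], d[3L]))
  }
  stopifnot(length(dim(pixels)) == 4L)
  if (any(pixels < 0, na.rm = TRUE)) {
    stop("frame_stack: pixels must be non-negative", call. = FALSE)
  }
  if (is.null(pixel_size_nm)) {
    warning("frame_stack: pixel_size_nm missing, defaulting to 40 nm")
    pixel_size_nm <- 40
  }
  if (is.null(frame_interval_s)) {
    warning("frame_stack: frame_interval_s missing, defaulting to 1 s")
    frame_interval_s <- 1
  }
  nc <- dim(pixels)[2L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  stopifnot(length(channel_names) == nc)
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 channel_names = channel_names),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %d frame(s) x %d channel(s) x %d x %d px; %g nm/px, %g s/frame\n",
              d[1], d[2], d[3], d[4], x$pixel_size_nm, x$frame_interval_s))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one frame/channel as a matrix
#' @param stack A [frame_stack()].
#' @param frame Frame index (1-based).
#' @param channel Channel index or name.
#' @return Numeric matrix.
#' @export
get_frame <- function(stack, frame = 1L, channel = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("get_frame: unknown channel", call. = FALSE)
  }
  stack$pixels[frame, channel, , ]
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer.
#' @export
n_frames <- function(stack) dim(stack$pixels)[1L]

#' Write a simulated or measured stack to disk
#'
#' One multi-page 32-bit float TIFF per channel plus a JSON metadata
#' sidecar (`metadata.json`: pixel size, frame interval, channel names).
#' When ground truth is supplied, the label map is written as `labels.tif`
#' and the crista registry/event log as `truth.json`.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `mv_truth` from [simulate_timelapse()].
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir, truth = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$pixels)
  for (c in seq_len(d[2L])) {
    pages <- lapply(seq_len(d[1L]), function(t) stack$pixels[t, c, , ])
    write_tiff(pages, file.path(dir, paste0(stack$channel_names[c], ".tif")))
  }
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               frame_interval_s = stack$frame_interval_s,
               channel_names = as.list(stack$channel_names))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth)) {
    write_tiff(list(matrix(as.numeric(truth$labels), nrow(truth$labels))),
               file.path(dir, "labels.tif"))
    ev <- lapply(truth$events, function(e) e[!vapply(e, is.null, logical(1))])
    tj <- list(registry = truth$registry, events = ev,
               scenario_name = truth$scenario$name,
               psi_matrix_mv = truth$scenario$psi_matrix_mv,
               psi_ibm_offset_mv = truth$scenario$psi_ibm_offset_mv,
               psi_crista_offset_mv = truth$scenario$psi_crista_offset_mv,
               per_crista_offsets_mv = truth$scenario$per_crista_offsets_mv)
    jsonlite::write_json(tj, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read an image stack from disk
#'
#' Accepts either a directory produced by [write_stack()] (per-channel
#' TIFFs plus `metadata.json`) or a single TIFF file. Missing calibration
#' metadata falls back to defaults with a warning.
#'
#' @param path Directory or TIFF file path.
#' @param metadata_path Optional explicit path to the JSON sidecar.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, metadata_path = NULL) {
  if (dir.exists(path)) {
    meta_file <- metadata_path %||% file.path(path, "metadata.json")
    meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file) else NULL
    chn <- if (!is.null(meta)) unlist(meta$channel_names) else {
      sub("[.]tif$", "", setdiff(basename(Sys.glob(file.path(path, "*.tif"))),
                                 "labels.tif"))
    }
    if (!length(chn)) stop("read_stack: no channel TIFFs found", call. = FALSE)
    chans <- lapply(chn, function(nm) read_tiff(file.path(path, paste0(nm, ".tif"))))
    nt <- length(chans[[1L]])
    dims <- dim(chans[[1L]][[1L]])
    for (ch in chans) {
      if (length(ch) != nt || !identical(dim(ch[[1L]]), dims)) {
        stop("read_stack: channel shapes do not match", call. = FALSE)
      }
    }
    pixels <- array(0, dim = c(nt, length(chans), dims[1L], dims[2L]))
    for (c in seq_along(chans)) for (t in seq_len(nt)) {
      pixels[t, c, , ] <- chans[[c]][[t]]
    }
    frame_stack(pixels,
                pixel_size_nm = if (!is.null(meta)) meta$pixel_size_nm else NULL,
                frame_interval_s = if (!is.null(meta)) meta$frame_interval_s else NULL,
                channel_names = chn)
  } else {
    pages <- read_tiff(path)
    nt <- length(pages)
    dims <- dim(pages[[1L]])
    pixels <- array(0, dim = c(nt, 1L, dims[1L], dims[2L]))
    for (t in seq_len(nt)) pixels[t, 1L, , ] <- pages[[t]]
    meta <- NULL
    if (!is.null(metadata_path) && file.exists(metadata_path)) {
      meta <- jsonlite::read_json(metadata_path)
    }
    frame_stack(pixels,
                pixel_size_nm = if (!is.null(meta)) meta$pixel_size_nm else NULL,
                frame_interval_s = if (!is.null(meta)) meta$frame_interval_s else NULL,
                channel_names = if (!is.null(meta)) unlist(meta$channel_names) else NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
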