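#' Pseudo-colour LUT rendering of a frame
#'
#' Encodes pixel intensity with the conventional potentiometric-imaging
#' colour ordering: white (most intense / highest potential) through red
#' and green down to blue (least intense). Writes a PNG with a legend bar
#' when `path` is given; always returns the colour assignment.
#'
#' @param frame Numeric matrix.
#' @param path Optional PNG output path.
#' @param scale Either "frame" (min/max of this frame) or a numeric
#'   `c(lo, hi)` fixed scale shared across frames.
#' @param n_colors Number of LUT bins.
#' @return Invisibly, a list with `colors` (character matrix of hex
#'   colours) and `breaks`.
#' @export
render_lut <- function(frame, path = NULL, scale = "frame", n_colors = 256L) {
  stopifnot(is.matrix(frame))
  if (identical(scale, "frame")) {
    lo <- min(frame); hi <- max(frame)
  } else {
    stopifnot(is.numeric(scale), length(scale) == 2L)
    lo <- scale[1L]; hi <- scale[2L]
  }
  ramp <- grDevices::colorRampPalette(c("blue", "green", "red", "white"))
  pal <- ramp(n_colors)
  if (hi <= lo) {
    idx <- matrix(1L, nrow(frame), ncol(frame))  # constant frame: one colour
  } else {
    sc <- (pmin(pmax(frame, lo), hi) - lo) / (hi - lo)
    idx <- matrix(pmin(n_colors, 1L + floor(sc * (n_colors - 1L) + 0.5)),
                  nrow(frame), ncol(frame))
  }
  cols <- matrix(pal[idx], nrow(frame), ncol(frame))
  if (!is.null(path)) {
    ny <- nrow(frame); nx <- ncol(frame)
    legend_w <- max(12L, nx %/% 10L)
    grDevices::png(path, width = nx + legend_w + 8L, height = ny,
                   type = "cairo")
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, nx + legend_w + 8L), ylim = c(0, ny),
                          xaxs = "i", yaxs = "i")
    graphics::rasterImage(grDevices::as.raster(cols), 0, 0, nx, ny,
                          interpolate = FALSE)
    leg <- grDevices::as.raster(matrix(rev(pal), ncol = 1L))
    graphics::rasterImage(leg, nx + 8L, 0, nx + 8L + legend_w, ny,
                          interpolate = TRUE)
  }
  invisible(list(colors = cols, breaks = seq(lo, hi, length.out = n_colors)))
}
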