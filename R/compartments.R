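#' Axial intensity profile along a mitochondrion
#'
#' Every object pixel is assigned to its nearest axis point; the profile
#' value at axis point *i* is the mean intensity of pixels assigned to
#' points within `band_halfwidth_px` of *i* (a transverse band for curved
#' as well as straight axes).
#'
#' @param frame Intensity matrix (one channel, one frame).
#' @param mito A `mito_object`.
#' @param axis Result of [extract_axis()] for that object.
#' @param band_halfwidth_px Axial half-width of the averaging band.
#' @return List with `arclength_um` and `intensity` vectors, plus the
#'   per-pixel axis assignment (`pixel_axis_idx`, aligned with
#'   `mito$pixels`).
#' @export
axial_profile <- function(frame, mito, axis, band_halfwidth_px = 2L) {
  n <- length(axis$rows)
  if (n < 3L) stop("axial_profile: axis shorter than 3 points", call. = FALSE)
  ny <- nrow(frame)
  pr <- (mito$pixels - 1L) %% ny + 1L
  pc <- (mito$pixels - 1L) %/% ny + 1L
  ## nearest axis point per object pixel
  d2 <- outer(pr, axis$rows, `-`)^2 + outer(pc, axis$cols, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  vals <- frame[mito$pixels]
  intensity <- vapply(seq_len(n), function(i) {
    sel <- abs(nearest - i) <= band_halfwidth_px
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  ## fill rare empty bands by neighbour interpolation
  if (anyNA(intensity)) {
    ok <- which(!is.na(intensity))
    intensity <- stats::approx(ok, intensity[ok], xout = seq_len(n),
                               rule = 2)$y
  }
  list(arclength_um = axis$arclength_um, intensity = intensity,
       pixel_axis_idx = nearest)
}

## Local maxima with prominence, minimum spacing and leftmost plateau
## tie-break.  Prominence of a peak: height above the higher of the two
## deepest valleys separating it from higher ground (standard definition).
.find_peaks <- function(y, min_prominence, min_spacing_pts) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L  # plateau
      if (j == n || y[j + 1L] < y[i]) cand <- c(cand, i)  # leftmost index
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    lv <- y[p]; k <- p
    left_min <- lv
    while (k > 1L) { k <- k - 1L; left_min <- min(left_min, y[k])
      if (y[k] > lv) break }
    rv <- lv; k <- p; right_min <- lv
    while (k < n) { k <- k + 1L; right_min <- min(right_min, y[k])
      if (y[k] > lv) break }
    lv - max(left_min, right_min)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  ## enforce spacing, keeping the more prominent peak
  ord <- order(prom, decreasing = TRUE)
  sel <- logical(length(keep))
  for (k in ord) {
    if (!any(sel & abs(keep - keep[k]) < min_spacing_pts)) sel[k] <- TRUE
  }
  sort(keep[sel])
}

#' Detect cristae as transverse intensity peaks
#'
#' Local-maximum detection on the structural-channel axial profile with a
#' prominence floor (fraction of the profile dynamic range) and a minimum
#' spacing at the resolution limit. Peak positions are refined to
#' sub-pixel precision by a parabolic fit around each maximum. Equal-height
#' plateaus resolve to the leftmost index.
#'
#' @param profile Result of [axial_profile()] (structural channel).
#' @param min_prominence_frac Prominence floor as a fraction of the profile
#'   dynamic range.
#' @param min_spacing_nm Minimum peak spacing in nm.
#' @param pixel_size_nm Pixel size in nm.
#' @return data.frame with `crista_id`, `axis_idx`, `position_um`,
#'   `prominence`; zero rows when the profile is flat.
#' @export
detect_cristae <- function(profile, min_prominence_frac = 0.1,
                           min_spacing_nm = 120, pixel_size_nm = 40) {
  y <- profile$intensity
  rng <- diff(range(y))
  if (rng <= 0) {
    return(data.frame(crista_id = integer(0), axis_idx = integer(0),
                      position_um = numeric(0), prominence = numeric(0)))
  }
  arc <- profile$arclength_um
  step_um <- mean(diff(arc))
  spacing_pts <- max(1, (min_spacing_nm / 1000) / step_um)
  idx <- .find_peaks(y, min_prominence = min_prominence_frac * rng,
                     min_spacing_pts = spacing_pts)
  if (!length(idx)) {
    return(data.frame(crista_id = integer(0), axis_idx = integer(0),
                      position_um = numeric(0), prominence = numeric(0)))
  }
  pos <- vapply(idx, function(p) {
    if (p <= 1L || p >= length(y)) return(arc[p])
    denom <- y[p - 1L] - 2 * y[p] + y[p + 1L]
    if (denom >= 0) return(arc[p])
    delta <- 0.5 * (y[p - 1L] - y[p + 1L]) / denom
    arc[p] + max(min(delta, 0.5), -0.5) * step_um
  }, numeric(1))
  prom <- vapply(idx, function(p) {
    y[p] - min(y[max(1L, p - 3L):min(length(y), p + 3L)])
  }, numeric(1))
  data.frame(crista_id = seq_along(idx), axis_idx = idx,
             position_um = pos, prominence = prom)
}

#' Classify object pixels into crista / IBM / matrix
#'
#' The object boundary shell (thickness `ibm_shell_px`) becomes IBM; pixels
#' assigned to the axis point of each detected crista (a transverse 1-px
#' band) become crista; the remaining interior is matrix. IBM pixels whose
#' axial position falls within `ibm_exclude_halfwidth_px` of a crista are
#' kept in the label map but flagged out of the IBM quantification mask
#' (`ibm_quant`), because PSF bleed-through from the crista contaminates
#' them.
#'
#' @param mito A `mito_object`.
#' @param axis [extract_axis()] result.
#' @param profile [axial_profile()] result (supplies the pixel-axis
#'   assignment).
#' @param cristae [detect_cristae()] result.
#' @param config An `mv_config`.
#' @return List: `labels` (integer matrix using [compartment_labels()]
#'   codes; background outside the object), `ibm_quant` (logical matrix),
#'   `crista_pixels` (list of linear indices per detected crista).
#' @export
classify_pixels <- function(mito, axis, profile, cristae,
                            config = default_config()) {
  ny <- nrow(mito$mask); nx <- ncol(mito$mask)
  labels <- matrix(LABELS[["background"]], ny, nx)
  ## threshold masks overshoot the membrane ridge by the blur halo; inset
  ## the shell so it sits on the true boundary (halo pixels -> cytosol)
  core <- mito$mask
  for (k in seq_len(config$ibm_inset_px)) core <- .erode4(core)
  inner <- core
  for (k in seq_len(config$ibm_shell_px)) inner <- .erode4(inner)
  ibm <- core & !inner
  labels[mito$mask] <- LABELS[["cytosol"]]
  labels[core] <- LABELS[["matrix"]]
  labels[ibm] <- LABELS[["ibm"]]
  nearest <- profile$pixel_axis_idx
  crista_pixels <- list()
  for (k in seq_len(nrow(cristae))) {
    band <- mito$pixels[nearest == cristae$axis_idx[k]]
    band <- band[inner[band]]
    labels[band] <- LABELS[["crista"]]
    crista_pixels[[k]] <- band
  }
  ## IBM quantification mask: drop shell pixels axially near a crista
  ibm_quant <- ibm
  if (nrow(cristae)) {
    excl <- config$ibm_exclude_halfwidth_px
    ibm_idx <- which(ibm)
    near <- nearest[match(ibm_idx, mito$pixels)]
    bad <- rep(FALSE, length(ibm_idx))
    for (k in seq_len(nrow(cristae))) {
      bad <- bad | abs(near - cristae$axis_idx[k]) <= excl
    }
    ibm_quant[ibm_idx[bad]] <- FALSE
  }
  list(labels = labels, ibm_quant = ibm_quant,
       crista_pixels = crista_pixels)
}

#' Detect detached hyperpolarized vesicles
#'
#' Bright interior components of the potentiometric channel: interior
#' (matrix- or crista-labelled) pixels at least `vesicle_k` times the
#' median matrix intensity, forming an 8-connected component of at least
#' `vesicle_min_area_um2`, with no pixel 8-adjacent to the IBM shell
#' (detached from the boundary; genuine crista bands reach the IBM and are
#' rejected by this rule). Matching pixels are relabelled vesicle. A
#' detected "crista" whose band is mostly vesicle pixels is a structural
#' false positive (vesicles are bright in the structural channel too) and
#' is reported in `dropped_cristae`.
#'
#' @param frame_pot Potentiometric-channel matrix.
#' @param classification [classify_pixels()] result.
#' @param pixel_size_nm Pixel size in nm.
#' @param config An `mv_config`.
#' @return List: `labels` (updated matrix), `vesicles` (list of linear
#'   index vectors, one per accepted vesicle), `dropped_cristae` (indices
#'   into `classification$crista_pixels`).
#' @export
detect_vesicles <- function(frame_pot, classification, pixel_size_nm,
                            config = default_config()) {
  labels <- classification$labels
  px <- pixel_size_nm / 1000
  mat_idx <- labels == LABELS[["matrix"]]
  out0 <- list(labels = labels, vesicles = list(),
               dropped_cristae = integer(0))
  if (!any(mat_idx)) return(out0)
  med <- stats::median(frame_pot[mat_idx])
  interior <- mat_idx | labels == LABELS[["crista"]]
  cand <- interior & frame_pot >= config$vesicle_k * med
  if (!any(cand)) return(out0)
  comp <- cpp_label(cand)
  ibm_grown <- .dilate8(labels == LABELS[["ibm"]])
  min_px <- config$vesicle_min_area_um2 / px^2
  vesicles <- list()
  for (id in seq_len(max(comp))) {
    idx <- which(comp == id)
    if (length(idx) < min_px) next
    if (any(ibm_grown[idx])) next   # touching the boundary: not detached
    labels[idx] <- LABELS[["vesicle"]]
    vesicles[[length(vesicles) + 1L]] <- idx
  }
  ves_idx <- unlist(vesicles)
  dropped <- which(vapply(classification$crista_pixels, function(band)
    length(band) > 0 && mean(band %in% ves_idx) > 0.25, logical(1)))
  list(labels = labels, vesicles = vesicles,
       dropped_cristae = as.integer(dropped))
}

#' Pearson correlation of two axial profiles
#'
#' Used to quantify co-partitioning of the structural and potentiometric
#' dyes along the organelle axis. Zero-variance profiles have no defined
#' correlation and return NA.
#'
#' @param profile_a,profile_b Equal-length numeric vectors or
#'   [axial_profile()] results.
#' @return Correlation in `[-1, 1]`, or NA.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  a <- if (is.list(profile_a)) profile_a$intensity else profile_a
  b <- if (is.list(profile_b)) profile_b$intensity else profile_b
  if (length(a) != length(b)) {
    stop("profile_correlation: profiles differ in length", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}
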