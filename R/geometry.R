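#' Rasterize the scenario geometry into a compartment label map
#'
#' Draws a capsule-shaped mitochondrion on a canvas with a 1 um margin:
#' a 1-px inner-boundary-membrane (IBM) ring on the capsule boundary,
#' `n_cristae` 1-px-wide transverse crista bands at the stated spacing
#' (centered on the organelle), detached vesicles as disks, matrix
#' elsewhere inside, cytosol outside. Membranes are drawn 1 px wide because
#' real cristae/IBM are below the resolution limit; the PSF blur applied at
#' render time produces their apparent width.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `mv_geometry`: list with `labels` (integer
#'   matrix, codes of [compartment_labels()]), `axial_um` (matrix of axial
#'   coordinates in um from the left tip, NA outside the object),
#'   `registry` (data.frame crista_id / axial_um / col), `crista_pixels`
#'   (list of linear pixel indices per crista), `vesicle_pixels`,
#'   `x0_um` (canvas x of the left tip) and `pixel_size_nm`.
#' @export
build_geometry <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  px <- scenario$pixel_size_nm / 1000  # um per pixel
  margin <- 1
  nx <- round((scenario$length_um + 2 * margin) / px) + 1L
  ny <- round((scenario$width_um + 2 * margin) / px) + 1L
  if (nx < 8 || ny < 8) stop("build_geometry: canvas too small", call. = FALSE)

  xs <- (seq_len(nx) - 1) * px       # physical x of each column
  ys <- (seq_len(ny) - 1) * px
  x0 <- margin                        # left tip
  x1 <- margin + scenario$length_um   # right tip
  r <- scenario$width_um / 2
  cy <- ys[[(ny + 1L) %/% 2L]]

  ## capsule: distance to the central segment [x0 + r, x1 - r] at y = cy
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  Xc <- pmin(pmax(X, x0 + r), x1 - r)
  D <- sqrt((X - Xc)^2 + (Y - cy)^2)
  mask <- D <= r + 1e-9

  labels <- matrix(LABELS[["cytosol"]], ny, nx)
  labels[mask] <- LABELS[["matrix"]]

  ## IBM: 1-px ring = mask pixels with a 4-neighbour outside
  interior <- .erode4(mask)
  ibm <- mask & !interior
  labels[ibm] <- LABELS[["ibm"]]

  ## cristae: transverse 1-px columns through the interior
  n <- scenario$n_cristae
  registry <- data.frame(crista_id = integer(0), axial_um = numeric(0),
                         col = integer(0))
  crista_pixels <- list()
  if (n > 0) {
    centers <- scenario$length_um / 2 +
      (seq_len(n) - (n + 1) / 2) * scenario$crista_spacing_um
    cols <- round((x0 + centers) / px) + 1L
    if (any(cols < 1 | cols > nx)) {
      stop("build_geometry: crista outside canvas", call. = FALSE)
    }
    for (k in seq_len(n)) {
      sel <- which(interior[, cols[k]])
      idx <- (cols[k] - 1L) * ny + sel  # linear indices
      labels[idx] <- LABELS[["crista"]]
      crista_pixels[[k]] <- idx
    }
    registry <- data.frame(crista_id = seq_len(n),
                           axial_um = (cols - 1) * px - x0,
                           col = cols)
  }

  ## vesicles: disks in the matrix, must not touch (8-adjacency) the IBM
  vesicle_pixels <- list()
  for (v in scenario$vesicles) {
    vc_x <- x0 + v$position_um
    disk <- sqrt((X - vc_x)^2 + (Y - cy)^2) <= v$radius_um + 1e-9
    grown <- .dilate8(disk)
    if (any(grown & ibm)) {
      stop("build_geometry: vesicle overlaps or touches the IBM",
           call. = FALSE)
    }
    labels[disk] <- LABELS[["vesicle"]]   # vesicle overrides crista pixels
    vesicle_pixels[[length(vesicle_pixels) + 1L]] <- which(disk)
  }
  if (length(vesicle_pixels)) {
    crista_pixels <- lapply(crista_pixels, function(idx)
      idx[labels[idx] == LABELS[["crista"]]])
  }

  axial <- matrix(NA_real_, ny, nx)
  axial[mask] <- pmin(pmax(X[mask] - x0, 0), scenario$length_um)

  structure(list(labels = labels, axial_um = axial, registry = registry,
                 crista_pixels = crista_pixels,
                 vesicle_pixels = vesicle_pixels,
                 mask = mask, x0_um = x0, cy_um = cy,
                 pixel_size_nm = scenario$pixel_size_nm),
            class = "mv_geometry")
}

## binary erosion / dilation with small fixed neighbourhoods
.erode4 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- mask
  out[c(1, ny), ] <- FALSE
  out[, c(1, nx)] <- FALSE
  inner_r <- 2:(ny - 1); inner_c <- 2:(nx - 1)
  out[inner_r, inner_c] <- mask[inner_r, inner_c] &
    mask[inner_r - 1, inner_c] & mask[inner_r + 1, inner_c] &
    mask[inner_r, inner_c - 1] & mask[inner_r, inner_c + 1]
  out
}

.dilate8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  out <- matrix(FALSE, ny, nx)
  for (dj in 0:2) for (di in 0:2) {
    out <- out | pad[(1 + di):(ny + di), (1 + dj):(nx + dj)]
  }
  out
}

#' Baseline per-pixel potential field of a scenario
#'
#' Assigns each pixel its membrane potential in mV (positive =
#' hyperpolarized versus cytosol) from the scenario's compartment
#' potentials: cytosol 0, matrix `psi_matrix_mv`, IBM matrix + IBM offset,
#' crista i IBM + crista offset + per-crista deviation, vesicle IBM +
#' vesicle offset.
#'
#' @param geometry Result of [build_geometry()].
#' @param scenario The matching [sim_scenario()].
#' @return Numeric matrix of mV values.
#' @export
potential_map <- function(geometry, scenario) {
  stopifnot(inherits(geometry, "mv_geometry"))
  lab <- geometry$labels
  psi <- matrix(0, nrow(lab), ncol(lab))
  psi_ibm <- scenario$psi_matrix_mv + scenario$psi_ibm_offset_mv
  psi[lab == LABELS[["matrix"]]] <- scenario$psi_matrix_mv
  psi[lab == LABELS[["ibm"]]] <- psi_ibm
  for (k in seq_along(geometry$crista_pixels)) {
    psi[geometry$crista_pixels[[k]]] <- psi_ibm +
      scenario$psi_crista_offset_mv + scenario$per_crista_offsets_mv[[k]]
  }
  for (k in seq_along(geometry$vesicle_pixels)) {
    psi[geometry$vesicle_pixels[[k]]] <- psi_ibm +
      scenario$vesicles[[k]]$psi_offset_mv
  }
  psi
}
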