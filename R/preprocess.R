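## Rolling-ball structuring element: offsets within `radius` and the height
## of a ball of that radius above each offset.
.ball_se <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dy^2 + g$dx^2
  keep <- d2 <= radius^2
  list(dy = as.integer(g$dy[keep]), dx = as.integer(g$dx[keep]),
       h = sqrt(radius^2 - d2[keep]))
}

## min-downsample by integer factor s (pad by edge replication)
.shrink_min <- function(img, s) {
  ny <- nrow(img); nx <- ncol(img)
  ny2 <- ceiling(ny / s); nx2 <- ceiling(nx / s)
  pad <- img[pmin(seq_len(ny2 * s), ny), pmin(seq_len(nx2 * s), nx),
             drop = FALSE]
  dim(pad) <- c(s, ny2, s, nx2)
  apply(pad, c(2, 4), min)
}

.enlarge_bilinear <- function(img, ny, nx, s) {
  ## block centres sit at rows (i-1)*s + (s+1)/2
  src_y <- ((seq_len(ny) - (s + 1) / 2) / s) + 1
  src_x <- ((seq_len(nx) - (s + 1) / 2) / s) + 1
  src_y <- pmin(pmax(src_y, 1), nrow(img))
  src_x <- pmin(pmax(src_x, 1), ncol(img))
  y0 <- pmax(pmin(floor(src_y), nrow(img) - 1L), 1L)
  x0 <- pmax(pmin(floor(src_x), ncol(img) - 1L), 1L)
  wy <- src_y - y0; wx <- src_x - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0 + 1, x0, drop = FALSE]
  c_ <- img[y0, x0 + 1, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  WY <- matrix(wy, ny, nx); WX <- matrix(wx, ny, nx, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * WY * (1 - WX) + c_ * (1 - WY) * WX +
    d * WY * WX
}

#' Rolling-ball background estimate
#'
#' Grayscale opening with a ball-shaped structuring element: the background
#' is the surface traced by rolling a ball of the given radius under the
#' intensity landscape. For large radii the image is min-downsampled by 4
#' first (`shrink = "auto"`), the classic speed-up; `shrink = 1` forces the
#' exact computation.
#'
#' @param frame Numeric matrix.
#' @param radius_px Ball radius in pixels (default 50).
#' @param shrink "auto", or an integer downsampling factor.
#' @return Background matrix of the same shape.
#' @export
rolling_ball_background <- function(frame, radius_px = 50, shrink = "auto") {
  stopifnot(is.matrix(frame), radius_px >= 1)
  if (radius_px >= min(dim(frame))) {
    stop("rolling_ball_background: radius larger than image", call. = FALSE)
  }
  s <- if (identical(shrink, "auto")) (if (radius_px >= 16) 4L else 1L)
  else as.integer(shrink)
  if (s > 1L) {
    small <- .shrink_min(frame, s)
    se <- .ball_se(radius_px / s)
    bg_small <- cpp_gray_dilate(cpp_gray_erode(small, se$dy, se$dx, se$h),
                                se$dy, se$dx, se$h)
    bg <- .enlarge_bilinear(bg_small, nrow(frame), ncol(frame), s)
    pmin(bg, frame + 0)   # background never exceeds the image after interp
  } else {
    se <- .ball_se(radius_px)
    cpp_gray_dilate(cpp_gray_erode(frame, se$dy, se$dx, se$h),
                    se$dy, se$dx, se$h)
  }
}

#' Subtract the rolling-ball background
#'
#' @inheritParams rolling_ball_background
#' @return Background-subtracted frame, clipped at 0.
#' @export
subtract_background <- function(frame, radius_px = 50, shrink = "auto") {
  pmax(frame - rolling_ball_background(frame, radius_px, shrink), 0)
}

## Otsu threshold on a numeric matrix.
.otsu <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(n_bins, 1L + floor((img - rng[1L]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1L] + k / n_bins * diff(rng)
}

## Moore-neighbour outer contour trace; returns perimeter length as the
## 8-connected chain length (1 for axial, sqrt(2) for diagonal moves).
## Termination by Jacob's criterion: stop when the start pixel is re-entered
## from the same backtrack cell.
.contour_perimeter <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  if (sum(mask) == 1L) return(4)  # single pixel: unit square
  start <- which(mask)[1L]       # leftmost column, topmost row
  si <- (start - 1L) %% ny + 1L; sj <- (start - 1L) %/% ny + 1L
  ## clockwise neighbour offsets starting north
  dy <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dx <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  inside <- function(i, j) i >= 1L && i <= ny && j >= 1L && j <= nx &&
    mask[i, j]
  ci <- si; cj <- sj
  bi <- si; bj <- sj - 1L        # backtrack: west cell (background)
  per <- 0
  step_limit <- 4L * sum(mask) + 8L
  steps <- 0L
  state1 <- NULL                 # (pixel, backtrack) after the first move
  repeat {
    ## index of the backtrack cell among the neighbours of (ci, cj)
    bidx <- which(dy == bi - ci & dx == bj - cj)
    found <- FALSE
    for (k in 1:8) {
      d <- (bidx + k - 1L) %% 8L + 1L
      ni <- ci + dy[d]; nj <- cj + dx[d]
      if (inside(ni, nj)) {
        prev_d <- (bidx + k - 2L) %% 8L + 1L
        nbi <- ci + dy[prev_d]; nbj <- cj + dx[prev_d]
        per <- per + if (abs(dy[d]) + abs(dx[d]) == 2L) sqrt(2) else 1
        ci <- ni; cj <- nj
        bi <- nbi; bj <- nbj
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated pixel (should not happen here)
    steps <- steps + 1L
    state <- c(ci, cj, bi, bj)
    if (is.null(state1)) {
      state1 <- state
      per1 <- per              # length of the artificial first step
    } else if (all(state == state1)) {
      per <- per - per1        # closed cycle length from the first state
      break
    }
    if (steps > step_limit) break  # safety
  }
  per
}

#' Segment mitochondria and compute whole-object morphometrics
#'
#' Global Otsu threshold on the (background-subtracted) structural channel,
#' 8-connected components, minimum-area filter, optional removal of
#' edge-touching objects, then per-object morphometrics: area, perimeter
#' (8-connected contour length), circularity `4 pi A / P^2` and aspect
#' ratio (major/minor axis of the intensity-free best-fit ellipse from
#' second moments). Digitization can push circularity of near-circular
#' objects slightly above 1.
#'
#' @param frame Background-subtracted structural-channel matrix.
#' @param pixel_size_nm Pixel size in nm.
#' @param config An `mv_config`.
#' @param threshold Optional fixed threshold overriding Otsu.
#' @return List of `mito_object`s, each with `id`, `pixels` (linear
#'   indices), `mask`, `area_um2`, `perimeter_um`, `circularity`,
#'   `aspect_ratio`, `centroid`.
#' @export
segment_mitochondria <- function(frame, pixel_size_nm,
                                 config = default_config(),
                                 threshold = NULL) {
  px <- pixel_size_nm / 1000
  thr <- threshold %||% .otsu(frame)
  mask <- frame > thr
  if (!any(mask)) return(list())
  lab <- cpp_label(mask)
  objs <- list()
  ny <- nrow(mask); nx <- ncol(mask)
  min_px <- config$min_area_um2 / px^2
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id)
    if (length(idx) < min_px) next
    rows <- (idx - 1L) %% ny + 1L
    cols <- (idx - 1L) %/% ny + 1L
    if (config$discard_edge_objects &&
        (any(rows %in% c(1L, ny)) || any(cols %in% c(1L, nx)))) next
    m <- matrix(FALSE, ny, nx); m[idx] <- TRUE
    area <- length(idx) * px^2
    per <- .contour_perimeter(m) * px
    ## second central moments -> best-fit ellipse axes
    mu_r <- mean(rows); mu_c <- mean(cols)
    crr <- mean((rows - mu_r)^2); ccc <- mean((cols - mu_c)^2)
    crc <- mean((rows - mu_r) * (cols - mu_c))
    tr <- crr + ccc; det_ <- crr * ccc - crc^2
    eig <- (tr + c(1, -1) * sqrt(max(tr^2 / 4 * 4 - 4 * det_, 0))) / 2
    eig <- sort(pmax(eig, 1 / 12), decreasing = TRUE)  # 1/12: 1-px variance
    objs[[length(objs) + 1L]] <- structure(list(
      id = length(objs) + 1L, pixels = idx, mask = m,
      area_um2 = area, perimeter_um = per,
      circularity = 4 * pi * area / per^2,
      aspect_ratio = sqrt(eig[1L] / eig[2L]),
      centroid = c(row = mu_r, col = mu_c)), class = "mito_object")
  }
  objs
}

#' Extract the long-axis polyline of an object
#'
#' Thins the object mask to a skeleton and prunes it to its single longest
#' path (two breadth-first passes), ordered end to end with an arclength
#' parameterization in um. Objects whose skeleton is shorter than 3 px are
#' flagged degenerate (`low_elongation = TRUE`).
#'
#' @param mito A `mito_object` from [segment_mitochondria()].
#' @param pixel_size_nm Pixel size in nm.
#' @return List with `rows`, `cols`, `arclength_um` (per axis point) and
#'   `low_elongation`.
#' @export
extract_axis <- function(mito, pixel_size_nm) {
  px <- pixel_size_nm / 1000
  skel <- cpp_thin(mito$mask)
  idx <- which(skel)
  ny <- nrow(skel)
  if (length(idx) < 3L) {
    rows <- (idx - 1L) %% ny + 1L; cols <- (idx - 1L) %/% ny + 1L
    return(list(rows = rows, cols = cols,
                arclength_um = seq_along(idx) * px - px,
                low_elongation = TRUE))
  }
  rows <- (idx - 1L) %% ny + 1L
  cols <- (idx - 1L) %/% ny + 1L
  key <- paste(rows, cols)
  pos <- stats::setNames(seq_along(idx), key)
  nbrs <- function(k) {
    out <- integer(0)
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      kk <- pos[paste(rows[k] + di, cols[k] + dj)]
      if (!is.na(kk)) out <- c(out, kk)
    }
    out
  }
  adj <- lapply(seq_along(idx), nbrs)
  bfs <- function(start) {
    dist <- rep(NA_real_, length(idx)); par <- rep(NA_integer_, length(idx))
    dist[start] <- 0
    q <- c(start)
    ## Dijkstra-lite on tiny graphs: axial step 1, diagonal sqrt(2)
    visited <- rep(FALSE, length(idx))
    while (length(q)) {
      u <- q[which.min(dist[q])]
      q <- setdiff(q, u)
      if (visited[u]) next
      visited[u] <- TRUE
      for (v in adj[[u]]) {
        w <- if (abs(rows[u] - rows[v]) + abs(cols[u] - cols[v]) == 2L)
          sqrt(2) else 1
        if (is.na(dist[v]) || dist[u] + w < dist[v]) {
          dist[v] <- dist[u] + w
          par[v] <- u
          q <- c(q, v)
        }
      }
    }
    list(dist = dist, par = par)
  }
  b1 <- bfs(1L)
  e1 <- which.max(b1$dist)
  b2 <- bfs(e1)
  e2 <- which.max(b2$dist)
  path <- integer(0)
  v <- e2
  while (!is.na(v)) { path <- c(v, path); v <- b2$par[v] }
  pr <- rows[path]; pc <- cols[path]
  ## canonical orientation: arclength 0 at the leftmost (then topmost) end
  n <- length(path)
  if (pc[n] < pc[1L] || (pc[n] == pc[1L] && pr[n] < pr[1L])) {
    pr <- rev(pr); pc <- rev(pc)
  }
  steps <- c(0, sqrt(diff(pr)^2 + diff(pc)^2)) * px
  list(rows = pr, cols = pc, arclength_um = cumsum(steps),
       low_elongation = length(path) < 3L ||
         max(b2$dist, na.rm = TRUE) * px < 2 * sqrt(mito$area_um2 / pi))
}
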