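## Shared fixtures: everything is generated in code at test time.

## A small, fast scenario for unit tests (not a published condition).
tiny_scenario <- function(...) {
  args <- list(name = "tiny", length_um = 4, width_um = 0.8, n_cristae = 5,
               crista_spacing_um = 0.3, n_frames = 2, rng_seed = 42L)
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(sim_scenario, args)
}

## Map detected crista rows to image columns via the analysis axis.
detected_cols <- function(res, object = 1L) {
  det <- res$detail[[object]]
  det$axis$cols[det$cristae$axis_idx]
}

## Precision/recall of detected crista columns against the truth registry,
## with a +/- tol px match window.
crista_f1 <- function(res, truth, tol = 1.5) {
  dc <- detected_cols(res)
  tc <- truth$registry$col
  tp <- sum(vapply(tc, function(x) any(abs(dc - x) <= tol), logical(1)))
  prec <- if (length(dc)) tp / length(dc) else 0
  rec <- if (length(tc)) tp / length(tc) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

## Per-class recall of the pipeline label map against simulator truth.
label_recall <- function(res, truth, classes = c("matrix", "ibm", "crista")) {
  est <- res$detail[[1L]]$classification$labels
  tru <- truth$labels
  codes <- compartment_labels()
  vapply(classes, function(cl) {
    sel <- tru == codes[[cl]]
    mean(est[sel] == codes[[cl]])
  }, numeric(1))
}

## Direct (shrink-free) rolling-ball opening written independently in R,
## used as the oracle for the fast implementation.
oracle_rolling_ball <- function(img, radius) {
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)
  ny <- nrow(img); nx <- ncol(img)
  shift <- function(m, dy, dx, fill) {
    out <- matrix(fill, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys - dy, xs - dx] <- m[ys, xs]
    out
  }
  ero <- matrix(Inf, ny, nx)
  for (k in seq_len(nrow(offs))) {
    ero <- pmin(ero, shift(img, offs$dy[k], offs$dx[k], Inf) - h[k])
  }
  dil <- matrix(-Inf, ny, nx)
  for (k in seq_len(nrow(offs))) {
    dil <- pmax(dil, shift(ero, -offs$dy[k], -offs$dx[k], -Inf) + h[k])
  }
  dil
}

## Longest path length in an 8-connected skeleton, by exhaustive BFS from
## every pixel (oracle for extract_axis on small masks).
oracle_longest_path <- function(skel) {
  idx <- which(skel)
  ny <- nrow(skel)
  rows <- (idx - 1L) %% ny + 1L
  cols <- (idx - 1L) %/% ny + 1L
  n <- length(idx)
  dmat <- matrix(Inf, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      dr <- abs(rows[a] - rows[b]); dc <- abs(cols[a] - cols[b])
      if (a != b && dr <= 1 && dc <= 1) {
        dmat[a, b] <- if (dr + dc == 2) sqrt(2) else 1
      }
    }
  }
  best <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    q <- s
    while (length(q)) {
      u <- q[which.min(dist[q])]
      q <- setdiff(q, u)
      for (v in which(is.finite(dmat[u, ]))) {
        if (dist[u] + dmat[u, v] < dist[v]) {
          dist[v] <- dist[u] + dmat[u, v]
          q <- union(q, v)
        }
      }
    }
    best <- max(best, max(dist[is.finite(dist)]))
  }
  best
}

quiet_analyze <- function(stack, config = default_config()) {
  suppressWarnings(analyze_stack(stack, config))
}
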