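#' Bilinear sub-pixel height interpolation
#'
#' Heights are defined on pixel centers at integer multiples of the pixel
#' size; any in-bounds point is interpolated bilinearly from the four
#' surrounding centers (exact at centers, exact for affine height fields).
#'
#' @param image An [afm_image()].
#' @param x,y Query coordinates in nm (vectorized).
#' @param outside `"error"` (default) to fail on out-of-bounds queries,
#'   `"na"` to return `NA` there.
#' @return Interpolated heights in nm.
#' @export
interpolate_height <- function(image, x, y, outside = c("error", "na")) {
  outside <- match.arg(outside)
  stopifnot(inherits(image, "afm_image"))
  H <- image$heights
  px <- image$pixel_size
  nr <- nrow(H); nc <- ncol(H)
  gx <- x / px
  gy <- y / px
  bad <- gx < -1e-9 | gx > nc - 1 + 1e-9 | gy < -1e-9 | gy > nr - 1 + 1e-9 |
    !is.finite(gx) | !is.finite(gy)
  if (any(bad) && outside == "error")
    stop("query point outside the image grid.", call. = FALSE)
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  j0 <- pmin(floor(gx), nc - 2)
  i0 <- pmin(floor(gy), nr - 2)
  fx <- gx - j0
  fy <- gy - i0
  i1 <- i0 + 1L; j1 <- j0 + 1L # zero-based -> 1-based row/col below
  v <- (1 - fx) * (1 - fy) * H[cbind(i0 + 1, j0 + 1)] +
    fx * (1 - fy) * H[cbind(i0 + 1, j1 + 1)] +
    (1 - fx) * fy * H[cbind(i1 + 1, j0 + 1)] +
    fx * fy * H[cbind(i1 + 1, j1 + 1)]
  v[bad] <- NA_real_
  v
}

#' Height-weighted correction direction for prediction-correction tracing
#'
#' Evaluates the correction integral `X = int Z(x(s)) x(s) ds` over a
#' segment of length `seg_length` (default 10 nm) centered on the predicted
#' point and perpendicular to the prediction direction, with position
#' vectors `x(s)` taken from `origin` (the previous accepted vertex). The
#' integral is discretized by the composite midpoint rule at a step of a
#' quarter pixel. Parts of the segment falling outside the image are
#' dropped and the result is flagged via the `"truncated"` attribute.
#'
#' @param image An [afm_image()].
#' @param origin Previous accepted vertex, length-2 numeric (nm).
#' @param predicted Predicted point, length-2 numeric (nm).
#' @param seg_length Length of the perpendicular segment, nm.
#' @return Length-2 correction vector (un-normalized), or `c(NA, NA)` if
#'   the whole segment is outside the image or carries no height.
#' @export
correction_direction <- function(image, origin, predicted, seg_length = 10) {
  u <- unit2(predicted - origin)
  nrm <- c(-u[2], u[1])
  ds <- image$pixel_size / 4
  nq <- max(2L, ceiling(seg_length / ds))
  ds <- seg_length / nq
  s <- -seg_length / 2 + (seq_len(nq) - 0.5) * ds
  qx <- predicted[1] + s * nrm[1]
  qy <- predicted[2] + s * nrm[2]
  z <- interpolate_height(image, qx, qy, outside = "na")
  ok <- !is.na(z)
  if (!any(ok)) return(structure(c(NA_real_, NA_real_), truncated = TRUE))
  X <- c(sum(z[ok] * (qx[ok] - origin[1])) * ds,
         sum(z[ok] * (qy[ok] - origin[2])) * ds)
  structure(X, truncated = !all(ok))
}

#' Trace a molecule through a height image
#'
#' Iterative prediction-correction contour tracing: starting from two seed
#' points at a chain end, each step predicts forward along the previous
#' link, corrects the direction three times with
#' [correction_direction()], then makes the final step with exactly the
#' required link length. Tracing terminates cleanly when the ridge is lost
#' (interpolated height at the next vertex falls below `height_frac` times
#' the running median vertex height), when the correction segment leaves
#' the image, or when the direction reverses.
#'
#' @param image An [afm_image()].
#' @param seeds Two seed points: a 2x2 matrix or data frame with columns
#'   `x_nm`, `y_nm`, ordered along the intended direction, separated by
#'   about `l0`.
#' @param l0 Link length, nm. Every produced link has chord length exactly
#'   `l0`.
#' @param height_frac Ridge-loss threshold as a fraction of the running
#'   median vertex height.
#' @param seg_length Correction segment length, nm.
#' @param max_vertices Safety cap.
#' @param molecule_id,image_ref Identifiers stored in the output.
#' @return A trace tibble (contour dialect, `source = "traced"`) with
#'   attributes `image_ref` and `flagged` (indices of vertices whose
#'   correction segment was truncated at the image boundary).
#' @export
trace_molecule <- function(image, seeds, l0, height_frac = 0.25,
                           seg_length = 10, max_vertices = 100000L,
                           molecule_id = 1L, image_ref = NA_character_) {
  if (is.data.frame(seeds)) seeds <- cbind(seeds$x_nm, seeds$y_nm)
  stopifnot(is.matrix(seeds), nrow(seeds) == 2, ncol(seeds) == 2, l0 > 0)
  v <- seeds[1, ]
  d <- unit2(seeds[2, ] - seeds[1, ])
  verts <- list(v)
  hs <- interpolate_height(image, v[1], v[2], outside = "na")
  flagged <- integer(0)
  repeat {
    if (length(verts) >= max_vertices) break
    d_it <- d
    X <- NULL
    failed <- FALSE
    for (it in 1:3) {
      p <- v + l0 * d_it
      X <- correction_direction(image, v, p, seg_length)
      if (any(is.na(X)) || sqrt(sum(X^2)) < 1e-300) {
        failed <- TRUE
        break
      }
      d_it <- unit2(X)
    }
    if (failed) break
    if (sum(d_it * d) <= 0) break # direction reversal: off the ridge end
    v_next <- v + l0 * d_it
    h_next <- interpolate_height(image, v_next[1], v_next[2],
                                 outside = "na")
    if (is.na(h_next)) break
    if (length(hs) >= 3 &&
        h_next < height_frac * stats::median(hs, na.rm = TRUE)) break
    verts[[length(verts) + 1]] <- v_next
    if (isTRUE(attr(X, "truncated")))
      flagged <- c(flagged, length(verts))
    hs <- c(hs, h_next)
    v <- v_next
    d <- d_it
  }
  P <- do.call(rbind, verts)
  out <- tibble::tibble(molecule_id = as.integer(molecule_id),
                        vertex_index = seq_len(nrow(P)),
                        x_nm = P[, 1], y_nm = P[, 2])
  out <- set_contour_meta(out, source = "traced", l0_nm = l0, link_nm = l0)
  attr(out, "image_ref") <- image_ref
  attr(out, "flagged") <- flagged
  out
}

# find the sub-pixel height maximum along perpendiculars at sample points;
# pts/dirs: n x 2 matrices; returns n x 2 matrix of refined points (NA rows
# where no in-image maximum exists). A coarse half-pixel search locates the
# peak; a quadratic fit to log heights at five pixel-spaced samples then
# localizes the crest (exact for a Gaussian ridge cross-section, and robust
# to the pixel-center bias of maximizing a bilinear surface directly).
perp_height_maxima <- function(image, pts, dirs, seg_length = 10) {
  px <- image$pixel_size
  off <- seq(-seg_length / 2, seg_length / 2, by = px / 2)
  no <- length(off)
  n <- nrow(pts)
  nx <- -dirs[, 2]
  ny <- dirs[, 1]
  interp_off <- function(omat) {
    qx <- matrix(pts[, 1], n, ncol(omat)) + omat * nx
    qy <- matrix(pts[, 2], n, ncol(omat)) + omat * ny
    matrix(interpolate_height(image, as.vector(qx), as.vector(qy),
                              outside = "na"), n, ncol(omat))
  }
  z <- interp_off(matrix(off, n, no, byrow = TRUE))
  z[is.na(z)] <- -Inf
  best <- max.col(z, ties.method = "first")
  o0 <- off[best]
  z0 <- z[cbind(seq_len(n), best)]
  # five samples at pixel spacing centered on the coarse peak
  h <- px
  omat <- outer(o0, rep(1, 5)) +
    matrix(c(-2, -1, 0, 1, 2) * h, n, 5, byrow = TRUE)
  zf <- interp_off(omat)
  ok <- is.finite(z0) & z0 > 0 &
    apply(is.finite(zf) & zf > 0.05 * z0, 1, all)
  o <- o0
  if (any(ok)) {
    ly <- log(pmax(zf[ok, , drop = FALSE], 1e-12))
    b <- (-2 * ly[, 1] - ly[, 2] + ly[, 4] + 2 * ly[, 5]) / (10 * h)
    cc <- (2 * ly[, 1] - ly[, 2] - 2 * ly[, 3] - ly[, 4] + 2 * ly[, 5]) /
      (14 * h^2)
    vert <- -b / (2 * cc)
    good <- is.finite(vert) & cc < 0 & abs(vert) <= 2 * h
    idx <- which(ok)[good]
    o[idx] <- o0[which(ok)[good]] + vert[good]
  }
  res <- cbind(pts[, 1] + nx * o, pts[, 2] + ny * o)
  res[!is.finite(z0), ] <- NA_real_
  res
}

# iteratively delete points whose interior turning exceeds 90 degrees
# (worst vertex per sweep, to fixpoint)
prune_acute <- function(P) {
  repeat {
    n <- nrow(P)
    if (n < 3) return(P)
    a <- P[-c(n - 1, n), , drop = FALSE]
    b <- P[-c(1, n), , drop = FALSE]
    c <- P[-c(1, 2), , drop = FALSE]
    u <- b - a
    v <- c - b
    dots <- rowSums(u * v)
    norms <- sqrt(rowSums(u^2) * rowSums(v^2))
    cosang <- dots / pmax(norms, 1e-300)
    if (all(cosang >= 0)) return(P)
    worst <- which.min(cosang) + 1L
    P <- P[-worst, , drop = FALSE]
  }
}

#' Refine a trace onto the ridge centerline
#'
#' The post-tracing refinement step: (1) sample the trace polyline at
#' half-pixel intervals; (2) at each sample, locate the height maximum
#' along a perpendicular segment by sub-pixel search (grid of a tenth of a
#' pixel plus parabolic refinement); (3) iteratively remove points that
#' produce acute angles (interior turning beyond 90 degrees), which arise
#' in strongly bent regions where the perpendicular search jumps ahead or
#' behind; (4) re-step along the pruned broken line with exact chord `l0`.
#' Rounds repeat until the maximum vertex displacement drops below
#' `tol_px` pixels or `max_rounds` is reached.
#'
#' @param image An [afm_image()].
#' @param trace A trace tibble from [trace_molecule()] (single molecule).
#' @param l0 Link length for the refined trace; defaults to the input
#'   trace's.
#' @param seg_length Perpendicular search segment length, nm (the
#'   correction segment length is reused).
#' @param max_rounds,tol_px Convergence controls.
#' @return A refined trace tibble (`source = "traced"`, attribute
#'   `refined = TRUE`).
#' @export
refine_trace <- function(image, trace, l0 = NULL, seg_length = 10,
                         max_rounds = 10L, tol_px = 0.05) {
  meta <- contour_meta(trace)
  if (is.null(l0)) l0 <- meta$l0_nm
  stopifnot(is.finite(l0), l0 > 0)
  P <- cbind(trace$x_nm, trace$y_nm)
  if (nrow(P) < 3) stop("trace too short to refine (< 2 links).",
                        call. = FALSE)
  px <- image$pixel_size
  for (round in seq_len(max_rounds)) {
    samp <- arc_sample_polyline(P, px / 2)
    ref <- perp_height_maxima(image, samp$points, samp$dirs, seg_length)
    keep <- stats::complete.cases(ref)
    ref <- ref[keep, , drop = FALSE]
    if (nrow(ref) < 2) stop("refinement lost the ridge.", call. = FALSE)
    pruned <- prune_acute(ref)
    Pn <- restep_polyline(pruned, l0)
    if (nrow(Pn) < 2) stop("refined trace degenerate.", call. = FALSE)
    disp <- max(dist_to_polyline(Pn, P)$dist)
    P <- Pn
    if (disp < tol_px * px) break
  }
  out <- tibble::tibble(molecule_id = trace$molecule_id[1],
                        vertex_index = seq_len(nrow(P)),
                        x_nm = P[, 1], y_nm = P[, 2])
  out <- set_contour_meta(out, source = "traced", l0_nm = l0, link_nm = l0)
  attr(out, "image_ref") <- attr(trace, "image_ref")
  attr(out, "refined") <- TRUE
  out
}

#' Cross-trace spread of a bundle of traces
#'
#' A bundle is a set of traces of the same molecule obtained from
#' different seed points and directions; its lateral spread measures
#' tracing reproducibility. The first trace serves as the arc-length
#' reference: at matched arc-length stations along it, every other trace
#' contributes its nearest polyline point, and the station reports the
#' standard deviation of the signed lateral offsets and the maximum
#' pairwise distance. Stations where some trace has no interior nearest
#' point (non-overlapping arc range) are dropped.
#'
#' @param traces Tibble of traces with a `trace_id` column (plus the
#'   contour columns).
#' @param n_stations Number of arc-length stations.
#' @return Tibble with `station`, `s_nm`, `sd_nm`, `max_pairwise_nm`.
#' @export
bundle_spread <- function(traces, n_stations = 100L) {
  stopifnot("trace_id" %in% names(traces))
  ids <- unique(traces$trace_id)
  if (length(ids) < 2) stop("a bundle needs at least two traces.",
                            call. = FALSE)
  polys <- lapply(ids, function(id) {
    d <- dplyr::arrange(traces[traces$trace_id == id, ], .data$vertex_index)
    cbind(d$x_nm, d$y_nm)
  })
  ref <- polys[[1]]
  total <- sum(sqrt(rowSums(diff(ref)^2)))
  samp <- arc_sample_polyline(ref, max(total / (n_stations - 1), 1e-9))
  st <- samp$points
  nrm <- cbind(-samp$dirs[, 2], samp$dirs[, 1])
  ns <- nrow(st)
  offs <- matrix(0, ns, length(ids))
  pts_x <- matrix(st[, 1], ns, length(ids))
  pts_y <- matrix(st[, 2], ns, length(ids))
  edge <- matrix(FALSE, ns, length(ids))
  for (k in seq_along(ids)[-1]) {
    dp <- dist_to_polyline(st, polys[[k]])
    offs[, k] <- (dp$nearest[, 1] - st[, 1]) * nrm[, 1] +
      (dp$nearest[, 2] - st[, 2]) * nrm[, 2]
    pts_x[, k] <- dp$nearest[, 1]
    pts_y[, k] <- dp$nearest[, 2]
    # endpoint-clamped matches indicate no overlap at this station
    p0 <- polys[[k]][1, ]
    p1 <- polys[[k]][nrow(polys[[k]]), ]
    at_end <- (abs(dp$nearest[, 1] - p0[1]) < 1e-9 &
                 abs(dp$nearest[, 2] - p0[2]) < 1e-9) |
      (abs(dp$nearest[, 1] - p1[1]) < 1e-9 &
         abs(dp$nearest[, 2] - p1[2]) < 1e-9)
    edge[, k] <- at_end
  }
  ok <- !apply(edge, 1, any)
  maxpair <- vapply(seq_len(ns), function(i) {
    pts <- cbind(pts_x[i, ], pts_y[i, ])
    max(stats::dist(pts))
  }, numeric(1))
  tibble::tibble(
    station = seq_len(ns),
    s_nm = samp$s,
    sd_nm = apply(offs, 1, stats::sd),
    max_pairwise_nm = maxpair
  )[ok, ]
}
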