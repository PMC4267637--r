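#' AFM height image container
#'
#' A rectangular grid of heights (nm). Pixel centers sit at integer
#' multiples of `pixel_size`: `heights[i, j]` is the height at physical
#' coordinates `x = (j - 1) * pixel_size`, `y = (i - 1) * pixel_size`.
#'
#' @param heights Numeric matrix of heights in nm (finite).
#' @param pixel_size Grid spacing in nm (> 0).
#' @return An object of class `afm_image`.
#' @export
afm_image <- function(heights, pixel_size) {
  stopifnot(is.matrix(heights), is.numeric(heights),
            all(is.finite(heights)),
            is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0)
  structure(list(heights = heights, pixel_size = pixel_size),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("<afm_image> %d x %d px, %.3g nm/px, heights %.3g..%.3g nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Rendering parameters for virtual AFM images
#'
#' @param ridge_height Apparent height of the DNA ridge, nm.
#' @param ridge_sigma Gaussian cross-section width of the tip-broadened
#'   ridge, nm. The default 2.5 nm gives an apparent full width at half
#'   maximum of ~6 nm, well above the 2 nm physical diameter of the double
#'   helix, as in tip-convolved scans.
#' @param undulation_amplitude Amplitude of the helical centerline
#'   undulation, nm, at most 1 (half the 2 nm enveloping cylinder).
#' @param undulation_period Period of the undulation along the contour, nm;
#'   default 3.5 (one helical turn).
#' @param noise_sigma Standard deviation of additive background height
#'   noise, nm.
#' @return An object of class `render_params`.
#' @export
render_params <- function(ridge_height = 1.5, ridge_sigma = 2.5,
                          undulation_amplitude = 1,
                          undulation_period = 3.5, noise_sigma = 0.1) {
  stopifnot(ridge_height >= 0, ridge_sigma > 0,
            undulation_amplitude >= 0, undulation_amplitude <= 1,
            undulation_period > 0, noise_sigma >= 0)
  structure(list(ridge_height = ridge_height, ridge_sigma = ridge_sigma,
                 undulation_amplitude = undulation_amplitude,
                 undulation_period = undulation_period,
                 noise_sigma = noise_sigma),
            class = "render_params")
}

#' Offset a centerline by a helical undulation
#'
#' Emulates the wavy line followed by the height maxima of a scanned
#' double helix: each vertex is displaced perpendicular to the local
#' tangent by `amplitude * sin(2*pi*s/period + phase)` where `s` is the
#' arc length from the chain start. Offsets are bounded by `amplitude`,
#' which may not exceed 1 nm (half the enveloping cylinder).
#'
#' @param contour Contour tibble (dense bead chains give a well-resolved
#'   wave).
#' @param amplitude Undulation amplitude, nm (0..1).
#' @param period Undulation period along the contour, nm (> 0).
#' @param phase Phase offset in radians.
#' @return A contour tibble with the same metadata.
#' @export
undulate_centerline <- function(contour, amplitude, period = 3.5,
                                phase = 0) {
  stopifnot(amplitude >= 0, amplitude <= 1)
  if (period <= 0) stop("`period` must be positive.", call. = FALSE)
  meta <- contour_meta(contour)
  if (amplitude == 0) return(contour)
  mats <- contour_split(contour)
  out <- contour_bind(lapply(mats, function(p) {
    n <- nrow(p)
    seg <- diff(p)
    len <- sqrt(rowSums(seg^2))
    s <- c(0, cumsum(len))
    # per-vertex tangent: mean of adjacent segment directions
    tx <- c(seg[1, 1], (seg[-nrow(seg), 1] + seg[-1, 1]) / 2, seg[nrow(seg), 1])
    ty <- c(seg[1, 2], (seg[-nrow(seg), 2] + seg[-1, 2]) / 2, seg[nrow(seg), 2])
    tn <- sqrt(tx^2 + ty^2)
    nx <- -ty / tn
    ny <- tx / tn
    off <- amplitude * sin(2 * pi * s / period + phase)
    p + cbind(nx * off, ny * off)
  }))
  set_contour_meta(out, source = meta$source, step_nm = meta$step_nm,
                   stride = meta$stride, l0_nm = meta$l0_nm,
                   link_nm = meta$link_nm)
}

# min squared distance from each pixel center in a window to one segment,
# folded into the running matrix d2 (squared distances)
update_min_dist2 <- function(d2, a, b, px, reach) {
  nr <- nrow(d2); nc <- ncol(d2)
  xlo <- min(a[1], b[1]) - reach; xhi <- max(a[1], b[1]) + reach
  ylo <- min(a[2], b[2]) - reach; yhi <- max(a[2], b[2]) + reach
  j0 <- max(1L, floor(xlo / px) + 1L); j1 <- min(nc, ceiling(xhi / px) + 1L)
  i0 <- max(1L, floor(ylo / px) + 1L); i1 <- min(nr, ceiling(yhi / px) + 1L)
  if (j0 > j1 || i0 > i1) return(d2)
  xs <- (seq(j0, j1) - 1) * px
  ys <- (seq(i0, i1) - 1) * px
  ab <- b - a
  len2 <- sum(ab^2)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  if (len2 < 1e-24) {
    dd <- (X - a[1])^2 + (Y - a[2])^2
  } else {
    t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2
    t[t < 0] <- 0; t[t > 1] <- 1
    dd <- (X - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2
  }
  sub <- d2[i0:i1, j0:j1]
  d2[i0:i1, j0:j1] <- pmin(sub, dd)
  d2
}

#' Render a contour into a virtual AFM height image
#'
#' The noiseless height at a pixel is
#' `ridge_height * exp(-d^2 / (2 * ridge_sigma^2))` where `d` is the
#' distance from the pixel center to the contour polyline (true polyline
#' distance, not per-vertex splats, so bead spacing leaves no artifacts).
#' Zero-mean Gaussian background noise with sd `noise_sigma` is added.
#' Images are zero-baseline, i.e. already flattened.
#'
#' Undulation is not applied here; pass the contour through
#' [undulate_centerline()] first if wanted.
#'
#' @param contour Contour tibble; all vertices must fit in the canvas with
#'   a margin of at least `3 * ridge_sigma`.
#' @param params A [render_params()].
#' @param pixel_size Grid spacing in nm.
#' @param n_row,n_col Canvas size in pixels; computed from the contour
#'   extent plus margin when `NULL`.
#' @return An [afm_image()].
#' @export
render_image <- function(contour, params, pixel_size, n_row = NULL,
                         n_col = NULL) {
  stopifnot(inherits(params, "render_params"), pixel_size > 0)
  mats <- contour_split(contour)
  all_xy <- do.call(rbind, mats)
  margin <- 3 * params$ridge_sigma
  if (nrow(all_xy) > 0 && (min(all_xy) < margin - 1e-9))
    stop("contour too close to the canvas origin: translate it so all ",
         "coordinates are >= 3 * ridge_sigma.", call. = FALSE)
  if (is.null(n_col)) n_col <- ceiling((max(all_xy[, 1]) + margin) / pixel_size) + 1
  if (is.null(n_row)) n_row <- ceiling((max(all_xy[, 2]) + margin) / pixel_size) + 1
  if (max(all_xy[, 1]) > (n_col - 1) * pixel_size - margin + 1e-9 ||
      max(all_xy[, 2]) > (n_row - 1) * pixel_size - margin + 1e-9)
    stop("contour does not fit inside the requested canvas with a ",
         "3 * ridge_sigma margin.", call. = FALSE)
  d2 <- matrix(Inf, n_row, n_col)
  reach <- 3.5 * params$ridge_sigma
  for (p in mats) {
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      d2 <- update_min_dist2(d2, p[i, ], p[i + 1, ], pixel_size, reach)
    }
  }
  h <- params$ridge_height * exp(-d2 / (2 * params$ridge_sigma^2))
  h[!is.finite(h)] <- 0
  if (params$noise_sigma > 0)
    h <- h + matrix(stats::rnorm(n_row * n_col, 0, params$noise_sigma),
                    n_row, n_col)
  afm_image(h, pixel_size)
}

#' Write a height image as TIFF plus JSON sidecar
#'
#' Heights are stored in a 32-bit TIFF normalized by `height_scale_nm`
#' (recorded in the sidecar) because TIFF samples must lie in `[0, 1]`;
#' [read_afm_image()] restores nm units. The sidecar also records
#' `pixel_size_nm` and any extra metadata supplied.
#'
#' @param image An [afm_image()].
#' @param path Output TIFF path; the sidecar is `path` with `.json`
#'   appended.
#' @param meta Optional named list of extra metadata (seed, render
#'   parameters, ...).
#' @return `path`, invisibly.
#' @export
write_afm_image <- function(image, path, meta = list()) {
  stopifnot(inherits(image, "afm_image"))
  h <- image$heights
  lo <- min(h, 0)
  scale <- max(h - lo, 1e-12)
  tiff::writeTIFF((h - lo) / scale, path, bits.per.sample = 32L)
  sidecar <- c(list(pixel_size_nm = image$pixel_size,
                    height_scale_nm = scale, height_offset_nm = lo), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a height image written by [write_afm_image()]
#'
#' Also accepts real flattened scans exported in the same TIFF + JSON
#' convention.
#'
#' @param path TIFF path (sidecar expected at `path` + `.json`).
#' @return An [afm_image()]; extra sidecar fields are attached as the
#'   `meta` attribute.
#' @export
read_afm_image <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h <- tiff::readTIFF(path)
  if (length(dim(h)) == 3) h <- h[, , 1]
  h <- h * side$height_scale_nm + (side$height_offset_nm %||% 0)
  img <- afm_image(h, side$pixel_size_nm)
  attr(img, "meta") <- side
  img
}

# reject chains whose distant stretches come closer than min_sep (proxy for
# self-crossing / near-crossing, which the default fixtures exclude)
chain_self_approaches <- function(p, min_sep = 5, decimate = 10) {
  idx <- seq(1, nrow(p), by = decimate)
  q <- p[idx, , drop = FALSE]
  n <- nrow(q)
  if (n < 6) return(FALSE)
  d <- as.matrix(stats::dist(q))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  guard <- ceiling(3 * min_sep / (decimate * 0.34))
  any(d[sep > guard] < min_sep)
}

#' Generate a reproducible set of virtual AFM images with ground truth
#'
#' Samples chains from `model`, optionally rejects self-approaching
#' (crossing-like) conformations, applies a random-phase helical
#' undulation, translates each molecule onto its own canvas, and renders a
#' height image. Every image is paired with the exact generating chain (in
#' image coordinates) for oracle-based scoring of the tracer.
#'
#' @param n_molecules Number of molecules (one per image).
#' @param model An [energy_model()].
#' @param n_beads Beads per chain.
#' @param step Bead step, nm.
#' @param pixel_size Grid spacing, nm (1.95 and 3.9 are the scan settings
#'   emulated).
#' @param params A [render_params()]; its undulation fields drive
#'   [undulate_centerline()].
#' @param allow_crossing Keep self-approaching chains instead of redrawing.
#' @param max_tries Redraw budget per molecule.
#' @return List with `images` (list of [afm_image()]) and `chains`
#'   (ground-truth chain tibble in image coordinates, one molecule per
#'   image).
#' @export
make_fixture_set <- function(n_molecules, model, n_beads, step = 0.34,
                             pixel_size = 1.95, params = render_params(),
                             allow_crossing = FALSE, max_tries = 50) {
  margin <- 3 * params$ridge_sigma + 2 * pixel_size
  images <- vector("list", n_molecules)
  chains <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    for (try in seq_len(max_tries)) {
      ch <- sample_chain(model, n_beads, step, molecule_id = i)
      p <- cbind(ch$x_nm, ch$y_nm)
      if (allow_crossing || !chain_self_approaches(p)) break
      if (try == max_tries)
        stop("could not draw a non-crossing chain; increase `max_tries` ",
             "or set `allow_crossing = TRUE`.", call. = FALSE)
    }
    ch$x_nm <- ch$x_nm - min(ch$x_nm) + margin
    ch$y_nm <- ch$y_nm - min(ch$y_nm) + margin
    und <- undulate_centerline(ch, params$undulation_amplitude,
                               params$undulation_period,
                               phase = stats::runif(1, 0, 2 * pi))
    images[[i]] <- render_image(und, params, pixel_size)
    chains[[i]] <- ch
  }
  chains <- dplyr::bind_rows(chains)
  chains <- set_contour_meta(chains, source = "chain", step_nm = step,
                             stride = 1, l0_nm = step, link_nm = step)
  list(images = images, chains = chains)
}
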