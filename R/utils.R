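#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

# wrap angles to (-pi, pi]
wrap_angle <- function(a) atan2(sin(a), cos(a))

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("zero-length direction vector.", call. = FALSE)
  v / n
}

# min distance from each query point (n x 2) to a polyline (m x 2);
# returns list(dist, nearest) with nearest points on the polyline
dist_to_polyline <- function(points, poly) {
  stopifnot(nrow(poly) >= 2)
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  n <- nrow(points)
  best <- rep(Inf, n)
  nearest <- matrix(0, n, 2)
  for (s in seq_len(nrow(a))) {
    t <- ((points[, 1] - a[s, 1]) * ab[s, 1] +
          (points[, 2] - a[s, 2]) * ab[s, 2]) / len2[s]
    t <- pmin(pmax(t, 0), 1)
    cx <- a[s, 1] + t * ab[s, 1]
    cy <- a[s, 2] + t * ab[s, 2]
    d2 <- (points[, 1] - cx)^2 + (points[, 2] - cy)^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    nearest[upd, 1] <- cx[upd]
    nearest[upd, 2] <- cy[upd]
  }
  list(dist = sqrt(best), nearest = nearest)
}

# resample a polyline at fixed arc-length spacing (includes both endpoints)
arc_sample_polyline <- function(poly, spacing) {
  seg <- diff(poly)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 1e-12
  if (!all(keep)) {
    poly <- poly[c(TRUE, keep), , drop = FALSE]
    seg <- diff(poly)
    len <- sqrt(rowSums(seg^2))
  }
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- unique(c(seq(0, total, by = spacing), total))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(poly) - 1)
  t <- (s - cum[idx]) / len[idx]
  pts <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
  dirs <- seg[idx, , drop = FALSE] / len[idx]
  list(points = pts, dirs = dirs, s = s, total = total)
}

# walk along a polyline placing vertices at exact chord distance l0
restep_polyline <- function(poly, l0) {
  stopifnot(nrow(poly) >= 2, l0 > 0)
  out <- list(poly[1, ])
  c0 <- poly[1, ]
  seg_i <- 1L
  seg_t <- 0
  nseg <- nrow(poly) - 1
  repeat {
    found <- FALSE
    i <- seg_i
    while (i <= nseg) {
      a <- poly[i, ]
      b <- poly[i + 1, ]
      ab <- b - a
      t_lo <- if (i == seg_i) seg_t else 0
      # solve |a + t*ab - c0|^2 = l0^2 for t in (t_lo, 1]
      A <- sum(ab^2)
      Bq <- 2 * sum(ab * (a - c0))
      Cq <- sum((a - c0)^2) - l0^2
      disc <- Bq^2 - 4 * A * Cq
      if (A > 1e-300 && disc >= 0) {
        r <- sqrt(disc)
        for (t in sort(c((-Bq - r) / (2 * A), (-Bq + r) / (2 * A)))) {
          if (t > t_lo + 1e-12 && t <= 1 + 1e-12) {
            t <- min(t, 1)
            c0 <- a + t * ab
            out[[length(out) + 1]] <- c0
            seg_i <- i
            seg_t <- t
            found <- TRUE
            break
          }
        }
      }
      if (found) break
      i <- i + 1L
    }
    if (!found) break
  }
  do.call(rbind, out)
}
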