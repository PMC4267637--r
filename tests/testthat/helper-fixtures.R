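# Shared synthetic scenes. Everything is generated in code; no stored data.

noiseless_params <- function(...) {
  render_params(undulation_amplitude = 0, noise_sigma = 0, ...)
}

# straight horizontal ridge at an off-grid height y0
straight_ridge <- function(y0 = 40.3, x_from = 10, x_to = 180, px = 1.95,
                           params = noiseless_params()) {
  co <- tibble::tibble(molecule_id = 1L, vertex_index = 1:2,
                       x_nm = c(x_from, x_to), y_nm = y0)
  co <- set_contour_meta(co, "chain", step_nm = x_to - x_from, stride = 1,
                         l0_nm = x_to - x_from, link_nm = x_to - x_from)
  list(image = render_image(co, params, px), y0 = y0,
       x_range = c(x_from, x_to), px = px)
}

# circular arc ridge of radius R
arc_ridge <- function(R = 50, center = c(70, 70), span = 4 * pi / 3,
                      px = 1.95, params = noiseless_params()) {
  th <- seq(0, span, length.out = ceiling(span * R / 0.34))
  co <- tibble::tibble(molecule_id = 1L, vertex_index = seq_along(th),
                       x_nm = center[1] + R * cos(th),
                       y_nm = center[2] + R * sin(th))
  co <- set_contour_meta(co, "chain", step_nm = 0.34, stride = 1,
                         l0_nm = 0.34, link_nm = 0.34)
  list(image = render_image(co, params, px), R = R, center = center,
       span = span, px = px)
}

# a straight per-bp chain along +x (deterministic)
straight_chain <- function(n_beads = 100, step = 0.34) {
  df <- tibble::tibble(molecule_id = 1L, vertex_index = seq_len(n_beads),
                       x_nm = step * (seq_len(n_beads) - 1), y_nm = 0)
  set_contour_meta(df, "chain", step_nm = step, stride = 1, l0_nm = step,
                   link_nm = step)
}

# contour from explicit coordinates, tagged as a resampled contour
manual_contour <- function(x, y, l0 = NA_real_, source = "mc_resampled",
                           stride = NA_real_, step_nm = NA_real_) {
  df <- tibble::tibble(molecule_id = 1L, vertex_index = seq_along(x),
                       x_nm = x, y_nm = y)
  set_contour_meta(df, source, step_nm = step_nm, stride = stride,
                   l0_nm = l0, link_nm = l0)
}

# an angle sample with explicit metadata (tangent angles, no chord bias)
manual_angles <- function(theta, L_nm, molecule_id = NULL, s = 1L) {
  if (is.null(molecule_id)) molecule_id <- rep(1L, length(theta))
  out <- tibble::tibble(molecule_id = molecule_id, theta = theta)
  attr(out, "separation_links") <- s
  attr(out, "L_nm") <- L_nm
  attr(out, "angle_kind") <- "exact"
  attr(out, "stride") <- NA_real_
  attr(out, "step_nm") <- NA_real_
  class(out) <- c("wlc_angles", class(out))
  out
}
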