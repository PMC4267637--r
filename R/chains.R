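#' Sample a planar discrete chain from a bending energy model
#'
#' Builds a phantom (no excluded volume) planar chain by cumulative turning
#' of a unit tangent: bend angles between successive segments are drawn
#' i.i.d. from the Boltzmann distribution of `model`, and beads are placed
#' at fixed steps along the running tangent. One bead per base pair
#' (`step = 0.34` nm) reproduces the base-pair-resolution discrete model.
#'
#' @param model An [energy_model()].
#' @param n_beads Number of beads (>= 2).
#' @param step Bead step in nm.
#' @param molecule_id Integer id stored in the output.
#' @param initial_angle Direction of the first segment in radians; `NULL`
#'   (default) draws it uniformly.
#' @return A chain tibble (columns `molecule_id`, `vertex_index`, `x_nm`,
#'   `y_nm`) with contour metadata `source = "chain"`.
#' @examples
#' set.seed(1)
#' ch <- sample_chain(energy_model("harmonic", lb = 56), n_beads = 100)
#' @export
sample_chain <- function(model, n_beads, step = 0.34, molecule_id = 1L,
                         initial_angle = NULL) {
  stopifnot(n_beads >= 2, step > 0)
  n_beads <- as.integer(n_beads)
  phi0 <- if (is.null(initial_angle)) stats::runif(1, 0, 2 * pi)
          else initial_angle
  bends <- if (n_beads > 2) sample_bend_angles(model, step, n_beads - 2)
           else numeric(0)
  phi <- cumsum(c(phi0, bends))
  x <- cumsum(c(0, step * cos(phi)))
  y <- cumsum(c(0, step * sin(phi)))
  df <- tibble::tibble(
    molecule_id = as.integer(molecule_id),
    vertex_index = seq_len(n_beads),
    x_nm = x, y_nm = y
  )
  set_contour_meta(df, source = "chain", step_nm = step, stride = 1,
                   l0_nm = step, link_nm = step)
}

#' Sample an ensemble of planar chains
#'
#' @inheritParams sample_chain
#' @param n_chains Number of molecules.
#' @return A chain tibble with `n_chains` molecules.
#' @export
sample_chains <- function(model, n_chains, n_beads, step = 0.34) {
  stopifnot(n_chains >= 1)
  out <- purrr::map_dfr(seq_len(n_chains), function(i) {
    sample_chain(model, n_beads, step, molecule_id = i)
  })
  set_contour_meta(out, source = "chain", step_nm = step, stride = 1,
                   l0_nm = step, link_nm = step)
}

#' Resample a bead chain with a fixed index stride
#'
#' Emulates digitized AFM contours: keeps every m-th bead of a
#' base-pair-resolution chain, `m = round(l0 / step)`, dropping the trailing
#' remainder. Vertices therefore coincide exactly with beads of the input
#' chain, and the contour stride along the chain is constant (`m * step` of
#' contour length per link).
#'
#' @param chain A chain tibble (see [sample_chain()]).
#' @param l0 Nominal link length in nm; must be >= the bead step.
#' @return A contour tibble with `source = "mc_resampled"`.
#' @examples
#' set.seed(1)
#' ch <- sample_chain(energy_model("harmonic", lb = 56), 4363)
#' co <- resample_with_stride(ch, 7)
#' @export
resample_with_stride <- function(chain, l0) {
  meta <- contour_meta(chain)
  step <- meta$step_nm
  if (!is.finite(step)) stop("input chain carries no bead step metadata.",
                             call. = FALSE)
  if (l0 < step) stop("`l0` must be >= the bead step.", call. = FALSE)
  m <- round(l0 / step)
  mats <- contour_split(chain)
  out <- contour_bind(lapply(mats, function(p) {
    p[seq(1, nrow(p), by = m), , drop = FALSE]
  }))
  set_contour_meta(out, source = "mc_resampled", step_nm = step, stride = m,
                   l0_nm = l0, link_nm = m * step)
}

#' Displace contour vertices along interior-angle bisectors
#'
#' Models the irreducible centerline localization noise set by the physical
#' width of the double helix: every interior vertex is shifted along the
#' bisector of the angle between its two adjacent links by a signed
#' magnitude drawn uniformly on `[-amplitude/2, +amplitude/2]`. Endpoints,
#' whose bisector is undefined, are shifted along the perpendicular to
#' their single link (they carry no bend angle anyway). Vertex order is
#' preserved.
#'
#' @param contour A contour tibble.
#' @param amplitude Full shift amplitude in nm (shift range is half of it
#'   each way); must be >= 0.
#' @return A contour tibble with `source = "noisy"`.
#' @export
apply_bisector_noise <- function(contour, amplitude) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    stop("`amplitude` must be a single non-negative number.", call. = FALSE)
  meta <- contour_meta(contour)
  if (amplitude == 0) {
    return(set_contour_meta(contour, source = "noisy",
                            step_nm = meta$step_nm, stride = meta$stride,
                            l0_nm = meta$l0_nm, link_nm = meta$link_nm))
  }
  mats <- contour_split(contour)
  out <- contour_bind(lapply(mats, function(p) {
    n <- nrow(p)
    dirs <- matrix(0, n, 2)
    if (n >= 3) {
      prev <- p[1:(n - 2), , drop = FALSE] - p[2:(n - 1), , drop = FALSE]
      nxt <- p[3:n, , drop = FALSE] - p[2:(n - 1), , drop = FALSE]
      prev <- prev / sqrt(rowSums(prev^2))
      nxt <- nxt / sqrt(rowSums(nxt^2))
      bis <- prev + nxt
      nb <- sqrt(rowSums(bis^2))
      straight <- nb < 1e-9
      # straight vertex: bisector degenerates; use link perpendicular
      bis[straight, ] <- cbind(-nxt[straight, 2], nxt[straight, 1])
      nb[straight] <- 1
      dirs[2:(n - 1), ] <- bis / nb
    }
    d1 <- p[2, ] - p[1, ]
    dn <- p[n, ] - p[n - 1, ]
    dirs[1, ] <- c(-d1[2], d1[1]) / sqrt(sum(d1^2))
    dirs[n, ] <- c(-dn[2], dn[1]) / sqrt(sum(dn^2))
    shift <- stats::runif(n, -amplitude / 2, amplitude / 2)
    p + dirs * shift
  }))
  set_contour_meta(out, source = "noisy", step_nm = meta$step_nm,
                   stride = meta$stride, l0_nm = meta$l0_nm,
                   link_nm = meta$link_nm)
}
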