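#' Bending energy models for a discrete planar DNA chain
#'
#' Constructs the per-segment bending energy model used by the chain
#' samplers. Two kinds are supported:
#'
#' * `"harmonic"` -- the worm-like chain (WLC): `E(theta) = kT * lb *
#'   theta^2 / (2 * step)`, so that the equilibrium bend-angle variance of a
#'   segment of length `step` is `step / lb` (planar convention).
#' * `"lsec"` -- the linear sub-elastic chain, a kinkable potential that is
#'   harmonic (`q * theta^2`) below a small flex angle `theta0` and grows
#'   essentially linearly (concave) beyond it, so that even small bends are
#'   realized as localized kinks rather than distributed curvature.
#'
#' @param kind `"harmonic"` or `"lsec"`.
#' @param lb Bending persistence length in nm (harmonic kind).
#' @param theta0 Flex angle in radians (lsec kind). Default 2 degrees.
#' @param k Positive integer exponent of the lsec tail term.
#' @param q Stiffness of the lsec quadratic core, kcal/mol/rad^2.
#' @param kT Thermal energy in kcal/mol; default 0.593 (T = 298 K).
#'
#' @return An object of class `energy_model`.
#' @examples
#' wlc <- energy_model("harmonic", lb = 56)
#' kinky <- energy_model("lsec")
#' bend_energy(pi / 18, kinky)
#' @export
energy_model <- function(kind = c("harmonic", "lsec"), lb = 50,
                         theta0 = 2 * pi / 180, k = 2L, q = 110,
                         kT = 0.593) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(kT), length(kT) == 1, kT > 0)
  if (kind == "harmonic") {
    if (!is.numeric(lb) || length(lb) != 1 || !is.finite(lb) || lb <= 0)
      stop("`lb` must be a single positive number (nm).", call. = FALSE)
  } else {
    if (!is.numeric(theta0) || length(theta0) != 1 ||
        theta0 <= 0 || theta0 >= pi)
      stop("`theta0` must lie in (0, pi).", call. = FALSE)
    if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
      stop("`k` must be a positive integer.", call. = FALSE)
    if (!is.numeric(q) || length(q) != 1 || q <= 0)
      stop("`q` must be positive (kcal/mol).", call. = FALSE)
  }
  structure(
    list(kind = kind, lb = lb, theta0 = theta0, k = as.integer(k), q = q,
         kT = kT),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  if (x$kind == "harmonic") {
    cat(sprintf("<energy_model> harmonic WLC, lb = %g nm, kT = %g kcal/mol\n",
                x$lb, x$kT))
  } else {
    cat(sprintf(
      "<energy_model> LSEC (kinkable), theta0 = %.3g rad, k = %d, q = %g kcal/mol, kT = %g kcal/mol\n",
      x$theta0, x$k, x$q, x$kT))
  }
  invisible(x)
}

#' Bending energy of a single chain segment
#'
#' Evaluates the bending energy `E(theta)` in kcal/mol for bend angles
#' `theta` between adjacent chain segments. The LSEC potential is applied to
#' `|theta|`; the harmonic energy depends on the segment length `step`
#' because its stiffness is expressed through the persistence length.
#'
#' @param theta Bend angle(s) in radians; must lie in `[-pi, pi]`.
#' @param model An [energy_model()].
#' @param step Segment length in nm (harmonic kind only). Default 0.34, one
#'   base-pair rise.
#' @return Energies in kcal/mol, `E(0) = 0`.
#' @examples
#' m <- energy_model("lsec")
#' bend_energy(c(0, m$theta0, pi), m)
#' @export
bend_energy <- function(theta, model, step = 0.34) {
  stopifnot(inherits(model, "energy_model"), is.numeric(theta))
  if (any(!is.finite(theta)) || any(abs(theta) > pi + 1e-12))
    stop("`theta` must be finite and within [-pi, pi].", call. = FALSE)
  a <- abs(theta)
  if (model$kind == "harmonic") {
    stopifnot(step > 0)
    return(model$kT * model$lb * theta^2 / (2 * step))
  }
  t0 <- model$theta0
  q <- model$q
  k <- model$k
  core <- q * a^2
  tail <- q * t0^2 -
    (q / k) * t0 * (t0 - pi) * (1 - ((a - pi) / (t0 - pi))^(2 * k))
  ifelse(a < t0, core, tail)
}

# Dense inverse-CDF table for LSEC Boltzmann sampling on [0, pi].
# Grid resolution 1e-4 rad; trapezoid cumulative weights.
lsec_cdf_table <- function(model, grid_step = 1e-4) {
  th <- seq(0, pi, by = grid_step)
  w <- exp(-bend_energy(th, model) / model$kT)
  cw <- cumsum((w[-1] + w[-length(w)]) / 2) * grid_step
  cdf <- c(0, cw / cw[length(cw)])
  list(theta = th, cdf = cdf)
}

#' Sample equilibrium bend angles from a Boltzmann distribution
#'
#' Draws i.i.d. signed bend angles on `(-pi, pi)` with density proportional
#' to `exp(-E(theta)/kT)`. The harmonic case is a truncated normal with
#' variance `step / lb`; draws outside `(-pi, pi)` are redrawn (negligible
#' for `lb/step >> 1`). The LSEC case uses inverse-CDF sampling on a dense
#' tabulated grid of `|theta|` followed by a random sign, so results are
#' deterministic given the R random seed.
#'
#' @inheritParams bend_energy
#' @param n Number of angles to draw.
#' @return Numeric vector of `n` signed angles in radians.
#' @examples
#' set.seed(1)
#' th <- sample_bend_angles(energy_model("harmonic", lb = 50), n = 1e4)
#' var(th) # ~ 0.34 / 50
#' @export
sample_bend_angles <- function(model, step = 0.34, n) {
  stopifnot(inherits(model, "energy_model"),
            is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (model$kind == "harmonic") {
    sd <- sqrt(step / model$lb)
    th <- stats::rnorm(n, 0, sd)
    bad <- which(abs(th) >= pi)
    while (length(bad) > 0) {
      th[bad] <- stats::rnorm(length(bad), 0, sd)
      bad <- bad[abs(th[bad]) >= pi]
    }
    return(th)
  }
  tab <- lsec_cdf_table(model)
  u <- stats::runif(n)
  mag <- stats::approx(tab$cdf, tab$theta, xout = u, ties = "ordered")$y
  mag * sample(c(-1, 1), n, replace = TRUE)
}
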