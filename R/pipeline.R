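#' Configuration for a virtual AFM experiment
#'
#' Collects every knob of the simulate -> render -> trace -> measure ->
#' estimate pipeline, validated eagerly through the owning constructors.
#' The seed is mandatory: every run is reproducible bit for bit.
#'
#' @param seed Integer RNG seed.
#' @param model An [energy_model()].
#' @param n_molecules Molecules per condition.
#' @param n_beads Beads per chain.
#' @param step_nm Bead step, nm.
#' @param l0_nm Vector of link lengths to resample/trace at, nm.
#' @param separations Integer vector of tangent separations (in links)
#'   measured at each `l0`.
#' @param noise_amplitudes_nm Bisector-shift amplitudes for the noise
#'   experiment, nm.
#' @param pixel_size_nm Pixel size(s) for rendered images, nm.
#' @param render A [render_params()].
#' @param bin_width Histogram bin width, radians.
#' @param n_boot Bootstrap resamples for standard errors.
#' @param out_dir Optional output directory for tables.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(seed, model = energy_model("harmonic", lb = 56),
                              n_molecules = 100L, n_beads = 4363L,
                              step_nm = 0.34, l0_nm = c(3.5, 7, 14),
                              separations = 1:3,
                              noise_amplitudes_nm = c(0, 1, 2),
                              pixel_size_nm = 1.95,
                              render = render_params(), bin_width = 0.05,
                              n_boot = 200L, out_dir = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("`seed` is mandatory.", call. = FALSE)
  stopifnot(inherits(model, "energy_model"),
            inherits(render, "render_params"),
            n_molecules >= 1, n_beads >= 2, step_nm > 0,
            all(l0_nm >= step_nm), all(separations >= 1),
            all(noise_amplitudes_nm >= 0), all(pixel_size_nm > 0),
            bin_width > 0, n_boot >= 0)
  cfg <- list(seed = as.integer(seed), model = model,
              n_molecules = as.integer(n_molecules),
              n_beads = as.integer(n_beads), step_nm = step_nm,
              l0_nm = l0_nm, separations = as.integer(separations),
              noise_amplitudes_nm = noise_amplitudes_nm,
              pixel_size_nm = pixel_size_nm, render = render,
              bin_width = bin_width, n_boot = as.integer(n_boot),
              out_dir = out_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from YAML
#'
#' Keys follow the flat dotted layout `model.kind`, `model.lb_nm`,
#' `model.theta0_deg`, `model.k`, `model.q_kcal_mol`, `chain.n_beads`,
#' `chain.n_molecules`, `chain.step_nm`, `resample.l0_nm`,
#' `noise.amplitude_nm`, `image.pixel_size_nm`, `seed` (missing keys fall
#' back to the [experiment_config()] defaults).
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(key, default) y[[key]] %||% default
  kind <- g("model.kind", "harmonic")
  model <- if (kind == "harmonic") {
    energy_model("harmonic", lb = g("model.lb_nm", 56))
  } else {
    energy_model("lsec",
                 theta0 = g("model.theta0_deg", 2) * pi / 180,
                 k = g("model.k", 2L), q = g("model.q_kcal_mol", 110))
  }
  experiment_config(
    seed = y$seed,
    model = model,
    n_molecules = g("chain.n_molecules", 100L),
    n_beads = g("chain.n_beads", 4363L),
    step_nm = g("chain.step_nm", 0.34),
    l0_nm = unlist(g("resample.l0_nm", c(3.5, 7, 14))),
    noise_amplitudes_nm = unlist(g("noise.amplitude_nm", c(0, 1, 2))),
    pixel_size_nm = unlist(g("image.pixel_size_nm", 1.95)),
    out_dir = y$out_dir
  )
}

config_provenance <- function(cfg) {
  list(seed = cfg$seed, config_hash = rlang::hash(unclass(cfg)))
}

stamp <- function(x, cfg) {
  attr(x, "provenance") <- config_provenance(cfg)
  x
}

#' Reference Monte-Carlo distributions and persistence estimates
#'
#' Simulates the chain ensemble at base-pair resolution, resamples it at
#' every requested link length, measures non-overlapping tangent angles at
#' every requested separation, and emits distribution tables plus
#' persistence-length estimates -- the reference WLC curves against which
#' experiment-like traces are compared.
#'
#' @param config An [experiment_config()].
#' @return List with `estimates` (one row per `l0` x separation) and
#'   `tables` (named list of distribution tibbles, names `l0_<x>_L_<y>`).
#'   Both carry a `provenance` attribute (seed + config hash). Tables are
#'   also written under `config$out_dir` when set.
#' @export
run_reference_mc <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  chains <- sample_chains(config$model, config$n_molecules,
                          config$n_beads, config$step_nm)
  tables <- list()
  rows <- list()
  for (l0 in config$l0_nm) {
    co <- resample_with_stride(chains, l0)
    for (s in config$separations) {
      a <- tangent_angles(co, s)
      if (nrow(a) == 0) next
      tab <- neg_log_distribution(a, config$bin_width)
      key <- sprintf("l0_%g_L_%g", l0, attr(a, "L_nm"))
      tables[[key]] <- tab
      est <- estimate_lb(a, "variance", n_boot = config$n_boot)
      rows[[key]] <- dplyr::mutate(glance(est), l0_nm = l0,
                                   separation_links = s, .before = 1)
    }
  }
  out <- list(estimates = dplyr::bind_rows(rows), tables = tables)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    lb_ref <- if (config$model$kind == "harmonic") config$model$lb else NULL
    for (key in names(tables)) {
      write_distribution(tables[[key]],
                         file.path(config$out_dir,
                                   paste0("reference_", key, ".tsv")),
                         lb = lb_ref,
                         L_nm = out$estimates$L_eff_nm[
                           match(key, names(tables))])
    }
    readr::write_tsv(out$estimates,
                     file.path(config$out_dir, "reference_estimates.tsv"))
  }
  stamp(out, config)
}

#' Bisector-shift noise experiment
#'
#' For every shift amplitude and link length, applies bisector noise to
#' the resampled reference chains and re-estimates the apparent
#' persistence length at each separation, quantifying how the irreducible
#' double-helix-width noise depresses the apparent `lb` at short tangent
#' separations while leaving long separations nearly untouched.
#'
#' @param config An [experiment_config()] (uses `noise_amplitudes_nm` and
#'   `l0_nm`).
#' @return List with `estimates` (rows: l0 x amplitude x separation) and
#'   `tables` (named list, `l0_<x>_amp_<a>_L_<y>`); provenance-stamped.
#' @export
run_noise_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$noise_amplitudes_nm) == 0)
    stop("`noise_amplitudes_nm` must be non-empty.", call. = FALSE)
  set.seed(config$seed)
  chains <- sample_chains(config$model, config$n_molecules,
                          config$n_beads, config$step_nm)
  tables <- list()
  rows <- list()
  for (l0 in config$l0_nm) {
    co <- resample_with_stride(chains, l0)
    for (amp in config$noise_amplitudes_nm) {
      noisy <- apply_bisector_noise(co, amp)
      for (s in config$separations) {
        a <- tangent_angles(noisy, s)
        if (nrow(a) == 0) next
        key <- sprintf("l0_%g_amp_%g_L_%g", l0, amp, attr(a, "L_nm"))
        tables[[key]] <- neg_log_distribution(a, config$bin_width)
        est <- estimate_lb(a, "variance", n_boot = config$n_boot)
        rows[[key]] <- dplyr::mutate(glance(est), l0_nm = l0,
                                     amplitude_nm = amp,
                                     separation_links = s, .before = 1)
      }
    }
  }
  out <- list(estimates = dplyr::bind_rows(rows), tables = tables)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out$estimates,
                     file.path(config$out_dir, "noise_estimates.tsv"))
  }
  stamp(out, config)
}

#' End-to-end virtual imaging experiment
#'
#' Renders seeded fixtures (chains + height images), traces every image
#' at each link length with refinement both off and on (seeding the
#' tracer from the ground-truth chain end), and reports apparent
#' persistence lengths per condition next to ground-truth-chain estimates.
#' Per-molecule tracing failures are collected and the run continues.
#'
#' @param config An [experiment_config()].
#' @param refine Logical vector of refinement settings to run.
#' @return List with `estimates` (rows: pixel size x l0 x refinement,
#'   plus `truth` rows from the generating chains), `failures` (tibble of
#'   molecule, condition, message), and `n_traced`; provenance-stamped.
#' @export
run_imaging_experiment <- function(config, refine = c(FALSE, TRUE)) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  rows <- list()
  fails <- list()
  for (px in config$pixel_size_nm) {
    fix <- make_fixture_set(config$n_molecules, config$model,
                            config$n_beads, config$step_nm, px,
                            config$render)
    truth_mats <- contour_split(fix$chains)
    for (l0 in config$l0_nm) {
      truth <- resample_with_stride(fix$chains, l0)
      a_true <- tangent_angles(truth, 1L)
      est_true <- estimate_lb(a_true, "variance", n_boot = config$n_boot)
      rows[[sprintf("truth_px%g_l0%g", px, l0)]] <- dplyr::mutate(
        glance(est_true), pixel_size_nm = px, l0_nm = l0,
        condition = "truth", .before = 1)
      for (rf in refine) {
        traces <- list()
        for (i in seq_along(fix$images)) {
          res <- tryCatch({
            p <- truth_mats[[as.character(i)]]
            m <- max(2L, round(l0 / config$step_nm) + 1L)
            seeds <- rbind(p[1, ], p[min(m, nrow(p)), ])
            tr <- trace_molecule(fix$images[[i]], seeds, l0,
                                 molecule_id = i)
            if (rf) tr <- refine_trace(fix$images[[i]], tr, l0)
            tr
          }, error = function(e) e)
          if (inherits(res, "error")) {
            fails[[length(fails) + 1]] <- tibble::tibble(
              molecule_id = i, pixel_size_nm = px, l0_nm = l0,
              refined = rf, message = conditionMessage(res))
          } else if (nrow(res) >= 3) {
            traces[[length(traces) + 1]] <- res
          }
        }
        if (length(traces) == 0) next
        all_tr <- dplyr::bind_rows(traces)
        all_tr <- set_contour_meta(all_tr, source = "traced",
                                   l0_nm = l0, link_nm = l0)
        a <- tangent_angles(all_tr, 1L)
        est <- estimate_lb(a, "variance", n_boot = config$n_boot)
        key <- sprintf("trace_px%g_l0%g_rf%d", px, l0, rf)
        rows[[key]] <- dplyr::mutate(
          glance(est), pixel_size_nm = px, l0_nm = l0,
          condition = if (rf) "traced_refined" else "traced_raw",
          .before = 1)
      }
    }
  }
  out <- list(estimates = dplyr::bind_rows(rows),
              failures = dplyr::bind_rows(fails))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out$estimates,
                     file.path(config$out_dir, "imaging_estimates.tsv"))
  }
  stamp(out, config)
}
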