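# Contours and chains are plain tibbles with columns
# molecule_id, vertex_index, x_nm, y_nm, plus metadata attributes:
#   wt_source  "chain" | "mc_resampled" | "traced" | "noisy"
#   wt_step_nm underlying bead step of the generating chain (nm)
#   wt_stride  beads per link for mc_resampled contours (NA otherwise)
#   wt_l0_nm   nominal link length (nm)
#   wt_link_nm actual link length (nm); stride * step for resampled contours
# dplyr verbs may drop these attributes; set_contour_meta() restores them.

contour_cols <- c("molecule_id", "vertex_index", "x_nm", "y_nm")

#' Attach contour metadata to a chain/contour tibble
#'
#' @param df Tibble with columns `molecule_id`, `vertex_index`, `x_nm`,
#'   `y_nm`.
#' @param source One of `"chain"`, `"mc_resampled"`, `"traced"`, `"noisy"`.
#' @param step_nm Bead step of the underlying chain, nm.
#' @param stride Beads per link (resampled contours), or `NA`.
#' @param l0_nm Nominal link length, nm.
#' @param link_nm Actual link length, nm.
#' @return The tibble with metadata attributes set.
#' @export
set_contour_meta <- function(df, source, step_nm = NA_real_,
                             stride = NA_real_, l0_nm = NA_real_,
                             link_nm = NA_real_) {
  stopifnot(all(contour_cols %in% names(df)))
  df <- tibble::as_tibble(df)
  attr(df, "wt_source") <- source
  attr(df, "wt_step_nm") <- step_nm
  attr(df, "wt_stride") <- stride
  attr(df, "wt_l0_nm") <- l0_nm
  attr(df, "wt_link_nm") <- link_nm
  df
}

#' Read contour metadata attributes
#' @param df A contour tibble.
#' @return Named list with `source`, `step_nm`, `stride`, `l0_nm`,
#'   `link_nm`.
#' @export
contour_meta <- function(df) {
  list(
    source = attr(df, "wt_source") %||% NA_character_,
    step_nm = attr(df, "wt_step_nm") %||% NA_real_,
    stride = attr(df, "wt_stride") %||% NA_real_,
    l0_nm = attr(df, "wt_l0_nm") %||% NA_real_,
    link_nm = attr(df, "wt_link_nm") %||% NA_real_
  )
}

# split a contour tibble into per-molecule coordinate matrices
contour_split <- function(df) {
  stopifnot(all(contour_cols %in% names(df)))
  df <- dplyr::arrange(df, .data$molecule_id, .data$vertex_index)
  lapply(split(df[c("x_nm", "y_nm")], df$molecule_id),
         function(d) cbind(d$x_nm, d$y_nm))
}

# rebuild a contour tibble from a named list of coordinate matrices
contour_bind <- function(mats) {
  ids <- names(mats)
  purrr::map2_dfr(mats, ids, function(m, id) {
    tibble::tibble(
      molecule_id = as.integer(id),
      vertex_index = seq_len(nrow(m)),
      x_nm = m[, 1], y_nm = m[, 2]
    )
  })
}

#' Write contours to CSV
#'
#' One file per ensemble, columns `molecule_id`, `vertex_index`, `x_nm`,
#' `y_nm` with a header row.
#'
#' @param df Contour tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(df, path) {
  stopifnot(all(contour_cols %in% names(df)))
  readr::write_csv(df[contour_cols], path)
  invisible(path)
}

#' Read contours from CSV
#' @param path CSV file written by [write_contours()].
#' @param source,step_nm,stride,l0_nm,link_nm Metadata to attach (CSV does
#'   not carry it).
#' @return Contour tibble.
#' @export
read_contours <- function(path, source = "traced", step_nm = NA_real_,
                          stride = NA_real_, l0_nm = NA_real_,
                          link_nm = NA_real_) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  set_contour_meta(df, source = source, step_nm = step_nm, stride = stride,
                   l0_nm = l0_nm, link_nm = link_nm)
}
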