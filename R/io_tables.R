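# Plain-text table interchange: plot-spectra CSV (rows = plots, columns =
# wavelengths) and gas-exchange curve CSV.

#' Write / read plot spectra as CSV
#'
#' One row per plot: `plot_id`, `n_pixels`, then reflectance at each
#' retained wavelength; column headers are the wavelengths in nm with one
#' decimal. A companion `*_sd.csv` of identical shape holds the per-band
#' standard deviations.
#'
#' @param plots List of `plot_spectrum` objects on a common grid.
#' @param path Output CSV path.
#' @param sd_path Optional companion SD CSV path (default: `path` with
#'   `_sd` inserted before the extension).
#' @return `path`, invisibly.
#' @export
write_plot_spectra_csv <- function(plots, path, sd_path = NULL) {
  if (inherits(plots, "plot_spectrum")) plots <- list(plots)
  wl <- plots[[1L]]$mean$wavelengths_nm
  hdr <- sprintf("%.1f", wl)
  rows <- lapply(plots, function(p) {
    stopifnot(identical(p$mean$wavelengths_nm, wl))
    c(plot_id = p$plot_id, n_pixels = p$n_pixels,
      setNames(as.list(p$mean$values), hdr))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  if (is.null(sd_path)) sd_path <- sub("(\\.[^.]+)$", "_sd\\1", path)
  sd_rows <- lapply(plots, function(p) {
    c(plot_id = p$plot_id, n_pixels = p$n_pixels,
      setNames(as.list(p$sd), hdr))
  })
  sd_df <- do.call(rbind, lapply(sd_rows, function(r) as.data.frame(r, check.names = FALSE)))
  utils::write.csv(sd_df, sd_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_spectra_csv
#' @return For the reader: a list with `spectra` (plots x bands matrix,
#'   wavelength column names, plot_id row names), `wavelengths_nm` and
#'   `n_pixels`.
#' @export
read_plot_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- setdiff(names(df), c("plot_id", "n_pixels"))
  m <- as.matrix(df[, wl_cols, drop = FALSE])
  rownames(m) <- df$plot_id
  list(spectra = m, wavelengths_nm = as.numeric(wl_cols),
       n_pixels = df$n_pixels)
}

#' Read gas-exchange curves from a long CSV
#'
#' Columns: `curve_id`, `kind` (`ACi`/`AQ`), `driver` (Ci or Q), `A`,
#' `leaf_T`, and optionally `Ia` for A/Q rows.
#'
#' @param path CSV path.
#' @return Named list of [gas_exchange_curve()] objects.
#' @export
read_gas_exchange_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("curve_id", "kind", "driver", "A", "leaf_T")
  if (!all(need %in% names(df))) {
    stop("gas-exchange CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$curve_id), function(d) {
    gas_exchange_curve(kind = d$kind[1L], A = d$A, driver = d$driver,
                       leaf_T = d$leaf_T[1L],
                       Ia = if ("Ia" %in% names(d)) d$Ia else NULL)
  })
  out
}
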