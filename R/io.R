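#' Read and write the package's delimited-text formats
#'
#' Plain-text interchange for the tabular objects the pipeline consumes:
#' turbidity curves (`time_min`, `od340`), trajectories (`time_min`,
#' `A_mM`, `B_mM`, `N_mM`), CD spectra (`wavelength_nm`, `ellipticity`)
#' and qPCR Ct tables (`gene`, `group`, `replicate`, `ct`). All files are
#' headered, comma- or tab-delimited (readr auto-detects on read; writes
#' are CSV).
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return a tibble (with curve/trajectory classes where
#'   applicable); writers return `x` invisibly.
#' @name fibrilkin_io
NULL

read_delim_checked <- function(path, need) {
  x <- readr::read_delim(path, show_col_types = FALSE)
  if (!all(need %in% names(x))) {
    abort(sprintf("File '%s' must have columns: %s.", path,
                  paste(need, collapse = ", ")),
          class = "fibrilkin_io_error")
  }
  x
}

#' @rdname fibrilkin_io
#' @export
read_kinetic_curve <- function(path) {
  x <- read_delim_checked(path, c("time_min", "od340"))
  check_curve(kinetic_curve(x$time_min, x$od340))
}

#' @rdname fibrilkin_io
#' @export
write_kinetic_curve <- function(x, path) {
  check_curve(x)
  readr::write_csv(tibble::as_tibble(x)[c("time_min", "od340")], path)
  invisible(x)
}

#' @rdname fibrilkin_io
#' @export
read_trajectory <- function(path) {
  x <- read_delim_checked(path, c("time_min", "A_mM", "B_mM", "N_mM"))
  tibble::as_tibble(x)
}

#' @rdname fibrilkin_io
#' @export
write_trajectory <- function(x, path) {
  readr::write_csv(
    tibble::as_tibble(x)[c("time_min", "A_mM", "B_mM", "N_mM")], path)
  invisible(x)
}

#' @rdname fibrilkin_io
#' @export
read_cd_spectrum <- function(path) {
  check_spectrum(read_delim_checked(path, c("wavelength_nm", "ellipticity")))
}

#' @rdname fibrilkin_io
#' @export
read_ct_table <- function(path) {
  read_delim_checked(path, c("gene", "group", "replicate", "ct"))
}

#' @rdname fibrilkin_io
#' @export
write_ct_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x)[c("gene", "group", "replicate", "ct")],
                   path)
  invisible(x)
}
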