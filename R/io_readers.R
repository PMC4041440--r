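# Readers for the pipeline's tabular input formats. These are thin
# validated wrappers over read.csv so that every generator output (and
# any equivalently formatted instrument export) parses without warnings.

#' Read a relaxation intensity table (CSV: residue, delay_s, intensity)
#' @param path CSV file.
#' @export
read_relaxation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("residue", "delay_s", "intensity")
  if (!all(need %in% names(df)))
    stop("relaxation table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read an HSQC peak list (CSV: residue, h_ppm, n_ppm, intensity)
#' @param path CSV file.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path)
  need <- c("residue", "h_ppm", "n_ppm", "intensity")
  if (!all(need %in% names(df)))
    stop("peak list needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a DLS correlogram (CSV: tau_s, g2)
#' @param path CSV file.
#' @param ... instrument metadata passed to [correlogram()].
#' @export
read_correlogram_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  if (!all(c("tau_s", "g2") %in% names(df)))
    stop("correlogram needs columns: tau_s, g2")
  correlogram(df$tau_s, df$g2, ...)
}

#' Read a CD spectrum (CSV: wavelength_nm, mdeg)
#' @param path CSV file.
#' @export
read_cd_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "mdeg") %in% names(df)))
    stop("CD spectrum needs columns: wavelength_nm, mdeg")
  df
}

#' Read electrospray peaks (CSV: mz, intensity)
#' @param path CSV file.
#' @export
read_ms_peaks_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"mz" %in% names(df)) stop("MS peak list needs column: mz")
  df
}
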