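# Plain-text writers/readers for every pipeline input. All files are UTF-8
# CSV with a mandatory header row and '.' decimal separator.

#' Write a spectrum to two-column CSV
#' @param s A [spectrum()].
#' @param path Output file.
#' @export
write_spectrum_csv <- function(s, path) {
  write.csv(data.frame(wavelength_nm = s$wavelengths, intensity = s$values),
            path, row.names = FALSE, quote = FALSE)
}

#' Read a spectrum from two-column CSV
#' @param path Input file with columns `wavelength_nm`, `intensity`.
#' @param kind Spectrum kind.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, kind = "emission") {
  df <- read.csv(path)
  spectrum(df$wavelength_nm, df$intensity, kind)
}

#' Write a TCSPC decay trace to three-column CSV
#' @param trace A [decay_trace()].
#' @param path Output file.
#' @export
write_decay_csv <- function(trace, path) {
  irf <- trace$irf_counts %||% rep(NA_real_, length(trace$time))
  write.csv(data.frame(time_ns = trace$time, counts = trace$counts,
                       irf_counts = irf),
            path, row.names = FALSE, quote = FALSE)
}

#' Read a TCSPC decay trace from CSV
#' @param path File with columns `time_ns`, `counts`, `irf_counts`.
#' @param irf_sigma Gaussian IRF sigma (ns) if known.
#' @return A [decay_trace()].
#' @export
read_decay_csv <- function(path, irf_sigma = NA_real_) {
  df <- read.csv(path)
  irf <- if ("irf_counts" %in% names(df) && !all(is.na(df$irf_counts))) {
    df$irf_counts
  } else {
    NULL
  }
  decay_trace(df$time_ns, df$counts, irf_counts = irf, irf_sigma = irf_sigma)
}

#' Write a transient-absorption map to long-format CSV
#' @param map A `ta_map`.
#' @param path Output file (`delay_ps`, `wavelength_nm`, `delta_mOD`).
#' @export
write_ta_csv <- function(map, path) {
  long <- expand.grid(wavelength_nm = map$wavelengths, delay_ps = map$delays)
  long <- long[, c("delay_ps", "wavelength_nm")]
  long$delta_mOD <- as.vector(t(map$delta_mOD))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
}

#' Read a transient-absorption map from long-format CSV
#' @param path File with columns `delay_ps`, `wavelength_nm`, `delta_mOD`.
#' @return A `ta_map`.
#' @export
read_ta_csv <- function(path) {
  df <- read.csv(path)
  delays <- sort(unique(df$delay_ps))
  wl <- sort(unique(df$wavelength_nm))
  m <- matrix(NA_real_, length(delays), length(wl))
  m[cbind(match(df$delay_ps, delays), match(df$wavelength_nm, wl))] <- df$delta_mOD
  stop_if(any(is.na(m)), "TA map is not a complete delay x wavelength grid")
  structure(list(delays = delays, wavelengths = wl, delta_mOD = m),
            class = "ta_map")
}

#' Write a binding titration series to CSV
#' @param series A [binding_series][simulate_titration()].
#' @param path Output file (`conc_uM`, `f_norm`, `replicate`).
#' @export
write_titration_csv <- function(series, path) {
  write.csv(as.data.frame(series)[, c("conc_uM", "f_norm", "replicate")],
            path, row.names = FALSE, quote = FALSE)
}

#' Read a binding titration series from CSV
#' @param path Input file.
#' @param ligand_total Total ligand (uM) attribute to attach.
#' @return A binding series data.frame.
#' @export
read_titration_csv <- function(path, ligand_total = 0.5) {
  df <- read.csv(path)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  structure(df, ligand_total = ligand_total,
            class = c("binding_series", "data.frame"))
}

#' Write a free-energy profile to CSV
#' @param profile A [free_energy_profile()].
#' @param path Output (`distance_A`, `free_energy_kJ_mol`\[, `std_kJ_mol`\]).
#' @export
write_fes_csv <- function(profile, path) {
  df <- data.frame(distance_A = profile$distance,
                   free_energy_kJ_mol = profile$free_energy)
  if (!is.null(profile$std)) df$std_kJ_mol <- profile$std
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a free-energy profile (CSV or whitespace-delimited dump)
#'
#' Auto-detects the delimiter: comma-separated with a header, or the common
#' two/three-column whitespace dump format (with or without a header line).
#'
#' @param path Input file.
#' @return A [free_energy_profile()].
#' @export
read_fes_profile <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first, fixed = TRUE)) {
    df <- read.csv(path)
  } else {
    has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                             "\\s+")[[1]][1])))
    df <- read.table(path, header = has_header)
    if (!has_header) {
      names(df) <- c("distance_A", "free_energy_kJ_mol",
                     "std_kJ_mol")[seq_len(ncol(df))]
    }
  }
  std <- if ("std_kJ_mol" %in% names(df)) df$std_kJ_mol else NULL
  free_energy_profile(df[[1]], df[[2]], std = std)
}

#' Write an irradiation time course to CSV
#' @param tc A [time_course()].
#' @param path Output file (`time_min`, `f_norm`).
#' @export
write_timecourse_csv <- function(tc, path) {
  write.csv(as.data.frame(tc)[, c("time_min", "f_norm")], path,
            row.names = FALSE, quote = FALSE)
}

#' Read an irradiation time course from CSV
#' @param path Input file.
#' @param label Sample id.
#' @return A [time_course()].
#' @export
read_timecourse_csv <- function(path, label = basename(path)) {
  df <- read.csv(path)
  time_course(df$time_min, df$f_norm, label = label)
}
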