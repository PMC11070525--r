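#' Read a spectral curve from CSV
#'
#' Expects columns `wavelength_nm, value`.  Wavelengths must increase
#' strictly and values must be non-negative; violations are reported with
#' the offending file line.  Input on a coarser or misaligned grid is
#' resampled to the integer 1-nm grid by linear interpolation.
#'
#' @param path CSV file path.
#' @param kind curve kind, see [spectral_curve()].
#' @return a [spectral_curve()].
#' @export
read_spectrum <- function(path, kind = "absorptivity") {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop(sprintf("'%s': expected columns 'wavelength_nm, value'", path))
  wl <- df$wavelength_nm; v <- df$value
  if (any(diff(wl) <= 0)) {
    k <- which(diff(wl) <= 0)[1L] + 1L
    stop(sprintf("'%s' line %d: wavelengths must increase strictly",
                 path, k + 1L))
  }
  if (anyNA(v) || any(v < 0)) {
    k <- which(is.na(v) | v < 0)[1L]
    stop(sprintf("'%s' line %d: negative or missing value", path, k + 1L))
  }
  grid <- ceiling(min(wl)):floor(max(wl))
  vi <- stats::approx(wl, v, xout = grid)$y
  spectral_curve(grid, vi, kind)
}

#' Write a spectral curve to CSV
#' @param curve a [spectral_curve()].
#' @param path output CSV path.
#' @export
write_spectrum <- function(curve, path) {
  utils::write.csv(data.frame(wavelength_nm = curve$wavelength,
                              value = curve$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a kinetic trace to CSV
#'
#' Columns `time_s`, one `C_<label>` per species, and `Atot_obs`;
#' provenance (lamp tag, observation wavelength, step size) goes into
#' `#`-prefixed header lines.
#'
#' @param trace a `kinetic_trace`.
#' @param path output CSV path.
#' @export
write_trace <- function(trace, path) {
  sys <- trace$system
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# lamp_tag: %s", sys$lamp_tag),
    sprintf("# lambda_obs_nm: %d", sys$lambda_obs),
    sprintf("# dt_s: %.10g", trace$dt)), con)
  df <- data.frame(time_s = trace$times, trace$conc,
                   Atot_obs = absorbance_trace(trace),
                   check.names = FALSE)
  names(df) <- c("time_s", paste0("C_", colnames(trace$conc)), "Atot_obs")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kinetic trace written by [write_trace()]
#'
#' @param path CSV file path.
#' @return list with `times`, `conc` (matrix), `a_tot`, and `meta` (the
#'   parsed header lines).  This is a plain data view, not a full
#'   `kinetic_trace` (the generating system is not serialized with it).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  cc <- grep("^C_", names(df))
  conc <- as.matrix(df[cc])
  colnames(conc) <- sub("^C_", "", names(df)[cc])
  list(times = df$time_s, conc = conc, a_tot = df$Atot_obs, meta = meta)
}

#' Write a photosystem bundle to a directory
#'
#' Serializes a [photo_system()] as one CSV per curve plus a
#' `system.yaml` manifest (species, initial concentrations, geometry,
#' steps with their quantum-yield files).  [read_system()] restores it.
#'
#' @param system a [photo_system()].
#' @param dir output directory (created if missing).
#' @export
write_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mech <- system$mechanism
  eps_files <- sprintf("epsilon_%s.csv", mech$labels)
  for (j in seq_len(mech$n_species))
    write_spectrum(system$epsilons[[j]], file.path(dir, eps_files[j]))
  write_spectrum(system$lamp, file.path(dir, "lamp.csv"))
  phi_files <- sprintf("phi_step%02d.csv", seq_along(mech$steps))
  for (s in seq_along(mech$steps))
    write_spectrum(mech$steps[[s]]$phi, file.path(dir, phi_files[s]))
  if (!is.null(system$spm))
    write_spectrum(system$spm, file.path(dir, "spm.csv"))
  manifest <- list(
    labels = mech$labels,
    c0 = system$c0,
    l_irr = system$l_irr, l_obs = system$l_obs,
    lambda_obs = system$lambda_obs, lamp_tag = system$lamp_tag,
    lamp_file = "lamp.csv",
    epsilon_files = eps_files,
    spm_file = if (is.null(system$spm)) NULL else "spm.csv",
    steps = lapply(seq_along(mech$steps), function(s)
      list(from = mech$labels[mech$steps[[s]]$from],
           to = mech$labels[mech$steps[[s]]$to],
           phi_file = phi_files[s])))
  yaml::write_yaml(manifest, file.path(dir, "system.yaml"))
  invisible(dir)
}

#' Read a photosystem bundle written by [write_system()]
#' @param dir bundle directory containing `system.yaml`.
#' @return a [photo_system()].
#' @export
read_system <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "system.yaml"))
  labels <- unlist(mf$labels)
  epsilons <- lapply(mf$epsilon_files, function(f)
    read_spectrum(file.path(dir, f), "absorptivity"))
  lamp <- read_spectrum(file.path(dir, mf$lamp_file), "lamp_intensity")
  steps <- lapply(mf$steps, function(s)
    photo_step(match(s$from, labels), match(s$to, labels),
               read_spectrum(file.path(dir, s$phi_file), "quantum_yield")))
  spm <- if (is.null(mf$spm_file)) NULL else
    read_spectrum(file.path(dir, mf$spm_file), "absorptivity")
  if (!is.null(spm)) spm$kind <- "absorptivity"
  photo_system(mechanism(length(labels), steps, labels = labels),
               epsilons, lamp, unlist(mf$c0), mf$l_irr, mf$l_obs,
               mf$lambda_obs, spm = spm, lamp_tag = mf$lamp_tag)
}
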