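#' Ground-truth ion for the synthetic generator
#'
#' Describes one planted species: its chemistry (formula + adduct, which fix
#' the target m/z and isotopic envelope), its mobility parameters, and its
#' peak-shape parameters. The arrival-time distribution broadens in
#' proportion to the arrival time itself (`dt_width_rel` is the relative
#' FWHM), emulating the predictable diffusion broadening of a drifting ion
#' cloud.
#'
#' @param formula Formula string or `empirical_formula`.
#' @param adduct Adduct kind or `adduct` object (default `"[M+H]"`).
#' @param K0_true Reduced mobility (cm^2 V^-1 s^-1).
#' @param t0_true_ms Time outside the drift cell (ms, default 4).
#' @param intensity Apex counts per frame for the monoisotopic peak
#'   (default 50).
#' @param dt_width_rel Relative ATD FWHM, in (0, 0.2] (default 0.025, i.e.
#'   a mobility resolving power of 40).
#' @param mz_sigma_ppm Gaussian m/z peak sigma in ppm (default 15).
#' @param name Optional label.
#' @param n_isotopomers Envelope length (default 5).
#' @return Object of class `ground_truth_ion`.
#' @export
ground_truth_ion <- function(formula, adduct = "[M+H]", K0_true,
                             t0_true_ms = 4, intensity = 50,
                             dt_width_rel = 0.025, mz_sigma_ppm = 15,
                             name = NULL, n_isotopomers = 5L) {
  if (!is.finite(K0_true) || K0_true <= 0) stop("K0_true must be positive",
                                                call. = FALSE)
  if (!is.finite(intensity) || intensity <= 0)
    stop("intensity must be positive", call. = FALSE)
  if (dt_width_rel <= 0 || dt_width_rel > 0.2)
    stop("dt_width_rel must lie in (0, 0.2]", call. = FALSE)
  target <- make_target(formula, adduct, name = name,
                        n_isotopomers = n_isotopomers)
  structure(list(target = target, K0_true = K0_true,
                 t0_true_ms = t0_true_ms, intensity = intensity,
                 dt_width_rel = dt_width_rel, mz_sigma_ppm = mz_sigma_ppm),
            class = "ground_truth_ion")
}

#' Synthetic acquisition configuration
#'
#' Defaults mirror a stepped-field acquisition: seven electric fields
#' spanning 10.8 to 18.5 V/cm over a 90 cm drift tube, 30 frames per field,
#' 4 torr nitrogen at 300 K, m/z bins of 0.005 Da over a +/- 2 Da window
#' around each target cluster, and 0.1 ms arrival-time bins over 0-80 ms.
#' The baseline is a uniform expected count per bin; when counting noise is
#' on, every bin is an independent Poisson draw around its expected value.
#'
#' @param seed Integer seed; mandatory for reproducibility.
#' @param drift_voltages Voltages (V); default the seven stepped fields.
#' @param frames_per_field Frames per field (default 30).
#' @param p_torr,T_K,l_cm Pressure, temperature, drift length.
#' @param gas_mass_da Buffer-gas mass (Da).
#' @param baseline_level Uniform baseline expected counts per bin
#'   (default 0.5, i.e. 1 percent of the default ion apex).
#' @param counting_noise_on Poisson counting noise flag (default TRUE).
#' @param decoys List of `ground_truth_ion` interferences.
#' @param mz_bin_da,mz_window_da m/z bin width and half-window per cluster.
#' @param dt_bin_ms,dt_range_ms Arrival-time bin width and range.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         drift_voltages = NULL,
                         frames_per_field = 30L,
                         p_torr = 4, T_K = 300, l_cm = 90,
                         gas_mass_da = 28.0134,
                         baseline_level = 0.5,
                         counting_noise_on = TRUE,
                         decoys = list(),
                         mz_bin_da = 0.005, mz_window_da = 2,
                         dt_bin_ms = 0.1, dt_range_ms = c(0, 80)) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory",
                                              call. = FALSE)
  if (is.null(drift_voltages)) {
    drift_voltages <- seq(10.8, 18.5, length.out = 7) * l_cm
  }
  if (length(drift_voltages) < 3L) stop("need at least 3 fields",
                                        call. = FALSE)
  if (dt_range_ms[2] <= dt_range_ms[1] || mz_bin_da <= 0 || dt_bin_ms <= 0)
    stop("axis configuration invalid", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 drift_voltages = sort(drift_voltages, decreasing = TRUE),
                 frames_per_field = as.integer(frames_per_field),
                 p_torr = p_torr, T_K = T_K, l_cm = l_cm,
                 gas_mass_da = gas_mass_da,
                 baseline_level = baseline_level,
                 counting_noise_on = counting_noise_on,
                 decoys = decoys,
                 mz_bin_da = mz_bin_da, mz_window_da = mz_window_da,
                 dt_bin_ms = dt_bin_ms, dt_range_ms = dt_range_ms),
            class = "synth_config")
}

#' Forward arrival-time model
#'
#' Evaluates the straight-line drift model: the drift term
#' `l^2 * 273.15 / (760 K0) * p/(TV)` plus the out-of-cell time `t0`.
#'
#' @param K0 Reduced mobility (cm^2 V^-1 s^-1).
#' @param t0_ms Time outside the drift cell (ms).
#' @param V Drift voltage (V).
#' @param p_torr,T_K Pressure (torr) and temperature (K).
#' @param l_cm Drift length (cm).
#' @return Arrival time in ms.
#' @export
arrival_time <- function(K0, t0_ms, V, p_torr, T_K, l_cm) {
  stopifnot(K0 > 0, V > 0, p_torr > 0, T_K > 0, l_cm > 0)
  .slope_ms_from_K0(K0, l_cm) * p_torr / (T_K * V) + t0_ms
}

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# union-of-intervals m/z axis covering every ion's +/- window Da cluster
.synth_mz_axis <- function(ions, config) {
  centers <- sort(vapply(ions, function(i) i$target$target_mz, numeric(1)))
  lo <- centers - config$mz_window_da
  hi <- centers + config$mz_window_da
  merged <- list(c(lo[1], hi[1]))
  for (i in seq_along(centers)[-1]) {
    last <- merged[[length(merged)]]
    if (lo[i] <= last[2] + config$mz_bin_da) {
      merged[[length(merged)]][2] <- max(last[2], hi[i])
    } else {
      merged[[length(merged) + 1L]] <- c(lo[i], hi[i])
    }
  }
  unlist(lapply(merged, function(iv) seq(iv[1], iv[2],
                                         by = config$mz_bin_da)))
}

#' Generate a multi-field synthetic frame set
#'
#' Every ion (ground truth and decoy) contributes, at each field, one 2D
#' Gaussian per isotopomer centred at (isotopomer m/z, model arrival time),
#' with ATD FWHM equal to `dt_width_rel * t_A` and amplitudes scaled by the
#' theoretical envelope. A uniform baseline is added, and when counting
#' noise is on each frame is an independent Poisson realisation of the
#' expected map. The returned `frame_set` carries a `truth_manifest`
#' attribute: a data frame with every ion's per-field true arrival time and
#' apex intensity.
#'
#' @param truth List of `ground_truth_ion` (or a single ion).
#' @param config A `synth_config`.
#' @return A `frame_set` with attribute `truth_manifest`.
#' @export
generate_frameset <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  if (inherits(truth, "ground_truth_ion")) truth <- list(truth)
  ions <- c(truth, config$decoys)
  kinds <- c(rep("truth", length(truth)),
             rep("decoy", length(config$decoys)))
  if (!length(ions)) stop("no ions to generate", call. = FALSE)
  set.seed(config$seed)
  mz_axis <- .synth_mz_axis(ions, config)
  dt_axis <- seq(config$dt_range_ms[1] + config$dt_bin_ms / 2,
                 config$dt_range_ms[2], by = config$dt_bin_ms)
  n_dt <- length(dt_axis); n_mz <- length(mz_axis)
  manifest <- list()
  frames <- vector("list",
                   length(config$drift_voltages) * config$frames_per_field)
  frame_id <- 0L
  for (fi in seq_along(config$drift_voltages)) {
    V <- config$drift_voltages[fi]
    lam <- matrix(config$baseline_level, nrow = n_dt, ncol = n_mz)
    for (ii in seq_along(ions)) {
      ion <- ions[[ii]]
      tA <- arrival_time(ion$K0_true, ion$t0_true_ms, V, config$p_torr,
                         config$T_K, config$l_cm)
      sig_dt <- .fwhm_to_sigma(ion$dt_width_rel * tA)
      rows <- which(abs(dt_axis - tA) <= 5 * sig_dt)
      env <- ion$target$envelope
      for (k in seq_along(env$offsets_da)) {
        q <- env$rel_intensities[k]
        if (q < 1e-6) next
        mzk <- ion$target$target_mz + env$offsets_da[k]
        sig_mz <- ion$mz_sigma_ppm * 1e-6 * mzk
        cols <- which(abs(mz_axis - mzk) <= 5 * sig_mz)
        if (!length(rows) || !length(cols)) next
        gdt <- exp(-0.5 * ((dt_axis[rows] - tA) / sig_dt)^2)
        gmz <- exp(-0.5 * ((mz_axis[cols] - mzk) / sig_mz)^2)
        lam[rows, cols] <- lam[rows, cols] +
          ion$intensity * q * outer(gdt, gmz)
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        ion = ion$target$name, adduct = ion$target$adduct$kind,
        kind = kinds[ii], field_index = fi, drift_voltage_V = V,
        x_value = config$p_torr / (config$T_K * V),
        t_A_ms = tA, apex_intensity = ion$intensity,
        target_mz = ion$target$target_mz, K0_true = ion$K0_true,
        t0_true_ms = ion$t0_true_ms, stringsAsFactors = FALSE)
    }
    for (rep_i in seq_len(config$frames_per_field)) {
      counts <- if (config$counting_noise_on) {
        matrix(stats::rpois(n_dt * n_mz, lam), nrow = n_dt)
      } else lam
      frame_id <- frame_id + 1L
      frames[[frame_id]] <- .sparse_frame(frame_id, V, config, counts,
                                          mz_axis, dt_axis)
    }
  }
  cond <- instrument_conditions(config$l_cm, config$gas_mass_da,
                                config$T_K, config$p_torr)
  fs <- frame_set(cond, frames, mz_axis, dt_axis)
  attr(fs, "truth_manifest") <- do.call(rbind, manifest)
  fs
}

.sparse_frame <- function(frame_id, V, config, counts, mz_axis, dt_axis) {
  n_dt <- length(dt_axis)
  nz <- which(counts > 0)
  rows <- (nz - 1L) %% n_dt + 1L
  cols <- (nz - 1L) %/% n_dt + 1L
  ord <- order(rows, cols)
  mz_by_row <- split(mz_axis[cols[ord]], rows[ord])
  val_by_row <- split(counts[nz[ord]], rows[ord])
  row_ids <- as.integer(names(mz_by_row))
  scans <- vector("list", length(row_ids))
  for (i in seq_along(row_ids)) {
    scans[[i]] <- list(arrival_time_ms = dt_axis[row_ids[i]],
                       mz = mz_by_row[[i]],
                       intensity = val_by_row[[i]])
  }
  ims_frame(frame_id, V, config$p_torr, config$T_K, scans)
}

#' Write a synthetic frame set plus its truth manifest
#'
#' Writes the frame store and a JSON side-file `<path>.truth.json` holding
#' the per-ion, per-field true arrival times and intensities.
#'
#' @param frameset A `frame_set` from [generate_frameset()].
#' @param path Frame store output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_set <- function(frameset, path) {
  write_frames(frameset, path)
  manifest <- attr(frameset, "truth_manifest")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".truth.json"),
                         digits = NA)
  }
  invisible(path)
}
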