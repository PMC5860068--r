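#' Extract the ppm window around a target m/z
#'
#' Restricts an intensity map to the m/z bins within
#' `target_mz * (1 +/- ppm * 1e-6)`, keeping the full arrival-time range.
#'
#' @param map An `intensity_map`.
#' @param target_mz Expected ion m/z (Da).
#' @param ppm Window half-width in ppm (default 250).
#' @return An `intensity_map` restricted to the window.
#' @export
extract_window <- function(map, target_mz, ppm = 250) {
  stopifnot(inherits(map, "intensity_map"), ppm > 0, target_mz > 0)
  lo <- target_mz * (1 - ppm * 1e-6)
  hi <- target_mz * (1 + ppm * 1e-6)
  cols <- which(map$mz_axis >= lo & map$mz_axis <= hi)
  if (!length(cols)) {
    stop(sprintf("empty m/z window: no bins in [%.4f, %.4f]", lo, hi),
         call. = FALSE)
  }
  intensity_map(map$mz_axis[cols], map$dt_axis,
                map$intensities[, cols, drop = FALSE])
}

# separable Gaussian smoothing with normalised (edge-corrected) kernels
.gaussian_smooth <- function(mat, sigma = 1) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  conv <- function(v) {
    n <- length(v)
    if (n == 1L) return(v)
    full <- stats::convolve(c(numeric(r), v, numeric(r)), rev(k),
                            type = "filter")
    mask <- stats::convolve(c(numeric(r), rep(1, n), numeric(r)), rev(k),
                            type = "filter")
    full / mask
  }
  out <- apply(mat, 2L, conv)                # along dt (columns of map)
  t(apply(out, 1L, conv))                    # along m/z
}

# log-parabolic sub-bin apex refinement; exact for a sampled Gaussian
.refine_apex <- function(axis, profile, i) {
  if (i <= 1L || i >= length(profile)) return(axis[i])
  y <- profile[(i - 1L):(i + 1L)]
  if (any(y <= 0)) return(axis[i])
  ly <- log(y)
  den <- ly[1] - 2 * ly[2] + ly[3]
  if (den >= 0) return(axis[i])
  delta <- 0.5 * (ly[1] - ly[3]) / den
  delta <- max(-0.5, min(0.5, delta))
  axis[i] + delta * (axis[min(i + 1L, length(axis))] - axis[i])
}

# FWHM by linear interpolation at half apex along a profile through idx
.fwhm_interp <- function(axis, profile, i) {
  half <- profile[i] / 2
  left <- axis[i]; right <- axis[i]
  j <- i
  while (j > 1L && profile[j - 1L] > half) j <- j - 1L
  if (j > 1L) {
    f <- (profile[j] - half) / (profile[j] - profile[j - 1L])
    left <- axis[j] - f * (axis[j] - axis[j - 1L])
  } else left <- axis[1]
  j <- i
  while (j < length(profile) && profile[j + 1L] > half) j <- j + 1L
  if (j < length(profile)) {
    f <- (profile[j] - half) / (profile[j] - profile[j + 1L])
    right <- axis[j] + f * (axis[j + 1L] - axis[j])
  } else right <- axis[length(axis)]
  max(right - left, .Machine$double.eps)
}

# steepest-ascent basin label for every bin of a matrix (9-neighbourhood)
.basin_labels <- function(sm) {
  n_r <- nrow(sm); n_c <- ncol(sm)
  pad <- matrix(-Inf, n_r + 2L, n_c + 2L)
  pad[2:(n_r + 1L), 2:(n_c + 1L)] <- sm
  best_val <- sm
  best_off <- matrix(0L, n_r, n_c)   # encoded dr + 10*dc
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(n_r + 1L)) + dr, (2:(n_c + 1L)) + dc, drop = FALSE]
    upd <- nb > best_val
    best_val[upd] <- nb[upd]
    best_off[upd] <- dr + 10L * dc
  }
  idx <- matrix(seq_len(n_r * n_c), n_r, n_c)
  dr <- ((best_off + 100L) %% 10L + 5L) %% 10L - 5L   # decode dr in {-1,0,1}
  dc <- as.integer(round((best_off - dr) / 10L))
  parent <- idx + dr + dc * n_r
  parent <- as.integer(parent)
  # pointer jumping to the root of each steepest-ascent chain
  repeat {
    pp <- parent[parent]
    if (all(pp == parent)) break
    parent <- pp
  }
  matrix(parent, n_r, n_c)
}

# flood fill (8-connectivity) from a seed over a logical mask
.flood <- function(mask, seed_r, seed_c) {
  n_r <- nrow(mask); n_c <- ncol(mask)
  out <- matrix(FALSE, n_r, n_c)
  queue <- (seed_c - 1L) * n_r + seed_r
  out[queue] <- TRUE
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    r <- (cur - 1L) %% n_r + 1L
    cc <- (cur - 1L) %/% n_r + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nr <- r + dr; nc <- cc + dc
      ok <- nr >= 1L & nr <= n_r & nc >= 1L & nc <= n_c
      if (!any(ok)) next
      lin <- (nc[ok] - 1L) * n_r + nr[ok]
      add <- lin[mask[lin] & !out[lin]]
      if (length(add)) {
        out[add] <- TRUE
        queue <- c(queue, add)
      }
    }
  }
  out
}

#' Detect 2D peaks in an extraction window
#'
#' The window is smoothed with a small separable Gaussian kernel; local
#' maxima above a noise floor (median + 3 MAD of the smoothed window) seed
#' peaks, touching peaks are separated by steepest-ascent watershed basins,
#' and each peak's footprint is the contiguous basin region above 10
#' percent of its apex (never below the noise floor, so low-level baseline
#' maxima keep compact footprints). Apex positions are refined to sub-bin
#' precision by
#' log-parabolic interpolation (exact for Gaussian peaks); widths are FWHM
#' by linear interpolation at half apex through the apex along each axis.
#' Every per-peak statistic is measured above the peak's local background
#' (the minimum of the smoothed map over its footprint), so a peak riding
#' on the pedestal of a broad overlapping neighbour is characterised by
#' its own profile rather than the blend; intensities come from the raw
#' (unsmoothed) window.
#'
#' @param window An `intensity_map` (typically from [extract_window()]).
#' @param field_index Field group index recorded on each peak.
#' @param smooth_sigma Smoothing kernel sigma in bins (default 1).
#' @param footprint_frac Footprint threshold as a fraction of the smoothed
#'   apex (default 0.1).
#' @return List of `peak2d` objects sorted by decreasing summed intensity.
#'   Each has `field_index`, `mzc`, `mzw`, `mzl`, `dtc`, `dtw`, `dtl`,
#'   `base_intensity`, `summed_intensity`, `profile_base` and
#'   `atd_profile` (data frame of arrival time and background-corrected
#'   raw intensity at the apex m/z column).
#' @export
detect_peaks <- function(window, field_index = NA_integer_,
                         smooth_sigma = 1, footprint_frac = 0.1) {
  stopifnot(inherits(window, "intensity_map"))
  raw <- window$intensities
  if (all(raw == 0)) return(list())
  sm <- .gaussian_smooth(raw, smooth_sigma)
  # noise floor; the dynamic-range term keeps numerical ripple in the far
  # tails of noiseless data from seeding spurious maxima
  floor_level <- max(stats::median(sm) + 3 * stats::mad(sm),
                     1e-3 * max(sm))
  n_r <- nrow(sm); n_c <- ncol(sm)
  pad <- matrix(-Inf, n_r + 2L, n_c + 2L)
  pad[2:(n_r + 1L), 2:(n_c + 1L)] <- sm
  is_max <- sm > floor_level
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max &
      sm > pad[(2:(n_r + 1L)) + dr, (2:(n_c + 1L)) + dc, drop = FALSE]
  }
  apices <- which(is_max)
  if (!length(apices)) return(list())
  basins <- .basin_labels(sm)
  peaks <- list()
  for (lin in apices[order(sm[apices], decreasing = TRUE)]) {
    r0 <- (lin - 1L) %% n_r + 1L
    c0 <- (lin - 1L) %/% n_r + 1L
    apex_sm <- sm[r0, c0]
    mask <- basins == basins[r0, c0] &
      sm >= max(footprint_frac * apex_sm, floor_level)
    fp <- .flood(mask, r0, c0)
    fp_idx <- which(fp)
    if (!length(fp_idx)) next
    rows <- (fp_idx - 1L) %% n_r + 1L
    cols <- (fp_idx - 1L) %/% n_r + 1L
    # local background: overlapping neighbours (e.g. a broad co-drifting
    # interference) leave a pedestal under this peak; all shape statistics
    # describe the peak above that pedestal
    base <- min(sm[fp_idx])
    raw_fp <- pmax(raw[fp_idx] - base, 0)
    dtc <- .refine_apex(window$dt_axis, pmax(sm[, c0] - base, 0), r0)
    mzc <- .refine_apex(window$mz_axis, pmax(sm[r0, ] - base, 0), c0)
    dtw <- .fwhm_interp(window$dt_axis, pmax(sm[, c0] - base, 0), r0)
    mzw <- .fwhm_interp(window$mz_axis, pmax(sm[r0, ] - base, 0), c0)
    tot <- sum(raw_fp)
    dtl <- if (tot > 0) sum(raw_fp[window$dt_axis[rows] < dtc]) / tot else 0
    mzl <- if (tot > 0) sum(raw_fp[window$mz_axis[cols] < mzc]) / tot else 0
    prof_rows <- min(rows):max(rows)
    peaks[[length(peaks) + 1L]] <- structure(list(
      field_index = field_index,
      mzc = mzc, mzw = mzw, mzl = mzl,
      dtc = dtc, dtw = dtw, dtl = dtl,
      base_intensity = max(raw_fp),
      summed_intensity = tot,
      profile_base = base,
      atd_profile = data.frame(
        arrival_time_ms = window$dt_axis[prof_rows],
        intensity = pmax(raw[prof_rows, c0] - base, 0))
    ), class = "peak2d")
  }
  ord <- order(vapply(peaks, `[[`, numeric(1), "summed_intensity"),
               decreasing = TRUE)
  peaks[ord]
}

#' Gaussian peak-shape score
#'
#' Treats the arrival-time profile as a weighted sample, computes its
#' weighted skewness `S` and excess kurtosis `C`, forms the Jarque-Bera
#' statistic `JB = n_eff/6 (S^2 + C^2/4)` with the effective sample size
#' `n_eff = (sum w)^2 / sum w^2`, and maps it to `[0, 1]` via the survival
#' function of the chi-squared distribution with 2 degrees of freedom. A
#' Gaussian profile scores near 1; flat-topped, clipped or bimodal profiles
#' decay towards 0. The score is invariant to intensity scaling.
#'
#' @param peak A `peak2d`, or a data frame / list with fields
#'   `arrival_time_ms` and `intensity`.
#' @return Score in `[0, 1]`.
#' @export
shape_score <- function(peak) {
  prof <- if (inherits(peak, "peak2d")) peak$atd_profile else peak
  t <- prof$arrival_time_ms
  w <- prof$intensity
  keep <- w > 0
  if (sum(keep) < 5L) {
    stop("insufficient profile: need at least 5 nonzero bins",
         call. = FALSE)
  }
  t <- t[keep]; w <- w[keep]
  sw <- sum(w)
  mu <- sum(w * t) / sw
  m2 <- sum(w * (t - mu)^2) / sw
  if (m2 <= 0) return(0)
  m3 <- sum(w * (t - mu)^3) / sw
  m4 <- sum(w * (t - mu)^4) / sw
  S <- m3 / m2^1.5
  C <- m4 / m2^2 - 3
  n_eff <- sw^2 / sum(w^2)
  jb <- n_eff / 6 * (S^2 + C^2 / 4)
  stats::pchisq(jb, df = 2, lower.tail = FALSE)
}

#' Isotopic distribution matching score
#'
#' The angle between the observed and theoretical isotopomer intensity
#' vectors, mapped so identical directions score 1 and orthogonal vectors
#' score 0: `score = 1 - theta / (pi/2)` with
#' `cos(theta) = (I_t . I_o) / (|I_t| |I_o|)`.
#'
#' @param observed Observed per-isotopomer summed intensities.
#' @param theoretical An `isotopic_envelope` or a numeric vector.
#' @return Score in `[0, 1]`.
#' @export
isotopic_score <- function(observed, theoretical) {
  if (inherits(theoretical, "isotopic_envelope")) {
    theoretical <- theoretical$rel_intensities
  }
  if (length(observed) != length(theoretical) || length(observed) < 2L) {
    stop("observed and theoretical vectors must have equal length >= 2",
         call. = FALSE)
  }
  no <- sqrt(sum(observed^2)); nt <- sqrt(sum(theoretical^2))
  if (no == 0 || nt == 0) {
    stop("undefined isotopic score: zero-norm vector", call. = FALSE)
  }
  ct <- sum(observed * theoretical) / (no * nt)
  theta <- acos(max(-1, min(1, ct)))
  1 - theta / (pi / 2)
}

#' Observed isotopomer intensities for a detected peak
#'
#' For each theoretical isotopomer, sums the intensities of the field's
#' averaged map within a +/- `ppm_strip` m/z strip around
#' `target_mz + offset_k` and within the peak's arrival-time FWHM band.
#' Strips falling outside the map's m/z axis contribute zero.
#'
#' @param map The field's full averaged `intensity_map` (not just the
#'   extraction window: higher isotopomers lie outside it).
#' @param target A `ccs_target`.
#' @param peak A `peak2d` providing `dtc` and `dtw`.
#' @param ppm_strip Strip half-width in ppm (default 15).
#' @return Numeric vector, one entry per envelope isotopomer.
#' @export
observed_envelope <- function(map, target, peak, ppm_strip = 15) {
  rows <- which(map$dt_axis >= peak$dtc - peak$dtw / 2 &
                map$dt_axis <= peak$dtc + peak$dtw / 2)
  vapply(seq_along(target$envelope$offsets_da), function(k) {
    mzk <- target$target_mz + target$envelope$offsets_da[k]
    tol <- ppm_strip * 1e-6 * mzk
    cols <- which(abs(map$mz_axis - mzk) <= tol)
    if (!length(rows) || !length(cols)) 0 else
      sum(map$intensities[rows, cols])
  }, numeric(1))
}

#' Score detected peaks against a target
#'
#' Attaches `shape_score`, `isotopic_score`, `rel_intensity` (summed
#' intensity relative to the most abundant peak in the same window) and
#' `mass_error_ppm` to each peak. Peaks whose arrival-time profile is too
#' sparse for the shape statistic receive a shape score of 0.
#'
#' @param peaks List of `peak2d` from one field's extraction window.
#' @param map The field's full averaged `intensity_map`.
#' @param target A `ccs_target`.
#' @param ppm_strip Isotopomer strip half-width in ppm (default 15).
#' @return The peak list with score fields filled in.
#' @export
score_peaks <- function(peaks, map, target, ppm_strip = 15) {
  if (!length(peaks)) return(peaks)
  max_sum <- max(vapply(peaks, `[[`, numeric(1), "summed_intensity"))
  lapply(peaks, function(p) {
    p$shape_score <- tryCatch(shape_score(p), error = function(e) 0)
    obs <- observed_envelope(map, target, p, ppm_strip)
    p$isotopic_score <- tryCatch(
      isotopic_score(obs, target$envelope), error = function(e) 0)
    p$rel_intensity <- p$summed_intensity / max_sum
    p$mass_error_ppm <- (p$mzc - target$target_mz) / target$target_mz * 1e6
    p
  })
}

#' Pre-filter scored peaks
#'
#' Keeps exactly the peaks passing all three bounds: shape score, isotopic
#' score, and relative summed intensity within the extraction window (the
#' latter discards peaks below a few percent of the most abundant peak, to
#' avoid reporting spurious conformers).
#'
#' @param peaks List of scored `peak2d`.
#' @param min_shape Minimum shape score (default 0.4).
#' @param min_isotopic Minimum isotopic score (default 0.4).
#' @param min_rel_intensity Minimum relative intensity (default 0.03).
#' @return The surviving subset, order preserved.
#' @export
prefilter <- function(peaks, min_shape = 0.4, min_isotopic = 0.4,
                      min_rel_intensity = 0.03) {
  Filter(function(p) {
    p$shape_score >= min_shape && p$isotopic_score >= min_isotopic &&
      p$rel_intensity >= min_rel_intensity
  }, peaks)
}
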