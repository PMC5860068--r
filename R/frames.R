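#' Instrument conditions
#'
#' Static acquisition geometry and buffer-gas description. Internal units
#' throughout the package: length in cm, voltage in V, pressure in torr,
#' temperature in K, time in ms, reduced mobility in cm^2 V^-1 s^-1.
#'
#' @param drift_length_cm Drift-tube length (cm).
#' @param gas_mass_da Buffer-gas molecular mass (Da); default nitrogen.
#' @param default_temperature_K,default_pressure_torr Fallback drift-gas
#'   conditions used when a frame does not carry its own.
#' @return Object of class `instrument_conditions`.
#' @export
instrument_conditions <- function(drift_length_cm,
                                  gas_mass_da = 28.0134,
                                  default_temperature_K = 300,
                                  default_pressure_torr = 4) {
  vals <- c(drift_length_cm, gas_mass_da, default_temperature_K,
            default_pressure_torr)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("instrument conditions must all be strictly positive",
         call. = FALSE)
  }
  structure(list(drift_length_cm = drift_length_cm,
                 gas_mass_da = gas_mass_da,
                 default_temperature_K = default_temperature_K,
                 default_pressure_torr = default_pressure_torr),
            class = "instrument_conditions")
}

#' Construct a single IMS frame
#'
#' A frame is one mobility acquisition cycle at a fixed drift voltage. Scans
#' are stored sparsely: each scan is a list with `arrival_time_ms`, `mz`
#' (numeric vector) and `intensity` (non-negative numeric vector of equal
#' length). Scans must be ordered by strictly increasing arrival time.
#'
#' @param frame_id Integer id.
#' @param drift_voltage_V Drift voltage (V), > 0.
#' @param pressure_torr,temperature_K Per-frame drift-gas conditions.
#' @param scans List of scans as described above (possibly empty).
#' @return Object of class `ims_frame`.
#' @export
ims_frame <- function(frame_id, drift_voltage_V, pressure_torr,
                      temperature_K, scans = list()) {
  if (!is.finite(drift_voltage_V) || drift_voltage_V <= 0) {
    stop("drift_voltage_V must be positive", call. = FALSE)
  }
  if (!is.finite(pressure_torr) || !is.finite(temperature_K)) {
    stop("frame pressure/temperature must be finite", call. = FALSE)
  }
  at <- vapply(scans, function(s) s$arrival_time_ms, numeric(1))
  if (length(at) > 1L && any(diff(at) <= 0)) {
    stop("scan arrival times must be strictly increasing", call. = FALSE)
  }
  for (s in scans) {
    if (length(s$mz) != length(s$intensity)) {
      stop("scan mz and intensity lengths differ", call. = FALSE)
    }
    if (length(s$intensity) && any(s$intensity < 0)) {
      stop("intensities must be non-negative", call. = FALSE)
    }
  }
  structure(list(frame_id = as.integer(frame_id),
                 drift_voltage_V = drift_voltage_V,
                 pressure_torr = pressure_torr,
                 temperature_K = temperature_K,
                 scans = scans),
            class = "ims_frame")
}

#' Construct a frame set
#'
#' A frame set bundles the frames of one multi-field acquisition with the
#' instrument conditions and the shared m/z / arrival-time calibration axes
#' onto which sparse scans are rasterised.
#'
#' @param conditions An `instrument_conditions` object.
#' @param frames Non-empty list of `ims_frame` objects.
#' @param mz_axis Strictly increasing vector of m/z bin centers (Da).
#' @param dt_axis Strictly increasing vector of arrival-time bin centers
#'   (ms).
#' @return Object of class `frame_set`.
#' @export
frame_set <- function(conditions, frames, mz_axis, dt_axis) {
  stopifnot(inherits(conditions, "instrument_conditions"))
  if (length(frames) < 1L) stop("frame set needs at least one frame",
                                call. = FALSE)
  if (length(mz_axis) < 1L || any(diff(mz_axis) <= 0)) {
    stop("mz_axis must be strictly increasing", call. = FALSE)
  }
  if (length(dt_axis) < 1L || any(diff(dt_axis) <= 0)) {
    stop("dt_axis must be strictly increasing", call. = FALSE)
  }
  step <- .axis_step(mz_axis)
  lo <- mz_axis[1] - step
  hi <- mz_axis[length(mz_axis)] + step
  for (fr in frames) {
    for (s in fr$scans) {
      if (length(s$mz) && (s$mz[1] < lo || s$mz[length(s$mz)] > hi ||
                           min(s$mz) < lo || max(s$mz) > hi)) {
        stop("frame ", fr$frame_id, " has m/z values outside the shared ",
             "mz_axis", call. = FALSE)
      }
    }
  }
  structure(list(conditions = conditions, frames = frames,
                 mz_axis = mz_axis, dt_axis = dt_axis),
            class = "frame_set")
}

.axis_step <- function(axis) {
  if (length(axis) > 1L) min(diff(axis)) else 1
}

#' Dense intensity map
#'
#' @param mz_axis,dt_axis Strictly increasing bin-center vectors.
#' @param intensities Matrix with `length(dt_axis)` rows and
#'   `length(mz_axis)` columns, non-negative.
#' @return Object of class `intensity_map`.
#' @export
intensity_map <- function(mz_axis, dt_axis, intensities) {
  stopifnot(is.matrix(intensities),
            nrow(intensities) == length(dt_axis),
            ncol(intensities) == length(mz_axis))
  if (any(diff(mz_axis) <= 0) || any(diff(dt_axis) <= 0)) {
    stop("axes must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be non-negative",
                                 call. = FALSE)
  structure(list(mz_axis = mz_axis, dt_axis = dt_axis,
                 intensities = intensities),
            class = "intensity_map")
}

# nearest-bin index lookup onto a (not necessarily uniform) axis
.bin_index <- function(values, axis) {
  idx <- findInterval(values, axis, all.inside = TRUE)
  up <- idx < length(axis) &
    (values - axis[idx]) > (axis[idx + 1L] - values)
  idx[up] <- idx[up] + 1L
  idx
}

#' Rasterise one frame onto the shared axes
#'
#' Sparse scans are binned to the nearest arrival-time and m/z bin centers;
#' values mapping to the same bin accumulate.
#'
#' @param frame An `ims_frame`.
#' @param mz_axis,dt_axis Shared axes (typically from the `frame_set`).
#' @return An `intensity_map`.
#' @export
rasterize_frame <- function(frame, mz_axis, dt_axis) {
  mat <- matrix(0, nrow = length(dt_axis), ncol = length(mz_axis))
  tr <- .frame_triplets(frame, mz_axis, dt_axis)
  mat[tr$lin] <- tr$vals
  intensity_map(mz_axis, dt_axis, mat)
}

# one frame's sparse scans as deduplicated (linear index, value) pairs on
# the dense dt x mz grid
.frame_triplets <- function(frame, mz_axis, dt_axis) {
  lens <- vapply(frame$scans, function(s) length(s$mz), integer(1))
  keep <- lens > 0L
  if (!any(keep)) return(list(lin = integer(0), vals = numeric(0)))
  at <- vapply(frame$scans, function(s) s$arrival_time_ms,
               numeric(1))[keep]
  rows <- rep(.bin_index(at, dt_axis), lens[keep])
  cols <- .bin_index(unlist(lapply(frame$scans[keep], `[[`, "mz"),
                            use.names = FALSE), mz_axis)
  vals <- as.numeric(unlist(lapply(frame$scans[keep], `[[`, "intensity"),
                            use.names = FALSE))
  lin <- (cols - 1L) * length(dt_axis) + rows
  if (anyDuplicated(lin)) {
    agg <- rowsum(vals, lin, reorder = FALSE)
    lin <- as.integer(rownames(agg))
    vals <- agg[, 1L]
  }
  list(lin = lin, vals = vals)
}

#' Group frames by electric field
#'
#' Frames are clustered on drift voltage by single linkage with tolerance
#' `voltage_tol_V`: sorted voltages are split wherever the gap between
#' neighbours exceeds the tolerance. Groups are returned in order of
#' descending voltage and indexed 1..n by descending field; per-group
#' voltage, pressure and temperature are arithmetic means over member
#' frames, and the regression abscissa `x_value = p / (T V)` is attached.
#'
#' @param frameset A `frame_set`.
#' @param voltage_tol_V Single-linkage tolerance in volts (default 0.5).
#' @return List of `field_group` objects, each with `field_index`,
#'   `drift_voltage_V`, `electric_field_Vcm`, `pressure_torr`,
#'   `temperature_K`, `x_value`, and `frame_ids` (positions into
#'   `frameset$frames`).
#' @export
group_by_field <- function(frameset, voltage_tol_V = 0.5) {
  stopifnot(inherits(frameset, "frame_set"), voltage_tol_V >= 0)
  volts <- vapply(frameset$frames, function(f) f$drift_voltage_V, numeric(1))
  ord <- order(volts)
  breaks <- which(diff(volts[ord]) > voltage_tol_V)
  cluster <- integer(length(volts))
  cluster[ord] <- findInterval(seq_along(ord), breaks + 0.5) + 1L
  means <- tapply(volts, cluster, mean)
  # rank clusters by descending mean voltage -> field_index
  rank_desc <- rank(-means, ties.method = "first")
  groups <- vector("list", length(means))
  for (cl in seq_along(means)) {
    members <- which(cluster == cl)
    p <- mean(vapply(frameset$frames[members],
                     function(f) f$pressure_torr, numeric(1)))
    tk <- mean(vapply(frameset$frames[members],
                      function(f) f$temperature_K, numeric(1)))
    v <- means[[cl]]
    groups[[rank_desc[cl]]] <- structure(list(
      field_index = as.integer(rank_desc[cl]),
      drift_voltage_V = v,
      electric_field_Vcm = v / frameset$conditions$drift_length_cm,
      pressure_torr = p,
      temperature_K = tk,
      x_value = p / (tk * v),
      frame_ids = members
    ), class = "field_group")
  }
  groups
}

#' Average the member frames of a field group
#'
#' Element-wise arithmetic mean of the rasterised member frames; averaging
#' the repeated frames collected at one field raises the signal-to-noise
#' ratio before peak detection.
#'
#' @param frameset A `frame_set`.
#' @param group A `field_group` from [group_by_field()], or an integer
#'   vector of frame positions.
#' @return An `intensity_map`.
#' @export
average_group <- function(frameset, group) {
  ids <- if (inherits(group, "field_group")) group$frame_ids else group
  if (length(ids) < 1L) stop("empty group", call. = FALSE)
  acc <- matrix(0, nrow = length(frameset$dt_axis),
                ncol = length(frameset$mz_axis))
  for (i in ids) {
    tr <- .frame_triplets(frameset$frames[[i]], frameset$mz_axis,
                          frameset$dt_axis)
    acc[tr$lin] <- acc[tr$lin] + tr$vals
  }
  intensity_map(frameset$mz_axis, frameset$dt_axis, acc / length(ids))
}
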