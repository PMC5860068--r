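# Arrival time across fields follows a straight line in x = p/(TV):
#   t_A[s] = (l^2 / K0) * (273.15 / 760) * p / (T V) + t0
# with l in cm and K0 in cm^2 V^-1 s^-1 (the cm^2 cancel), so
#   slope[s-units] = l^2 * 273.15 / (760 * K0).
# The package carries t in ms; the ms <-> s conversion happens exactly here.
.slope_ms_from_K0 <- function(K0, drift_length_cm) {
  1000 * drift_length_cm^2 * 273.15 / (760 * K0)
}

.K0_from_slope_ms <- function(slope_ms, drift_length_cm) {
  drift_length_cm^2 * 273.15 / (760 * (slope_ms / 1000))
}

#' Fit the multi-field mobility line
#'
#' Fits `t_A = slope * x + t0` with `x = p/(TV)` across the electric fields
#' of one ion path, and converts the slope to the reduced mobility `K0`
#' (standardised to 273.15 K and 760 torr by the `273.15/760` factor built
#' into the line model). Ordinary least squares is the default; iteratively
#' reweighted least squares with the bisquare weight (tuning constant 4.685
#' on a MAD-based robust scale, at most 50 iterations, convergence at 1e-10)
#' is available to resist occasional gross apex-picking errors.
#'
#' @param t_ms Arrival times at the peak apex (ms), one per field.
#' @param x Abscissa values `p/(TV)` (torr K^-1 V^-1), same length.
#' @param drift_length_cm Drift-tube length (cm).
#' @param method `"ols"` or `"irls_bisquare"`.
#' @return Object of class `mobility_fit` with fields `slope_ms`,
#'   `intercept_t0_ms`, `r_squared`, `K0`, `method`, `n_points`,
#'   `residuals_ms`, `weights`.
#' @export
fit_mobility <- function(t_ms, x, drift_length_cm,
                         method = c("ols", "irls_bisquare")) {
  method <- match.arg(method)
  if (length(t_ms) != length(x)) stop("t_ms and x lengths differ",
                                      call. = FALSE)
  if (length(x) < 3L) {
    stop("mobility fit needs at least 3 points, got ", length(x),
         call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("degenerate fit: all x values identical",
                              call. = FALSE)
  df <- data.frame(t = t_ms, x = x)
  if (method == "ols") {
    fit <- stats::lm(t ~ x, data = df)
    slope <- unname(stats::coef(fit)[2])
    t0 <- unname(stats::coef(fit)[1])
    res <- unname(stats::residuals(fit))
    sst <- sum((t_ms - mean(t_ms))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    w <- rep(1, length(x))
  } else {
    # an (essentially) exact line defeats the MAD scale estimate; the
    # bisquare solution coincides with OLS there, so short-circuit
    pre <- stats::lm(t ~ x, data = df)
    if (max(abs(stats::residuals(pre))) <=
        1e-10 * max(abs(t_ms - mean(t_ms)), 1e-300)) {
      slope <- unname(stats::coef(pre)[2])
      return(structure(list(
        slope_ms = slope, intercept_t0_ms = unname(stats::coef(pre)[1]),
        r_squared = 1,
        K0 = if (is.finite(slope) && slope > 0) {
          .K0_from_slope_ms(slope, drift_length_cm)
        } else NA_real_,
        method = method, n_points = length(x),
        residuals_ms = unname(stats::residuals(pre)),
        weights = rep(1, length(x))), class = "mobility_fit"))
    }
    fit <- MASS::rlm(t ~ x, data = df, psi = MASS::psi.bisquare,
                     c = 4.685, maxit = 50, acc = 1e-10)
    slope <- unname(stats::coef(fit)[2])
    t0 <- unname(stats::coef(fit)[1])
    w <- unname(fit$w)
    res <- unname(stats::residuals(fit))
    # R^2 against the final weighted fit
    ybar <- sum(w * t_ms) / sum(w)
    sst <- sum(w * (t_ms - ybar)^2)
    r2 <- if (sst > 0) 1 - sum(w * res^2) / sst else 1
  }
  K0 <- if (is.finite(slope) && slope > 0) {
    .K0_from_slope_ms(slope, drift_length_cm)
  } else NA_real_
  structure(list(slope_ms = slope, intercept_t0_ms = t0, r_squared = r2,
                 K0 = K0, method = method, n_points = length(x),
                 residuals_ms = res, weights = w),
            class = "mobility_fit")
}

#' Predict arrival times from a mobility fit
#'
#' @param fit A `mobility_fit`.
#' @param x Abscissa values `p/(TV)`.
#' @return Predicted arrival times (ms).
#' @export
predict_arrival <- function(fit, x) {
  fit$slope_ms * x + fit$intercept_t0_ms
}

#' Collision cross section from reduced mobility (Mason-Schamp)
#'
#' Inverts the low-field Mason-Schamp relation
#' `K0 = (3 q / 16 N0) * sqrt(2 pi / (mu kB T)) / Omega` for the momentum
#' transfer collision integral Omega. Because `K0` is already standardised
#' to 273.15 K / 760 torr, the buffer-gas density is the Loschmidt number
#' `N0`; `T` is the drift-gas temperature.
#'
#' @param K0 Reduced mobility (cm^2 V^-1 s^-1).
#' @param ion_mass_da Ion mass (Da).
#' @param charge Absolute charge number `|z|` (default 1).
#' @param gas_mass_da Buffer-gas molecular mass (Da, default nitrogen).
#' @param temperature_K Drift-gas temperature (K).
#' @return Omega in square Angstroms.
#' @examples
#' compute_ccs(1.3930, 205.0977, 1, 28.0134, 300)
#' @export
compute_ccs <- function(K0, ion_mass_da, charge = 1, gas_mass_da = 28.0134,
                        temperature_K = 300) {
  args <- c(K0, ion_mass_da, charge, gas_mass_da, temperature_K)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("compute_ccs arguments must be positive and finite", call. = FALSE)
  }
  pc <- physical_constants
  mu <- ion_mass_da * gas_mass_da / (ion_mass_da + gas_mass_da) * pc$amu_kg
  K0_SI <- K0 * 1e-4  # cm^2/(V s) -> m^2/(V s)
  omega_m2 <- 3 * charge * pc$e_C / (16 * pc$N0_per_m3 * K0_SI) *
    sqrt(2 * pi / (mu * pc$kB_J_per_K * temperature_K))
  omega_m2 * 1e20
}

#' Reduced mobility from a collision cross section
#'
#' Algebraic inverse of [compute_ccs()].
#'
#' @param ccs_A2 Omega in square Angstroms.
#' @inheritParams compute_ccs
#' @return K0 in cm^2 V^-1 s^-1.
#' @export
mobility_from_ccs <- function(ccs_A2, ion_mass_da, charge = 1,
                              gas_mass_da = 28.0134, temperature_K = 300) {
  args <- c(ccs_A2, ion_mass_da, charge, gas_mass_da, temperature_K)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("mobility_from_ccs arguments must be positive and finite",
         call. = FALSE)
  }
  pc <- physical_constants
  mu <- ion_mass_da * gas_mass_da / (ion_mass_da + gas_mass_da) * pc$amu_kg
  K0_SI <- 3 * charge * pc$e_C / (16 * pc$N0_per_m3 * (ccs_A2 * 1e-20)) *
    sqrt(2 * pi / (mu * pc$kB_J_per_K * temperature_K))
  K0_SI * 1e4
}

#' Post-filter accepted ion records
#'
#' Applies the user-facing acceptance bounds on mass error, isotopic score,
#' path a posteriori probability and fit linearity to a list of CCS records
#' (as produced by [run_analysis()]). Rejection reasons are reported per
#' record.
#'
#' @param records List of `ccs_record` objects.
#' @param max_ppm Maximum absolute mass error (ppm, default 15).
#' @param min_isotopic Minimum mean isotopic score (default 0.4).
#' @param min_posterior Minimum path a posteriori probability `P(T_k)`
#'   (default 0, i.e. disabled).
#' @param min_r2 Minimum fit R^2 (default 0.96).
#' @return List with `accepted` (list of records), `rejected` (list of
#'   records) and `reasons` (character vector parallel to `rejected`, with
#'   comma-separated failed bounds).
#' @export
postfilter <- function(records, max_ppm = 15, min_isotopic = 0.4,
                       min_posterior = 0, min_r2 = 0.96) {
  accepted <- list(); rejected <- list(); reasons <- character(0)
  for (rec in records) {
    why <- character(0)
    if (!is.finite(rec$mass_error_ppm) || abs(rec$mass_error_ppm) > max_ppm)
      why <- c(why, "mass_error")
    if (!is.finite(rec$isotopic_score) || rec$isotopic_score < min_isotopic)
      why <- c(why, "isotopic_score")
    if (!is.finite(rec$posterior) || rec$posterior < min_posterior)
      why <- c(why, "posterior")
    if (!is.finite(rec$r_squared) || rec$r_squared < min_r2)
      why <- c(why, "r_squared")
    if (length(why)) {
      rejected[[length(rejected) + 1L]] <- rec
      reasons <- c(reasons, paste(why, collapse = ","))
    } else {
      accepted[[length(accepted) + 1L]] <- rec
    }
  }
  list(accepted = accepted, rejected = rejected, reasons = reasons)
}
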