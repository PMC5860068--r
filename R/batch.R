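#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default:
#' extraction window 250 ppm, post-filter mass error 15 ppm, shape and
#' isotopic score thresholds 0.4, relative intensity threshold 3 percent,
#' K-shortest-path budget 3000, artifact probability 0.1, minimum 3 fields
#' per path, OLS fitting, 0.5 V voltage grouping tolerance, minimum fit
#' R^2 of 0.96.
#'
#' @param ppm_window Extraction window half-width (ppm).
#' @param max_ppm Post-filter mass error bound (ppm).
#' @param min_shape,min_isotopic,min_rel_intensity Pre-filter thresholds.
#' @param max_K K-shortest-path enumeration budget.
#' @param delta Artifact probability.
#' @param min_fields Minimum fields per ion path.
#' @param fit_method `"ols"` or `"irls_bisquare"`.
#' @param voltage_tol Field-grouping tolerance (V).
#' @param n_isotopomers Envelope length for targets.
#' @param ppm_strip Isotopomer integration strip half-width (ppm).
#' @param sigma_t_rel Relative arrival-time tolerance of the peak
#'   likelihood.
#' @param w_r Weight of the R^2 term in the path probability.
#' @param max_conformers Maximum disjoint paths per hypothesis.
#' @param start_penalty Source/sink edge weight.
#' @param match Diffusion-match parameters ([match_params()]).
#' @param min_r2,min_posterior Post-filter bounds.
#' @param smooth_sigma,footprint_frac Peak-detector parameters.
#' @return Object of class `ccs_config` (a named list).
#' @export
ccs_config <- function(ppm_window = 250, max_ppm = 15,
                       min_shape = 0.4, min_isotopic = 0.4,
                       min_rel_intensity = 0.03,
                       max_K = 3000L, delta = 0.1, min_fields = 3L,
                       fit_method = c("ols", "irls_bisquare"),
                       voltage_tol = 0.5, n_isotopomers = 5L,
                       ppm_strip = 15, sigma_t_rel = 0.02, w_r = 0.5,
                       max_conformers = 4L, start_penalty = -log(0.5),
                       match = match_params(),
                       min_r2 = 0.96, min_posterior = 0,
                       smooth_sigma = 1, footprint_frac = 0.1) {
  fit_method <- match.arg(fit_method)
  structure(list(
    ppm_window = ppm_window, max_ppm = max_ppm, min_shape = min_shape,
    min_isotopic = min_isotopic, min_rel_intensity = min_rel_intensity,
    max_K = as.integer(max_K), delta = delta,
    min_fields = as.integer(min_fields), fit_method = fit_method,
    voltage_tol = voltage_tol, n_isotopomers = as.integer(n_isotopomers),
    ppm_strip = ppm_strip, sigma_t_rel = sigma_t_rel, w_r = w_r,
    max_conformers = as.integer(max_conformers),
    start_penalty = start_penalty, match = match,
    min_r2 = min_r2, min_posterior = min_posterior,
    smooth_sigma = smooth_sigma, footprint_frac = footprint_frac
  ), class = "ccs_config")
}

#' Load an analysis configuration from a JSON or YAML file
#'
#' Keys mirror the arguments of [ccs_config()]; unknown keys error, absent
#' keys keep their defaults. `overrides` (e.g. from command-line flags)
#' take precedence over the file.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list applied last.
#' @return A `ccs_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required for YAML configs", call. = FALSE)
      }
      yaml::read_yaml(path)
    } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(ccs_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(ccs_config, vals)
}

#' Analyse one target against one frame set
#'
#' Runs the full pipeline: field grouping and averaging, per-field window
#' extraction, peak detection, scoring and pre-filtering, ion transition
#' graph construction, K-shortest-path enumeration, MAP hypothesis
#' selection, per-path mobility fit and CCS calculation, and post-
#' filtering. One CCS record is produced per path (conformer) of the
#' optimal hypothesis.
#'
#' @param frameset A `frame_set`.
#' @param target A `ccs_target`.
#' @param config A `ccs_config`.
#' @param prepared Optional [field_maps()] result, so batch runs average
#'   each dataset once across its targets.
#' @return Object of class `ccs_analysis` with `status` (`"ok"`,
#'   `"no_peaks"`, `"insufficient_fields"` or `"rejected"`), `records`
#'   (all CCS records, each carrying `accepted` and `reject_reason`),
#'   `accepted` (the accepted subset), `hypothesis`, `peaks_by_field`,
#'   `field_peak_counts` and `groups`.
#' @export
run_analysis <- function(frameset, target, config = ccs_config(),
                         prepared = NULL) {
  stopifnot(inherits(frameset, "frame_set"), inherits(target, "ccs_target"))
  if (is.null(prepared)) prepared <- field_maps(frameset,
                                                config$voltage_tol)
  groups <- prepared$groups
  peaks_by_field <- vector("list", length(groups))
  counts <- integer(length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    map <- prepared$maps[[gi]]
    window <- tryCatch(
      extract_window(map, target$target_mz, config$ppm_window),
      error = function(e) NULL)
    if (is.null(window)) {
      peaks_by_field[[gi]] <- list()
      next
    }
    pk <- detect_peaks(window, field_index = g$field_index,
                       smooth_sigma = config$smooth_sigma,
                       footprint_frac = config$footprint_frac)
    pk <- score_peaks(pk, map, target, config$ppm_strip)
    pk <- prefilter(pk, config$min_shape, config$min_isotopic,
                    config$min_rel_intensity)
    pk <- lapply(pk, function(p) {
      p$x_value <- g$x_value
      p$drift_voltage_V <- g$drift_voltage_V
      p$temperature_K <- g$temperature_K
      p
    })
    counts[gi] <- length(pk)
    peaks_by_field[[gi]] <- pk
  }
  done <- function(status, hyp = NULL, records = list(),
                   accepted = list()) {
    structure(list(status = status, target = target, records = records,
                   accepted = accepted, hypothesis = hyp,
                   peaks_by_field = peaks_by_field,
                   field_peak_counts = counts, groups = groups),
              class = "ccs_analysis")
  }
  if (sum(counts) == 0L) return(done("no_peaks"))
  if (sum(counts > 0L) < config$min_fields) {
    return(done("insufficient_fields"))
  }
  graph <- build_graph(peaks_by_field, config$match, config$min_fields,
                       config$start_penalty)
  paths <- k_shortest_paths(graph, config$max_K, config$min_fields)
  hyp <- select_optimal(paths, graph$peaks,
                        frameset$conditions$drift_length_cm,
                        method = config$fit_method, w_r = config$w_r,
                        sigma_t_rel = config$sigma_t_rel,
                        delta = config$delta,
                        max_conformers = config$max_conformers)
  if (!length(hyp$paths)) return(done("no_peaks", hyp))
  charge <- abs(target$adduct$charge)
  records <- lapply(hyp$paths, function(p) {
    temp <- mean(vapply(p$peaks, `[[`, numeric(1), "temperature_K"))
    ccs <- if (is.finite(p$fit$K0)) {
      compute_ccs(p$fit$K0, target$target_mz * charge, charge,
                  frameset$conditions$gas_mass_da, temp)
    } else NA_real_
    structure(list(
      name = target$name, formula = format_formula(target$formula),
      adduct = target$adduct$kind, mz = target$target_mz,
      K0 = p$fit$K0, t0_ms = p$fit$intercept_t0_ms, ccs_A2 = ccs,
      r_squared = p$fit$r_squared,
      mass_error_ppm = mean(vapply(p$peaks, `[[`, numeric(1),
                                   "mass_error_ppm")),
      isotopic_score = mean(vapply(p$peaks, `[[`, numeric(1),
                                   "isotopic_score")),
      shape_score = mean(vapply(p$peaks, `[[`, numeric(1),
                                "shape_score")),
      posterior = p$p_path, log_posterior = hyp$log_posterior,
      n_points = p$fit$n_points, path = p
    ), class = "ccs_record")
  })
  pf <- postfilter(records, config$max_ppm, config$min_isotopic,
                   config$min_posterior, config$min_r2)
  records <- c(
    lapply(pf$accepted, function(r) { r$accepted <- TRUE
      r$reject_reason <- ""; r }),
    mapply(function(r, why) { r$accepted <- FALSE
      r$reject_reason <- why; r },
      pf$rejected, pf$reasons, SIMPLIFY = FALSE))
  status <- if (length(pf$accepted)) "ok" else "rejected"
  done(status, hyp, records, accepted = Filter(function(r) r$accepted,
                                               records))
}

#' Group a frame set by field and average each group
#'
#' Convenience wrapper around [group_by_field()] and [average_group()];
#' the result can be fed to repeated [run_analysis()] calls on the same
#' dataset.
#'
#' @param frameset A `frame_set`.
#' @param voltage_tol Field-grouping tolerance (V).
#' @return List with `groups` (field groups) and `maps` (their averaged
#'   `intensity_map`s, same order).
#' @export
field_maps <- function(frameset, voltage_tol = 0.5) {
  groups <- group_by_field(frameset, voltage_tol)
  list(groups = groups,
       maps = lapply(groups, function(g) average_group(frameset, g)))
}

.store_schema <- c(
  "CREATE TABLE chemical_targets (target_id INTEGER PRIMARY KEY,
     name TEXT, formula TEXT, adduct TEXT, mz REAL)",
  "CREATE TABLE datasets (dataset_id INTEGER PRIMARY KEY, path TEXT)",
  "CREATE TABLE analyses (analysis_id INTEGER PRIMARY KEY,
     dataset_id INTEGER, target_id INTEGER, status TEXT,
     log_posterior REAL, n_candidate_paths INTEGER,
     field_peak_counts TEXT, params_json TEXT)",
  "CREATE TABLE detected_ions (ion_id INTEGER PRIMARY KEY,
     analysis_id INTEGER, dataset_id INTEGER, target_id INTEGER,
     K0 REAL, t0_ms REAL, ccs_A2 REAL, r_squared REAL,
     mass_error_ppm REAL, isotopic_score REAL, shape_score REAL,
     posterior REAL, accepted INTEGER, n_points INTEGER)",
  "CREATE TABLE peaks (peak_id INTEGER PRIMARY KEY,
     analysis_id INTEGER, field_index INTEGER, mzc REAL, mzw REAL,
     mzl REAL, dtc REAL, dtw REAL, dtl REAL, base_intensity REAL,
     summed_intensity REAL, shape_score REAL, isotopic_score REAL,
     rel_intensity REAL, mass_error_ppm REAL, assignment INTEGER)")

#' Batch-process targets against datasets into a results store
#'
#' Runs every (dataset, target) analysis and aggregates everything into a
#' single-file relational results store (SQLite format) with tables
#' `chemical_targets`, `datasets`, `analyses`, `detected_ions` and
#' `peaks`. A failing analysis records its status and the batch continues;
#' an unreadable dataset is logged and skipped. Analyses run sequentially
#' in deterministic order, so reruns on identical inputs produce identical
#' stores.
#'
#' @param targets List of `ccs_target`, or the path of a target list file
#'   (see [read_target_list()]).
#' @param datasets Character vector of frame store paths, or a named list
#'   of `frame_set` objects.
#' @param store_path Output store path (overwritten).
#' @param config A `ccs_config`.
#' @return `store_path`, invisibly.
#' @export
run_batch <- function(targets, datasets, store_path,
                      config = ccs_config()) {
  if (is.character(targets)) {
    targets <- read_target_list(targets, config$n_isotopomers)
  }
  if (file.exists(store_path)) unlink(store_path)
  con <- DBI::dbConnect(RSQLite::SQLite(), store_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (sql in .store_schema) DBI::dbExecute(con, sql)
  params_json <- as.character(jsonlite::toJSON(
    config[setdiff(names(config), "match")], auto_unbox = TRUE,
    digits = NA))
  for (ti in seq_along(targets)) {
    t <- targets[[ti]]
    DBI::dbExecute(con,
      "INSERT INTO chemical_targets VALUES (?, ?, ?, ?, ?)",
      params = list(ti, t$name, format_formula(t$formula),
                    t$adduct$kind, t$target_mz))
  }
  ds_names <- if (is.character(datasets)) datasets else {
    if (is.null(names(datasets))) paste0("dataset_", seq_along(datasets))
    else names(datasets)
  }
  for (di in seq_along(datasets)) {
    DBI::dbExecute(con, "INSERT INTO datasets VALUES (?, ?)",
                   params = list(di, ds_names[di]))
  }
  analysis_id <- 0L; ion_id <- 0L; peak_id <- 0L
  for (di in seq_along(datasets)) {
    fs <- tryCatch({
      if (is.character(datasets)) read_frames(datasets[di]) else
        datasets[[di]]
    }, error = function(e) {
      warning("skipping dataset ", ds_names[di], ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(fs)) next
    prepared <- field_maps(fs, config$voltage_tol)
    for (ti in seq_along(targets)) {
      res <- tryCatch(run_analysis(fs, targets[[ti]], config, prepared),
                      error = function(e) e)
      analysis_id <- analysis_id + 1L
      if (inherits(res, "error")) {
        DBI::dbExecute(con,
          "INSERT INTO analyses VALUES (?, ?, ?, ?, ?, ?, ?, ?)",
          params = list(analysis_id, di, ti,
                        paste0("error: ", conditionMessage(res)),
                        NA_real_, NA_integer_, "", params_json))
        next
      }
      DBI::dbExecute(con,
        "INSERT INTO analyses VALUES (?, ?, ?, ?, ?, ?, ?, ?)",
        params = list(
          analysis_id, di, ti, res$status,
          if (is.null(res$hypothesis)) NA_real_ else
            res$hypothesis$log_posterior,
          length(res$records),
          paste(res$field_peak_counts, collapse = ","), params_json))
      for (rec in res$records) {
        ion_id <- ion_id + 1L
        DBI::dbExecute(con, paste(
          "INSERT INTO detected_ions VALUES",
          "(?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?)"),
          params = list(ion_id, analysis_id, di, ti, rec$K0, rec$t0_ms,
                        rec$ccs_A2, rec$r_squared, rec$mass_error_ppm,
                        rec$isotopic_score, rec$shape_score,
                        rec$posterior, as.integer(rec$accepted),
                        rec$n_points))
      }
      if (!is.null(res$hypothesis)) {
        flat <- unlist(res$peaks_by_field, recursive = FALSE)
        for (pi in seq_along(flat)) {
          p <- flat[[pi]]
          peak_id <- peak_id + 1L
          DBI::dbExecute(con, paste(
            "INSERT INTO peaks VALUES",
            "(?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?)"),
            params = list(peak_id, analysis_id, p$field_index, p$mzc,
                          p$mzw, p$mzl, p$dtc, p$dtw, p$dtl,
                          p$base_intensity, p$summed_intensity,
                          p$shape_score, p$isotopic_score,
                          p$rel_intensity, p$mass_error_ppm,
                          res$hypothesis$assignments[pi]))
        }
      }
    }
  }
  invisible(store_path)
}

#' Export an accurate-mass and CCS library from a results store
#'
#' Selects detected ions passing the post-filter bounds with a relational
#' query (so that database-side threshold queries and [postfilter()] agree
#' row for row) and writes a CSV library. Output ordering and formatting
#' are deterministic: identical stores yield byte-identical files.
#'
#' @param store_path Results store from [run_batch()].
#' @param path Output CSV path.
#' @param max_ppm,min_isotopic,min_posterior,min_r2 Post-filter bounds
#'   (defaults as in [postfilter()]).
#' @return The exported data frame, invisibly.
#' @export
export_library <- function(store_path, path, max_ppm = 15,
                           min_isotopic = 0.4, min_posterior = 0,
                           min_r2 = 0.96) {
  con <- DBI::dbConnect(RSQLite::SQLite(), store_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  df <- DBI::dbGetQuery(con, paste(
    "SELECT t.name, t.formula, t.adduct, t.mz, i.K0, i.ccs_A2, i.t0_ms,",
    "i.r_squared, i.isotopic_score, i.mass_error_ppm, i.posterior",
    "FROM detected_ions i JOIN chemical_targets t",
    "ON i.target_id = t.target_id",
    "WHERE ABS(i.mass_error_ppm) <= ? AND i.isotopic_score >= ?",
    "AND i.posterior >= ? AND i.r_squared >= ?",
    "ORDER BY i.ion_id"),
    params = list(max_ppm, min_isotopic, min_posterior, min_r2))
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.10g", out[[nm]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(df)
}
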