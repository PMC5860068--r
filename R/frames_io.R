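#' Read a multi-field frame store
#'
#' Two dialects are supported. `"framestore"` is a single-file relational
#' store (SQLite file format) with tables `global_params(key, value)`,
#' `frame_params(frame_id, drift_voltage_v, pressure_torr, temperature_k)`
#' and `frame_scans(frame_id, scan_index, arrival_time_ms, mz_blob,
#' intensity_blob)`; blobs hold little-endian float64 (m/z) and int64
#' (intensity counts) arrays of equal length. `"csv"` is a long-format
#' fixture dialect with columns `frame_id, drift_voltage_v, pressure_torr,
#' temperature_k, arrival_time_ms, mz, intensity`; since CSV carries no
#' calibration block, instrument conditions come from the `conditions`
#' argument and the axes are inferred from the observed values.
#'
#' @param path File path.
#' @param dialect `"framestore"` (default) or `"csv"`.
#' @param conditions `instrument_conditions` used for the CSV dialect
#'   (ignored for framestore, which embeds them).
#' @return A `frame_set`.
#' @export
read_frames <- function(path, dialect = c("framestore", "csv"),
                        conditions = instrument_conditions(90)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "framestore") .read_framestore(path) else
    .read_frames_csv(path, conditions)
}

#' Write a multi-field frame store
#'
#' Inverse of [read_frames()]; the written file round-trips with value
#' equality. Intensities must be integral counts for the framestore dialect
#' (they are stored as int64 arrays).
#'
#' @param frameset A `frame_set`.
#' @param path Output path (overwritten).
#' @param dialect `"framestore"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frameset, path,
                         dialect = c("framestore", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(frameset, "frame_set"))
  if (dialect == "framestore") .write_framestore(frameset, path) else
    .write_frames_csv(frameset, path)
  invisible(path)
}

.num_to_text <- function(x) paste(sprintf("%.17g", x), collapse = ",")
.text_to_num <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

.encode_f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8L,
                                    endian = "little")

.decode_f64 <- function(r) readBin(r, "numeric", n = length(r) %/% 8L,
                                   size = 8L, endian = "little")

# int64 little-endian as (lo32, hi32) pairs; counts are < 2^31 so hi = 0
.encode_i64 <- function(x) {
  if (any(abs(x - round(x)) > 1e-9) || any(x < 0) || any(x >= 2^31)) {
    stop("framestore intensities must be integral counts in [0, 2^31)",
         call. = FALSE)
  }
  lo <- as.integer(round(x))
  buf <- integer(2L * length(lo))
  buf[seq(1L, length(buf), by = 2L)] <- lo
  writeBin(buf, raw(), size = 4L, endian = "little")
}

.decode_i64 <- function(r) {
  ints <- readBin(r, "integer", n = length(r) %/% 4L, size = 4L,
                  endian = "little")
  as.numeric(ints[seq(1L, length(ints), by = 2L)])
}

.write_framestore <- function(frameset, path) {
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, "CREATE TABLE global_params (key TEXT, value TEXT)")
  DBI::dbExecute(con, paste(
    "CREATE TABLE frame_params (frame_id INTEGER PRIMARY KEY,",
    "drift_voltage_v REAL, pressure_torr REAL, temperature_k REAL)"))
  DBI::dbExecute(con, paste(
    "CREATE TABLE frame_scans (frame_id INTEGER, scan_index INTEGER,",
    "arrival_time_ms REAL, mz_blob BLOB, intensity_blob BLOB)"))
  cond <- frameset$conditions
  gp <- data.frame(
    key = c("drift_length_cm", "gas_mass_da", "default_temperature_K",
            "default_pressure_torr", "mz_axis", "dt_axis"),
    value = c(sprintf("%.17g", cond$drift_length_cm),
              sprintf("%.17g", cond$gas_mass_da),
              sprintf("%.17g", cond$default_temperature_K),
              sprintf("%.17g", cond$default_pressure_torr),
              .num_to_text(frameset$mz_axis),
              .num_to_text(frameset$dt_axis)),
    stringsAsFactors = FALSE)
  DBI::dbWriteTable(con, "global_params", gp, append = TRUE)
  fp <- data.frame(
    frame_id = vapply(frameset$frames, `[[`, integer(1), "frame_id"),
    drift_voltage_v = vapply(frameset$frames, `[[`, numeric(1),
                             "drift_voltage_V"),
    pressure_torr = vapply(frameset$frames, `[[`, numeric(1),
                           "pressure_torr"),
    temperature_k = vapply(frameset$frames, `[[`, numeric(1),
                           "temperature_K"))
  DBI::dbWriteTable(con, "frame_params", fp, append = TRUE)
  ins <- DBI::dbSendStatement(con, paste(
    "INSERT INTO frame_scans VALUES (?, ?, ?, ?, ?)"))
  on.exit(DBI::dbClearResult(ins), add = TRUE, after = FALSE)
  for (fr in frameset$frames) {
    for (si in seq_along(fr$scans)) {
      s <- fr$scans[[si]]
      DBI::dbBind(ins, list(fr$frame_id, si, s$arrival_time_ms,
                            list(.encode_f64(s$mz)),
                            list(.encode_i64(s$intensity))))
    }
  }
  invisible(path)
}

.require_table <- function(con, tbl, cols) {
  if (!DBI::dbExistsTable(con, tbl)) {
    stop("frame store schema error: missing table '", tbl, "'",
         call. = FALSE)
  }
  have <- DBI::dbListFields(con, tbl)
  miss <- setdiff(cols, have)
  if (length(miss)) {
    stop("frame store schema error: table '", tbl, "' missing column(s) ",
         paste0("'", miss, "'", collapse = ", "), call. = FALSE)
  }
}

.read_framestore <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  .require_table(con, "global_params", c("key", "value"))
  .require_table(con, "frame_params",
                 c("frame_id", "drift_voltage_v", "pressure_torr",
                   "temperature_k"))
  .require_table(con, "frame_scans",
                 c("frame_id", "scan_index", "arrival_time_ms", "mz_blob",
                   "intensity_blob"))
  gp <- DBI::dbReadTable(con, "global_params")
  gv <- function(key) {
    i <- match(key, gp$key)
    if (is.na(i)) stop("frame store schema error: missing global_params ",
                       "key '", key, "'", call. = FALSE)
    gp$value[i]
  }
  cond <- instrument_conditions(
    drift_length_cm = as.numeric(gv("drift_length_cm")),
    gas_mass_da = as.numeric(gv("gas_mass_da")),
    default_temperature_K = as.numeric(gv("default_temperature_K")),
    default_pressure_torr = as.numeric(gv("default_pressure_torr")))
  mz_axis <- .text_to_num(gv("mz_axis"))
  dt_axis <- .text_to_num(gv("dt_axis"))
  fp <- DBI::dbGetQuery(con, "SELECT * FROM frame_params ORDER BY frame_id")
  if (nrow(fp) == 0L) stop("frame store contains zero frames",
                           call. = FALSE)
  if (anyNA(fp)) stop("frame store schema error: frame_params contains ",
                      "missing values", call. = FALSE)
  scans <- DBI::dbGetQuery(con, paste(
    "SELECT * FROM frame_scans ORDER BY frame_id, scan_index"))
  by_frame <- split(seq_len(nrow(scans)), scans$frame_id)
  frames <- vector("list", nrow(fp))
  for (i in seq_len(nrow(fp))) {
    id <- fp$frame_id[i]
    rows <- by_frame[[as.character(id)]]
    sc <- lapply(rows, function(r) list(
      arrival_time_ms = scans$arrival_time_ms[r],
      mz = .decode_f64(scans$mz_blob[[r]]),
      intensity = .decode_i64(scans$intensity_blob[[r]])))
    frames[[i]] <- ims_frame(id, fp$drift_voltage_v[i], fp$pressure_torr[i],
                             fp$temperature_k[i], sc)
  }
  frame_set(cond, frames, mz_axis, dt_axis)
}

.write_frames_csv <- function(frameset, path) {
  rows <- list()
  for (fr in frameset$frames) {
    for (s in fr$scans) {
      if (!length(s$mz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame_id = fr$frame_id,
        drift_voltage_v = fr$drift_voltage_V,
        pressure_torr = fr$pressure_torr,
        temperature_k = fr$temperature_K,
        arrival_time_ms = s$arrival_time_ms,
        mz = s$mz, intensity = s$intensity)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame_id = integer(0), drift_voltage_v = numeric(0),
               pressure_torr = numeric(0), temperature_k = numeric(0),
               arrival_time_ms = numeric(0), mz = numeric(0),
               intensity = numeric(0))
  out <- df
  for (nm in setdiff(names(out), "frame_id")) {
    out[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.read_frames_csv <- function(path, conditions) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "drift_voltage_v", "pressure_torr", "temperature_k",
            "arrival_time_ms", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CSV frame dialect missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("CSV frame file contains zero frames",
                           call. = FALSE)
  frames <- list()
  for (id in sort(unique(df$frame_id))) {
    sub <- df[df$frame_id == id, ]
    sc <- lapply(sort(unique(sub$arrival_time_ms)), function(at) {
      rows <- sub[sub$arrival_time_ms == at, ]
      ord <- order(rows$mz)
      list(arrival_time_ms = at, mz = rows$mz[ord],
           intensity = rows$intensity[ord])
    })
    frames[[length(frames) + 1L]] <- ims_frame(
      id, sub$drift_voltage_v[1], sub$pressure_torr[1],
      sub$temperature_k[1], sc)
  }
  frame_set(conditions, frames,
            mz_axis = sort(unique(df$mz)),
            dt_axis = sort(unique(df$arrival_time_ms)))
}
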