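# fast three-field configuration for end-to-end tests
batch_config <- ccs_config()

test_that("a clean synthetic ion yields one accepted record", {
  ion <- ground_truth_ion("C11H12N2O2", K0_true = 1.4, t0_true_ms = 4)
  fs <- generate_frameset(ion, tiny_synth_config(seed = 31,
                                                 frames_per_field = 3L))
  res <- run_analysis(fs, make_target("C11H12N2O2", "[M+H]"))
  expect_equal(res$status, "ok")
  expect_length(res$accepted, 1L)
  rec <- res$accepted[[1]]
  expect_lt(abs(rec$K0 - 1.4) / 1.4, 0.005)
  expect_lt(abs(rec$t0_ms - 4), 0.5)
  expect_gt(rec$r_squared, 0.999)
  expect_lt(abs(rec$mass_error_ppm), 15)
  # CCS consistent with the Mason-Schamp conversion of the fitted K0
  expect_equal(rec$ccs_A2,
               compute_ccs(rec$K0, rec$mz, 1, 28.0134, 300),
               tolerance = 1e-9)
})

test_that("a noiseless ion is recovered essentially exactly", {
  ion <- ground_truth_ion("C11H12N2O2", K0_true = 1.4)
  fs <- generate_frameset(
    ion, tiny_synth_config(seed = 32, baseline_level = 0,
                           counting_noise_on = FALSE,
                           frames_per_field = 1L))
  res <- run_analysis(fs, make_target("C11H12N2O2", "[M+H]"))
  expect_equal(res$status, "ok")
  rec <- res$accepted[[1]]
  expect_lt(abs(rec$K0 - 1.4) / 1.4, 0.001)
  expect_gte(rec$r_squared, 0.9999)
})

test_that("a blank frame set produces no records", {
  blank <- ground_truth_ion("C2H6O2", K0_true = 2.5, intensity = 1e-4)
  fs <- generate_frameset(blank,
                          tiny_synth_config(seed = 33,
                                            baseline_level = 0.05))
  res <- run_analysis(fs, make_target("C11H12N2O2", "[M+H]"))
  expect_true(res$status %in% c("no_peaks", "insufficient_fields"))
  expect_length(res$accepted, 0L)
})

test_that("two synthetic conformers give two distinct mobilities", {
  a <- ground_truth_ion("C11H12N2O2", K0_true = 1.30)
  b <- ground_truth_ion("C11H12N2O2", K0_true = 1.55)
  cfg <- tiny_synth_config(seed = 34, frames_per_field = 3L)
  fs <- generate_frameset(list(a, b), cfg)
  res <- run_analysis(fs, make_target("C11H12N2O2", "[M+H]"))
  expect_equal(res$status, "ok")
  expect_length(res$accepted, 2L)
  K0s <- sort(vapply(res$accepted, `[[`, numeric(1), "K0"))
  expect_lt(abs(K0s[1] - 1.30) / 1.30, 0.005)
  expect_lt(abs(K0s[2] - 1.55) / 1.55, 0.005)
})

test_that("batch processing fills the relational store consistently", {
  formulas <- c("C11H12N2O2", "C6H12O6", "C9H13NO3")
  K0s <- c(1.40, 1.55, 1.32)
  ions <- mapply(function(f, k) ground_truth_ion(f, "[M+H]", K0_true = k),
                 formulas, K0s, SIMPLIFY = FALSE)
  fs <- generate_frameset(ions, tiny_synth_config(seed = 35,
                                                  frames_per_field = 3L))
  store <- withr::local_tempfile(fileext = ".db")
  targets_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,formula,adducts",
               paste0(c("trp,", "glc,", "adr,"), formulas, ",[M+H]")),
             targets_csv)
  run_batch(targets_csv, list(synthetic = fs), store, batch_config)
  con <- DBI::dbConnect(RSQLite::SQLite(), store)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  expect_equal(DBI::dbGetQuery(con,
    "SELECT COUNT(*) n FROM analyses")$n, 3L)
  expect_equal(DBI::dbGetQuery(con,
    "SELECT COUNT(*) n FROM chemical_targets")$n, 3L)
  ions_tbl <- DBI::dbReadTable(con, "detected_ions")
  expect_equal(sum(ions_tbl$accepted), 3L)   # one ion per planted target
  expect_equal(DBI::dbGetQuery(con,
    "SELECT status FROM analyses ORDER BY analysis_id")$status,
    rep("ok", 3))
  # store-side threshold query reproduces postfilter row-for-row
  q <- DBI::dbGetQuery(con, paste(
    "SELECT ion_id FROM detected_ions WHERE ABS(mass_error_ppm) <= 15",
    "AND isotopic_score >= 0.4 AND posterior >= 0 AND r_squared >= 0.96",
    "ORDER BY ion_id"))
  expect_equal(q$ion_id, ions_tbl$ion_id[ions_tbl$accepted == 1])
  # peaks table carries assignments for every surviving peak
  pk <- DBI::dbReadTable(con, "peaks")
  expect_gt(nrow(pk), 0L)
  expect_true(all(pk$assignment >= 0))
})

test_that("library export is filtered, monotone and byte-stable", {
  ion <- ground_truth_ion("C11H12N2O2", K0_true = 1.4)
  fs <- generate_frameset(ion, tiny_synth_config(seed = 36,
                                                 frames_per_field = 3L))
  store <- withr::local_tempfile(fileext = ".db")
  tcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,formula,adducts", "trp,C11H12N2O2,[M+H]"), tcsv)
  run_batch(tcsv, list(a = fs), store, batch_config)
  lib1 <- withr::local_tempfile(fileext = ".csv")
  lib2 <- withr::local_tempfile(fileext = ".csv")
  df <- export_library(store, lib1)
  expect_equal(nrow(df), 1L)
  expect_equal(names(df)[1:5],
               c("name", "formula", "adduct", "mz", "K0"))
  # rerunning the identical batch gives a byte-identical export
  store2 <- withr::local_tempfile(fileext = ".db")
  run_batch(tcsv, list(a = fs), store2, batch_config)
  export_library(store2, lib2)
  expect_identical(readLines(lib1), readLines(lib2))
  # impossible bound empties the library; sweeping a bound is monotone
  none <- export_library(store, withr::local_tempfile(), max_ppm = 0)
  expect_equal(nrow(none), 0L)
  sizes <- vapply(c(0, 0.5, 0.9, 0.99),
                  function(p) nrow(export_library(
                    store, withr::local_tempfile(), min_posterior = p)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the CLI drives simulate, run and export end to end", {
  dir <- withr::local_tempdir()
  storein <- file.path(dir, "frames.db")
  out <- driftccs_cli(c("simulate", "--out", storein, "--seed", "3",
                        "--formula", "C6H12O6", "--k0", "1.6",
                        "--frames", "2"))
  expect_equal(out, 0L)
  expect_true(file.exists(storein))
  tcsv <- file.path(dir, "targets.csv")
  writeLines(c("name,formula,adducts", "glucose,C6H12O6,[M+H]"), tcsv)
  results <- file.path(dir, "results.db")
  driftccs_cli(c("run", "--targets", tcsv, "--input", storein,
                 "--store", results))
  expect_true(file.exists(results))
  lib <- file.path(dir, "library.csv")
  driftccs_cli(c("export", "--store", results, "--out", lib))
  df <- read.csv(lib)
  expect_equal(nrow(df), 1L)
  expect_lt(abs(df$K0 - 1.6) / 1.6, 0.01)
})
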