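# Independent oracles and small fixture builders used across the suite.

# Jarque-Bera score computed directly from definitional sums (independent
# of the package's vectorised implementation path).
oracle_jb_score <- function(t, w) {
  keep <- w > 0
  t <- t[keep]; w <- w[keep]
  sw <- sum(w)
  mu <- sum(w * t) / sw
  m2 <- sum(w * (t - mu)^2) / sw
  m3 <- sum(w * (t - mu)^3) / sw
  m4 <- sum(w * (t - mu)^4) / sw
  S <- m3 / m2^1.5
  C <- m4 / m2^2 - 3
  n_eff <- sw^2 / sum(w^2)
  pchisq(n_eff / 6 * (S^2 + C^2 / 4), df = 2, lower.tail = FALSE)
}

# Exhaustive isotopomer expansion for small CHNO formulae: enumerates every
# per-element heavy-isotope count with binomial/multinomial probabilities
# and accumulates by total neutron offset.
oracle_envelope_C11H12N2O2 <- function(nmax = 5L) {
  out <- numeric(nmax + 6L)
  pC <- 0.0107; pH <- 0.000115; pN <- 0.00364
  aO <- c(0.99757, 0.00038, 0.00205); aO <- aO / sum(aO)
  for (c13 in 0:4) for (h2 in 0:3) for (n15 in 0:2)
    for (o17 in 0:2) for (o18 in 0:2) {
      if (o17 + o18 > 2) next
      p <- dbinom(c13, 11, pC) * dbinom(h2, 12, pH) * dbinom(n15, 2, pN) *
        dmultinom(c(2 - o17 - o18, o17, o18), prob = aO)
      off <- c13 + h2 + n15 + o17 + 2 * o18
      out[off + 1L] <- out[off + 1L] + p
    }
  out <- out[seq_len(nmax)]
  out / max(out)
}

# All source-sink paths of a DAG by depth-first enumeration, sorted by
# (cost, lexicographic vertex sequence).
oracle_all_paths <- function(edges, source, sink) {
  paths <- list()
  recurse <- function(v, path, cost) {
    if (v == sink) {
      paths[[length(paths) + 1L]] <<- list(vertices = path, cost = cost)
      return()
    }
    idx <- which(edges$from == v)
    for (ei in idx) {
      recurse(edges$to[ei], c(path, edges$to[ei]), cost + edges$weight[ei])
    }
  }
  recurse(source, source, 0)
  if (!length(paths)) return(paths)
  keys <- vapply(paths, function(p)
    paste(sprintf("%06d", p$vertices), collapse = "."), character(1))
  costs <- vapply(paths, `[[`, numeric(1), "cost")
  paths[order(costs, keys)]
}

# Random DAG with dyadic edge weights (exactly representable, so path
# costs are order-independent and ties are exact). Vertices 1..n are in
# topological order; source = 1, sink = n.
random_dag <- function(n, p_edge = 0.45) {
  from <- integer(0); to <- integer(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      from <- c(from, i); to <- c(to, j)
    }
  }
  data.frame(from = from, to = to,
             weight = sample(1:64, length(from), replace = TRUE) / 64)
}

# hand-built peak with defaults representative of a clean detection
fake_peak <- function(field_index = 1L, mzc = 205.0977, mzw = 0.006,
                      mzl = 0.5, dtc = 25, dtw = 0.6, dtl = 0.5,
                      base_intensity = 50, summed_intensity = 500,
                      x_value = NA_real_, shape = NA_real_,
                      iso = NA_real_, rel = NA_real_) {
  structure(list(field_index = field_index, mzc = mzc, mzw = mzw,
                 mzl = mzl, dtc = dtc, dtw = dtw, dtl = dtl,
                 base_intensity = base_intensity,
                 summed_intensity = summed_intensity,
                 atd_profile = data.frame(arrival_time_ms = numeric(0),
                                          intensity = numeric(0)),
                 x_value = x_value, temperature_K = 300,
                 shape_score = shape, isotopic_score = iso,
                 rel_intensity = rel),
            class = "peak2d")
}

fake_record <- function(mass_error_ppm = 1, isotopic_score = 0.9,
                        posterior = 0.9, r_squared = 0.9999) {
  structure(list(name = "x", formula = "X", adduct = "[M+H]", mz = 100,
                 K0 = 1.4, t0_ms = 4, ccs_A2 = 150,
                 r_squared = r_squared, mass_error_ppm = mass_error_ppm,
                 isotopic_score = isotopic_score, shape_score = 0.9,
                 posterior = posterior, log_posterior = -1,
                 n_points = 7L), class = "ccs_record")
}

# compact three-field synthetic configuration for fast unit tests
tiny_synth_config <- function(seed, frames_per_field = 2L, ...) {
  synth_config(seed = seed,
               drift_voltages = c(1665, 1300, 972),
               frames_per_field = frames_per_field,
               dt_range_ms = c(0, 50), ...)
}

# small frame set built by hand (2 frames, 3 x 4 grid)
tiny_frameset <- function() {
  mz <- c(100.00, 100.01, 100.02, 100.03)
  dt <- c(1, 2, 3)
  f1 <- ims_frame(1L, 1500, 4, 300, list(
    list(arrival_time_ms = 1, mz = mz[c(1, 3)], intensity = c(5, 7)),
    list(arrival_time_ms = 3, mz = mz[2], intensity = 2)))
  f2 <- ims_frame(2L, 1200, 4.1, 299, list(
    list(arrival_time_ms = 2, mz = mz[4], intensity = 11)))
  frame_set(instrument_conditions(90), list(f1, f2), mz, dt)
}

expect_frameset_equal <- function(a, b) {
  expect_equal(a$mz_axis, b$mz_axis)
  expect_equal(a$dt_axis, b$dt_axis)
  expect_equal(a$conditions, b$conditions)
  expect_equal(length(a$frames), length(b$frames))
  for (i in seq_along(a$frames)) {
    expect_equal(a$frames[[i]], b$frames[[i]])
  }
}
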