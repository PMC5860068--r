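test_that("diffusion match is 1 for identical profiles and decays", {
  a <- fake_peak(field_index = 1L)
  b <- fake_peak(field_index = 2L)
  expect_equal(diffusion_match(a, b), 1.0)
  # one feature off by exactly one scale unit, equal weights
  p <- match_params()
  b2 <- b
  b2$mzc <- a$mzc * (1 + p$scales[["mzc"]] * 1e-6 /
                       (1 - p$scales[["mzc"]] * 1e-6 / 2))
  expect_equal(diffusion_match(a, b2), exp(-1 / 6), tolerance = 1e-6)
  # bounded and monotone in each |Delta|
  prev <- 1
  for (d in c(0.05, 0.1, 0.2, 0.4)) {
    b3 <- b; b3$dtl <- b$dtl + d
    val <- diffusion_match(a, b3)
    expect_true(val > 0 && val <= 1)
    expect_lt(val, prev)
    prev <- val
  }
})

test_that("graph wiring counts vertices and edges as expected", {
  by_field <- list(list(fake_peak(1L)), list(fake_peak(2L)),
                   list(fake_peak(3L)))
  g <- build_graph(by_field)
  expect_equal(g$n_peaks, 3L)
  inter <- g$edges[g$edges$from <= 3 & g$edges$to <= 3, ]
  expect_equal(nrow(inter), 2L)
  expect_equal(nrow(g$edges), 2L + 2L * 3L)   # + source/sink wiring
  # 2x2 adjacent fields: complete bipartite
  by2 <- list(list(fake_peak(1L), fake_peak(1L)),
              list(fake_peak(2L), fake_peak(2L)),
              list(fake_peak(3L)))
  g2 <- build_graph(by2)
  inter2 <- g2$edges[g2$edges$from <= 5 & g2$edges$to <= 5, ]
  expect_equal(nrow(inter2), 4L + 2L)
  expect_true(all(g2$edges$weight >= 0))
  expect_error(build_graph(list(list(fake_peak(1L)), list(),
                                list(fake_peak(3L)))),
               "insufficient fields")
})

test_that("a 3x3 transition graph realises disjoint full-span paths", {
  by_field <- lapply(1:3, function(f) {
    lapply(1:3, function(i) {
      fake_peak(f, mzc = 205.09 + i * 0.001, dtc = 20 + 2 * i + f)
    })
  })
  g <- build_graph(by_field)
  paths <- k_shortest_paths(g, K = 3000L, min_fields = 3L)
  keys <- vapply(paths, function(p) paste(p$peak_ids, collapse = "-"),
                 character(1))
  expect_true("1-4-7" %in% keys)   # peaks 1,4,7: same i across fields
  expect_true("2-5-8" %in% keys)
  expect_equal(length(paths), 27L)  # all full-span combinations
})

test_that("K-shortest paths on a hand-built 2x2 graph are ordered", {
  # vertices: 1,2 (first field), 3,4 (second); 5 = source, 6 = sink
  edges <- data.frame(
    from = c(1, 1, 2, 2, 5, 5, 3, 4),
    to = c(3, 4, 3, 4, 1, 2, 6, 6),
    weight = c(0.1, 0.2, 0.3, 0.4, 0, 0, 0, 0))
  out <- ksp_dag(edges, 6L, 5L, 6L, 10L)
  expect_length(out, 4L)
  expect_equal(vapply(out, `[[`, numeric(1), "cost"),
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(out[[1]]$vertices, c(5, 1, 3, 6))
  expect_equal(out[[2]]$vertices, c(5, 1, 4, 6))
  expect_equal(out[[3]]$vertices, c(5, 2, 3, 6))
  # single-chain graph returns its one path with summed cost
  chain <- data.frame(from = c(1, 2, 3), to = c(2, 3, 4),
                      weight = c(0.5, 0.25, 0.125))
  out1 <- ksp_dag(chain, 4L, 1L, 4L, 5L)
  expect_length(out1, 1L)
  expect_equal(out1[[1]]$cost, 0.875)
  # disconnected source and sink
  expect_length(ksp_dag(chain, 5L, 1L, 5L, 3L), 0L)
})

test_that("path enumeration equals brute force on random DAGs", {
  set.seed(2024)
  n_checked <- 0L
  for (rep in 1:110) {
    n <- sample(4:12, 1)
    edges <- random_dag(n)
    if (!nrow(edges)) next
    oracle <- oracle_all_paths(edges, 1L, n)
    got <- ksp_dag(edges, n, 1L, n, K = 10000L)
    expect_equal(length(got), length(oracle))
    for (i in seq_along(oracle)) {
      expect_equal(got[[i]]$vertices, oracle[[i]]$vertices)
      expect_equal(got[[i]]$cost, oracle[[i]]$cost, tolerance = 1e-12)
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("path costs satisfy the product identity with match scores", {
  by_field <- lapply(1:4, function(f) {
    lapply(1:2, function(i) {
      fake_peak(f, mzc = 205.09 + i * 0.002, dtc = 18 + 3 * i + 1.5 * f,
                dtw = 0.5 + 0.05 * i, mzw = 0.005 + 0.001 * i)
    })
  })
  g <- build_graph(by_field)
  for (p in k_shortest_paths(g, K = 200L)) {
    prod_match <- 1
    for (i in seq_len(length(p$peak_ids) - 1L)) {
      prod_match <- prod_match *
        diffusion_match(p$peaks[[i]], p$peaks[[i + 1L]])
    }
    expect_equal(exp(-p$length_cost), prod_match, tolerance = 1e-9)
    expect_equal(p$p_diffusion,
                 prod_match^(1 / (length(p$peak_ids) - 1L)),
                 tolerance = 1e-9)
  }
})

test_that("path probability combines fit and diffusion geometrically", {
  x <- c(1, 2, 3, 4) * 1e-5
  t_ms <- 2e6 * x + 4
  fit <- fit_mobility(t_ms, x, 90)
  path <- structure(list(p_diffusion = 1), class = "ion_path")
  expect_equal(path_probability(path, fit, 0.5), 1.0)
  fit$r_squared <- 0.81
  expect_equal(path_probability(path, fit, 0.5), 0.9)
  fit$r_squared <- -0.5
  expect_equal(path_probability(path, fit, 0.5), 0)
  fit$r_squared <- 0.81
  path$p_diffusion <- 0.49
  expect_equal(path_probability(path, fit, 0.5), sqrt(0.81 * 0.49))
})

test_that("peak likelihood follows the Gaussian arrival-time error model", {
  x <- c(1, 2, 3) * 1e-5
  fit <- fit_mobility(2e6 * x + 4, x, 90)
  on_line <- fake_peak(dtc = 2e6 * 2e-5 + 4, x_value = 2e-5)
  expect_equal(peak_likelihood(on_line, fit), 1.0)
  expect_equal(peak_likelihood(on_line, NULL, delta = 0.1), 0.1)
  t_hat <- 2e6 * 2e-5 + 4
  off <- fake_peak(dtc = t_hat + 0.02 * t_hat, x_value = 2e-5)
  expect_equal(peak_likelihood(off, fit, sigma_t_rel = 0.02),
               exp(-0.5), tolerance = 1e-9)
})

test_that("MAP selection labels a clean ion's peaks and rejects strays", {
  # three fields, one consistent ion + one stray peak in field 2
  x_vals <- c(1.0e-5, 1.2e-5, 1.4e-5)
  slope <- 2.0e6
  mk <- function(f, dtc, mzc = 205.0977) {
    fake_peak(f, mzc = mzc, dtc = dtc, x_value = x_vals[f])
  }
  by_field <- list(list(mk(1L, slope * x_vals[1] + 4)),
                   list(mk(2L, slope * x_vals[2] + 4),
                        mk(2L, slope * x_vals[2] + 12, 205.105)),
                   list(mk(3L, slope * x_vals[3] + 4)))
  g <- build_graph(by_field)
  paths <- k_shortest_paths(g)
  hyp <- select_optimal(paths, g$peaks, 90)
  expect_length(hyp$paths, 1L)
  expect_equal(sort(hyp$paths[[1]]$peak_ids), c(1L, 2L, 4L))
  expect_equal(sum(hyp$assignments == 0L), 1L)
  expect_equal(hyp$paths[[1]]$fit$K0,
               90^2 * 273.15 / (760 * slope / 1000), tolerance = 1e-9)
})

test_that("empty inputs give the all-artifact hypothesis with score 0", {
  hyp <- select_optimal(list(), list(), 90)
  expect_length(hyp$paths, 0L)
  expect_equal(hyp$log_posterior, 0)
})

test_that("two true conformers beat any single-path hypothesis", {
  x_vals <- c(1.0e-5, 1.2e-5, 1.4e-5)
  mk <- function(f, slope, dtw) {
    fake_peak(f, dtc = slope * x_vals[f] + 4, dtw = dtw,
              x_value = x_vals[f])
  }
  by_field <- lapply(1:3, function(f) {
    list(mk(f, 1.8e6, 0.5), mk(f, 2.4e6, 0.7))
  })
  g <- build_graph(by_field)
  paths <- k_shortest_paths(g)
  hyp <- select_optimal(paths, g$peaks, 90)
  expect_length(hyp$paths, 2L)
  K0s <- sort(vapply(hyp$paths, function(p) p$fit$K0, numeric(1)))
  expect_equal(K0s,
               90^2 * 273.15 / (760 * c(2.4e3, 1.8e3)), tolerance = 1e-9)
  expect_true(all(hyp$assignments > 0L))
  # oracle: exhaustive scoring over all disjoint subsets of candidates
  score_subset <- function(sel) {
    n <- length(g$peaks)
    tot <- n * log(0.1)
    for (p in paths[sel]) {
      fit <- fit_mobility(vapply(p$peaks, `[[`, numeric(1), "dtc"),
                          vapply(p$peaks, `[[`, numeric(1), "x_value"),
                          90)
      pp <- path_probability(p, fit, 0.5)
      lik <- vapply(p$peaks, peak_likelihood, numeric(1), fit = fit)
      tot <- tot + log(pp) + sum(log(lik)) -
        length(p$peaks) * log(0.1)
    }
    tot
  }
  best <- -Inf
  for (sz in 0:2) {
    for (sel in if (sz == 0) list(integer(0)) else
         asplit(utils::combn(length(paths), sz), 2)) {
      ids <- unlist(lapply(paths[sel], `[[`, "peak_ids"))
      if (anyDuplicated(ids)) next
      best <- max(best, score_subset(sel))
    }
  }
  expect_equal(hyp$log_posterior, best, tolerance = 1e-9)
})

test_that("hypothesis choice is invariant to candidate path order", {
  x_vals <- c(1.0e-5, 1.2e-5, 1.4e-5)
  by_field <- lapply(1:3, function(f) {
    list(fake_peak(f, dtc = 2e6 * x_vals[f] + 4, x_value = x_vals[f]),
         fake_peak(f, dtc = 2e6 * x_vals[f] + 9, x_value = x_vals[f],
                   dtw = 0.9))
  })
  g <- build_graph(by_field)
  paths <- k_shortest_paths(g)
  h1 <- select_optimal(paths, g$peaks, 90)
  h2 <- select_optimal(rev(paths), g$peaks, 90)
  expect_equal(h1$log_posterior, h2$log_posterior, tolerance = 1e-12)
  key <- function(h) sort(vapply(h$paths, function(p)
    paste(p$peak_ids, collapse = "-"), character(1)))
  expect_equal(key(h1), key(h2))
})
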