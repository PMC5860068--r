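#' Diffusion-profile matching parameters
#'
#' Six per-feature scale constants and six non-negative weights (summing
#' to 1) for the diffusion-profile match between peaks observed at
#' different electric fields. Features: apex m/z (compared in ppm), m/z
#' FWHM (relative), low-side m/z intensity fraction (absolute), apex
#' arrival time (relative; deliberately loose, acting as a locality prior
#' since apex times legitimately shift with field), ATD FWHM (relative),
#' pre-apex intensity fraction (absolute).
#'
#' @param scales Named numeric vector with entries `mzc` (ppm), `mzw`,
#'   `mzl`, `dtc`, `dtw`, `dtl`.
#' @param weights Same names, non-negative, normalised to sum to 1.
#' @return Object of class `match_params`.
#' @export
match_params <- function(scales = c(mzc = 20, mzw = 0.5, mzl = 0.25,
                                    dtc = 0.5, dtw = 0.5, dtl = 0.25),
                         weights = c(mzc = 1, mzw = 1, mzl = 1,
                                     dtc = 1, dtw = 1, dtl = 1) / 6) {
  keys <- c("mzc", "mzw", "mzl", "dtc", "dtw", "dtl")
  stopifnot(all(keys %in% names(scales)), all(keys %in% names(weights)))
  scales <- scales[keys]; weights <- weights[keys]
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero", call. = FALSE)
  structure(list(scales = scales, weights = weights / s),
            class = "match_params")
}

#' Diffusion-profile match probability of two peaks
#'
#' Each feature difference is reduced to a sub-score
#' `s_k = exp(-(Delta_k / sigma_k)^2)`; the match probability is the
#' weighted geometric product `prod s_k^{w_k}`, in (0, 1], equal to 1 for
#' identical profiles and monotone decreasing in each `|Delta_k|`. Apex m/z
#' is compared in ppm; m/z width, apex arrival time and ATD width as
#' relative differences (normalised by the pair mean); the two asymmetry
#' fractions as absolute differences.
#'
#' @param p_i,p_j `peak2d` objects from different fields.
#' @param params A `match_params`.
#' @return Probability in (0, 1].
#' @export
diffusion_match <- function(p_i, p_j, params = match_params()) {
  rel <- function(a, b) {
    m <- (a + b) / 2
    if (m <= 0) 0 else abs(a - b) / m
  }
  delta <- c(
    mzc = abs(p_i$mzc - p_j$mzc) / ((p_i$mzc + p_j$mzc) / 2) * 1e6,
    mzw = rel(p_i$mzw, p_j$mzw),
    mzl = abs(p_i$mzl - p_j$mzl),
    dtc = rel(p_i$dtc, p_j$dtc),
    dtw = rel(p_i$dtw, p_j$dtw),
    dtl = abs(p_i$dtl - p_j$dtl))
  sub <- exp(-(delta / params$scales)^2)
  prod(sub^params$weights)
}

#' Build the ion transition graph
#'
#' Vertices are the surviving peaks of all fields plus a source and a sink.
#' Complete bipartite edges connect each peak to every peak of the adjacent
#' (next non-empty, lower-field) group, weighted by the negative log of the
#' diffusion-match probability, so shorter paths have more consistent
#' diffusion profiles. The source connects to every peak and every peak
#' connects to the sink with a constant `start_penalty`, allowing paths
#' that span any contiguous run of at least `min_fields` fields (tolerating
#' detector dropout at extreme fields).
#'
#' @param peaks_by_field List of per-field peak lists, ordered by
#'   field index (descending field strength); entries may be empty.
#' @param params A `match_params`.
#' @param min_fields Minimum number of non-empty fields (default 3).
#' @param start_penalty Source/sink edge weight (default `-log(0.5)`).
#' @return Object of class `ion_graph` with flattened `peaks`, their
#'   `fields`, an edge data frame (`from`, `to`, `weight`), and `source` /
#'   `sink` vertex ids.
#' @export
build_graph <- function(peaks_by_field, params = match_params(),
                        min_fields = 3L, start_penalty = -log(0.5)) {
  nonempty <- which(vapply(peaks_by_field, length, integer(1)) > 0)
  if (length(nonempty) < min_fields) {
    stop(sprintf("insufficient fields: %d non-empty groups, need %d",
                 length(nonempty), min_fields), call. = FALSE)
  }
  peaks <- list(); fields <- integer(0); index_by_field <- list()
  for (g in nonempty) {
    ids <- integer(0)
    for (p in peaks_by_field[[g]]) {
      peaks[[length(peaks) + 1L]] <- p
      fields <- c(fields, g)
      ids <- c(ids, length(peaks))
    }
    index_by_field[[as.character(g)]] <- ids
  }
  n <- length(peaks)
  source <- n + 1L; sink <- n + 2L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (gi in seq_along(nonempty)[-length(nonempty)]) {
    a <- index_by_field[[as.character(nonempty[gi])]]
    b <- index_by_field[[as.character(nonempty[gi + 1L])]]
    for (i in a) for (j in b) {
      from <- c(from, i); to <- c(to, j)
      w <- c(w, -log(diffusion_match(peaks[[i]], peaks[[j]], params)))
    }
  }
  from <- c(from, rep(source, n), seq_len(n))
  to <- c(to, seq_len(n), rep(sink, n))
  w <- c(w, rep(start_penalty, 2L * n))
  structure(list(peaks = peaks, fields = fields,
                 edges = data.frame(from = from, to = to, weight = w),
                 n_peaks = n, source = source, sink = sink,
                 start_penalty = start_penalty),
            class = "ion_graph")
}

# --- K shortest loopless paths on a DAG (Hoffman-Pavley deviation scheme) -

# topological order of vertices 1..n given an edge data frame
.topo_order <- function(edges, n) {
  indeg <- tabulate(edges$to, nbins = n)
  out_by <- split(seq_len(nrow(edges)), factor(edges$from, levels = 1:n))
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ei in out_by[[v]]) {
      u <- edges$to[ei]
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) queue <- c(queue, u)
    }
  }
  if (length(order) != n) stop("graph contains a cycle", call. = FALSE)
  order
}

#' K shortest paths between two vertices of a weighted DAG
#'
#' Deviation-based enumeration (Hoffman-Pavley): the shortest-path tree to
#' the sink is computed once by dynamic programming in reverse topological
#' order, and candidate paths are generated by deviating from already
#' emitted paths at or after their deviation point, completing each
#' deviation with the shortest suffix from the tree. On a DAG every path is
#' loopless by construction. Paths are returned in non-decreasing cost;
#' equal-cost paths are ordered lexicographically by vertex sequence.
#'
#' @param edges Data frame with columns `from`, `to`, `weight`
#'   (non-negative).
#' @param n_vertices Number of vertices (ids 1..n).
#' @param source,sink Vertex ids.
#' @param K Maximum number of paths.
#' @return List of `list(vertices, cost)` in order.
#' @export
ksp_dag <- function(edges, n_vertices, source, sink, K) {
  stopifnot(K >= 1)
  out_by <- split(seq_len(nrow(edges)),
                  factor(edges$from, levels = seq_len(n_vertices)))
  topo <- .topo_order(edges, n_vertices)
  dist <- rep(Inf, n_vertices); dist[sink] <- 0
  nxt <- rep(NA_integer_, n_vertices)
  for (v in rev(topo)) {
    if (v == sink) next
    for (ei in out_by[[v]]) {
      u <- edges$to[ei]
      cand <- edges$weight[ei] + dist[u]
      if (cand < dist[v] - 1e-15 ||
          (abs(cand - dist[v]) <= 1e-15 && !is.na(nxt[v]) && u < nxt[v])) {
        dist[v] <- cand; nxt[v] <- u
      }
    }
  }
  if (!is.finite(dist[source])) return(list())
  tree_suffix <- function(v) {
    path <- v
    while (v != sink) {
      v <- nxt[v]
      path <- c(path, v)
    }
    path
  }
  path_key <- function(p) paste(sprintf("%06d", p), collapse = ".")
  # binary min-heap on (cost, lexicographic path key) for deterministic
  # emission order; payload holds the path and its deviation index
  h_cost <- numeric(0); h_key <- character(0); h_val <- list()
  h_less <- function(i, j) {
    h_cost[i] < h_cost[j] ||
      (h_cost[i] == h_cost[j] && h_key[i] < h_key[j])
  }
  h_push <- function(cost, key, val) {
    n <- length(h_cost) + 1L
    h_cost[n] <<- cost; h_key[n] <<- key; h_val[[n]] <<- val
    while (n > 1L) {
      p <- n %/% 2L
      if (h_less(n, p)) {
        h_cost[c(p, n)] <<- h_cost[c(n, p)]
        h_key[c(p, n)] <<- h_key[c(n, p)]
        tmp <- h_val[[p]]; h_val[[p]] <<- h_val[[n]]; h_val[[n]] <<- tmp
        n <- p
      } else break
    }
  }
  h_pop <- function() {
    top <- list(cost = h_cost[1], key = h_key[1], val = h_val[[1]])
    n <- length(h_cost)
    h_cost[1] <<- h_cost[n]; h_key[1] <<- h_key[n]
    h_val[[1]] <<- h_val[[n]]
    h_cost <<- h_cost[-n]; h_key <<- h_key[-n]
    h_val[[n]] <<- NULL
    i <- 1L; n <- n - 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      sm <- i
      if (l <= n && h_less(l, sm)) sm <- l
      if (r <= n && h_less(r, sm)) sm <- r
      if (sm == i) break
      h_cost[c(i, sm)] <<- h_cost[c(sm, i)]
      h_key[c(i, sm)] <<- h_key[c(sm, i)]
      tmp <- h_val[[i]]; h_val[[i]] <<- h_val[[sm]]; h_val[[sm]] <<- tmp
      i <- sm
    }
    top
  }
  seen <- new.env(hash = TRUE)
  first <- tree_suffix(source)
  assign(path_key(first), TRUE, envir = seen)
  h_push(dist[source], path_key(first), list(path = first, dev = 1L))
  edge_w <- function(a, b) {
    ei <- out_by[[a]]
    min(edges$weight[ei[edges$to[ei] == b]])
  }
  results <- list()
  while (length(results) < K && length(h_cost)) {
    top <- h_pop()
    path <- top$val$path; dev0 <- top$val$dev
    results[[length(results) + 1L]] <- list(vertices = path,
                                            cost = top$cost)
    # deviations at or after this path's own deviation point
    prefix_cost <- 0
    for (i in seq_len(length(path) - 1L)) {
      if (i >= dev0) {
        for (ei in out_by[[path[i]]]) {
          u <- edges$to[ei]
          if (u == path[i + 1L] || !is.finite(dist[u])) next
          new_path <- c(path[seq_len(i)], tree_suffix(u))
          key <- path_key(new_path)
          if (exists(key, envir = seen, inherits = FALSE)) next
          assign(key, TRUE, envir = seen)
          h_push(prefix_cost + edges$weight[ei] + dist[u], key,
                 list(path = new_path, dev = i))
        }
      }
      prefix_cost <- prefix_cost + edge_w(path[i], path[i + 1L])
    }
  }
  results
}

#' Enumerate candidate ion paths from a transition graph
#'
#' Runs the K-shortest-path enumeration on the ion transition graph,
#' strips the source and sink, discards paths visiting fewer than
#' `min_fields` fields and deduplicates. Each surviving path records its
#' inter-peak cost (`length_cost`, the negative log of the product of
#' per-edge match probabilities) and the per-edge geometric mean
#' `p_diffusion`.
#'
#' @param graph An `ion_graph`.
#' @param K Maximum number of source-sink paths to enumerate
#'   (default 3000).
#' @param min_fields Minimum fields per path (default 3).
#' @return List of `ion_path` objects ordered by total cost.
#' @export
k_shortest_paths <- function(graph, K = 3000L, min_fields = 3L) {
  raw <- ksp_dag(graph$edges, graph$n_peaks + 2L, graph$source,
                 graph$sink, K)
  out <- list(); seen <- character(0)
  for (r in raw) {
    verts <- r$vertices[-c(1L, length(r$vertices))]
    if (length(verts) < min_fields) next
    key <- paste(verts, collapse = ".")
    if (key %in% seen) next
    seen <- c(seen, key)
    length_cost <- r$cost - 2 * graph$start_penalty
    length_cost <- max(length_cost, 0)
    n_edges <- length(verts) - 1L
    out[[length(out) + 1L]] <- structure(list(
      peak_ids = verts,
      peaks = graph$peaks[verts],
      fields = graph$fields[verts],
      length_cost = length_cost,
      total_cost = r$cost,
      p_diffusion = exp(-length_cost / n_edges)
    ), class = "ion_path")
  }
  out
}

#' A posteriori probability of one ion path
#'
#' The weighted geometric mean of the mobility-fit linearity and the
#' diffusion-profile consistency:
#' `P(T_k) = max(R^2, 0)^w_r * p_diffusion^(1 - w_r)`.
#'
#' @param path An `ion_path`.
#' @param fit The path's `mobility_fit`.
#' @param w_r Weight on the R^2 term (default 0.5).
#' @return Probability in `[0, 1]`.
#' @export
path_probability <- function(path, fit, w_r = 0.5) {
  r2 <- max(fit$r_squared, 0)
  r2^w_r * path$p_diffusion^(1 - w_r)
}

#' Likelihood of one observed peak under a hypothesis
#'
#' An on-path peak is scored by the arrival-time error between its apex and
#' the arrival time its path's mobility fit predicts at the peak's
#' `x = p/(TV)`: `exp(-1/2 (e / (sigma_t_rel * t_hat))^2)`. A peak assigned
#' to no path is an artifact or interference and scores the constant
#' `delta`.
#'
#' @param peak A `peak2d` carrying its `x_value` (attached during
#'   analysis).
#' @param fit The `mobility_fit` of the peak's path, or `NULL` for an
#'   artifact.
#' @param sigma_t_rel Relative arrival-time tolerance (default 0.02).
#' @param delta Artifact probability (default 0.1).
#' @return Probability in (0, 1].
#' @export
peak_likelihood <- function(peak, fit = NULL, sigma_t_rel = 0.02,
                            delta = 0.1) {
  if (is.null(fit)) return(delta)
  t_hat <- predict_arrival(fit, peak$x_value)
  e <- abs(peak$dtc - t_hat)
  exp(-0.5 * (e / (sigma_t_rel * t_hat))^2)
}

#' Select the optimal association hypothesis (MAP)
#'
#' A hypothesis is a set of pairwise vertex-disjoint ion paths; every peak
#' not on a path is labelled an artifact. The log-posterior is
#' `sum_k log P(T_k) + sum_i log Pr(x_i | T)`. Subsets of up to
#' `max_conformers` disjoint paths from the candidate list are enumerated
#' exhaustively when at most 20 candidates survive (always including the
#' empty, all-artifact hypothesis); larger candidate sets are searched by
#' deterministic best-first beam (width 50). Ties are broken towards fewer
#' paths, then higher summed on-path intensity.
#'
#' @param paths Candidate `ion_path` list from [k_shortest_paths()].
#' @param peaks All surviving peaks (graph vertex order), each carrying
#'   `x_value`.
#' @param drift_length_cm Drift length for the per-path mobility fits.
#' @param method Fit method (`"ols"` or `"irls_bisquare"`).
#' @param w_r,sigma_t_rel,delta,max_conformers Model constants (see
#'   [path_probability()] and [peak_likelihood()]).
#' @return Object of class `association_hypothesis` with `paths` (each
#'   augmented with `fit` and `p_path`), `log_posterior`, and `assignments`
#'   (0 = artifact, k = index into `paths`).
#' @export
select_optimal <- function(paths, peaks, drift_length_cm,
                           method = "ols", w_r = 0.5, sigma_t_rel = 0.02,
                           delta = 0.1, max_conformers = 4L) {
  n <- length(peaks)
  base <- n * log(delta)
  # score each candidate path: log P(T_k) plus the likelihood gain of its
  # peaks over their artifact baseline (paths are disjoint, so hypothesis
  # scores are additive in these contributions)
  scored <- list()
  for (p in paths) {
    fit <- tryCatch(
      fit_mobility(vapply(p$peaks, `[[`, numeric(1), "dtc"),
                   vapply(p$peaks, `[[`, numeric(1), "x_value"),
                   drift_length_cm, method = method),
      error = function(e) NULL)
    if (is.null(fit)) next
    p$fit <- fit
    p$p_path <- path_probability(p, fit, w_r)
    if (p$p_path <= 0) next
    lik <- vapply(p$peaks, peak_likelihood, numeric(1), fit = fit,
                  sigma_t_rel = sigma_t_rel, delta = delta)
    p$gain <- log(p$p_path) + sum(log(lik)) - length(p$peaks) * log(delta)
    p$intensity <- sum(vapply(p$peaks, `[[`, numeric(1),
                              "summed_intensity"))
    scored[[length(scored) + 1L]] <- p
  }
  best <- list(sel = integer(0), score = base, n_paths = 0L,
               intensity = 0)
  consider <- function(sel) {
    score <- base + sum(vapply(scored[sel], `[[`, numeric(1), "gain"))
    inten <- sum(vapply(scored[sel], `[[`, numeric(1), "intensity"))
    better <- score > best$score + 1e-12 ||
      (abs(score - best$score) <= 1e-12 &&
         (length(sel) < best$n_paths ||
            (length(sel) == best$n_paths && inten > best$intensity)))
    if (better) {
      best <<- list(sel = sel, score = score, n_paths = length(sel),
                    intensity = inten)
    }
  }
  disjoint <- function(sel, j) {
    !any(scored[[j]]$peak_ids %in%
           unlist(lapply(scored[sel], `[[`, "peak_ids")))
  }
  m <- length(scored)
  if (m <= 20L) {
    recurse <- function(sel, start) {
      consider(sel)
      if (length(sel) >= max_conformers) return()
      for (j in seq_len(m)[seq_len(m) >= start]) {
        if (disjoint(sel, j)) recurse(c(sel, j), j + 1L)
      }
    }
    if (m > 0L) recurse(integer(0), 1L) else consider(integer(0))
  } else {
    beam <- list(integer(0))
    consider(integer(0))
    repeat {
      nxt <- list(); keys <- character(0); scores <- numeric(0)
      for (sel in beam) {
        if (length(sel) >= max_conformers) next
        start <- if (length(sel)) max(sel) + 1L else 1L
        for (j in seq_len(m)[seq_len(m) >= start]) {
          if (!disjoint(sel, j)) next
          new_sel <- c(sel, j)
          key <- paste(new_sel, collapse = ".")
          if (key %in% keys) next
          keys <- c(keys, key)
          nxt[[length(nxt) + 1L]] <- new_sel
          scores <- c(scores, base + sum(vapply(scored[new_sel], `[[`,
                                                numeric(1), "gain")))
          consider(new_sel)
        }
      }
      if (!length(nxt)) break
      keep <- order(-scores)[seq_len(min(50L, length(nxt)))]
      beam <- nxt[keep]
    }
  }
  sel_paths <- scored[best$sel]
  assignments <- integer(n)
  for (k in seq_along(sel_paths)) {
    assignments[sel_paths[[k]]$peak_ids] <- k
  }
  structure(list(paths = sel_paths, log_posterior = best$score,
                 assignments = assignments, delta = delta,
                 n_peaks = n),
            class = "association_hypothesis")
}
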