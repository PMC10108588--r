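#' Pool GFP-normalized group-average maps at topographically consistent
#' timepoints
#'
#' Microstate templates are identified from the grand-average maps of every
#' group at the timepoints where the topographic consistency test found a
#' reliable topography. Maps are normalized to unit GFP so clustering sees
#' field configuration, not strength; the original GFP is kept as a weight.
#'
#' @param groups Named list of [epoch_set()]s (one per group/cohort).
#' @param tct_results List of `randomization_result`s from [tct()], same
#'   names/order, each run over the same window.
#' @return An object of class `map_pool`: `maps` (n_maps x channels, unit
#'   GFP, average-referenced), `info` (tibble: group, time_ms, gfp) and the
#'   montage.
#' @export
pool_consistent_maps <- function(groups, tct_results) {
  stopifnot(length(groups) == length(tct_results))
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  maps <- list()
  info <- list()
  for (g in names(groups)) {
    res <- tct_results[[g]]
    keep <- which(res$significant)
    if (!length(keep)) next
    es <- window_epochs(groups[[g]],
                        c(res$times_ms[1],
                          res$times_ms[length(res$times_ms)] +
                            1000 / groups[[g]]$fs_hz))
    avg <- grand_average(es)
    gvals <- gfp_columns(avg)
    ok <- keep[gvals[keep] > 0]
    if (!length(ok)) next
    m <- t(avg[, ok, drop = FALSE])
    m <- m - rowMeans(m)
    m <- m / apply(m, 1, gfp)
    maps[[g]] <- m
    info[[g]] <- tibble::tibble(group = g, time_ms = res$times_ms[ok],
                                gfp = gvals[ok])
  }
  if (!length(maps)) abort("no topographically consistent timepoints to pool")
  structure(list(maps = do.call(rbind, maps),
                 info = dplyr::bind_rows(info),
                 montage = groups[[1]]$montage),
            class = "map_pool")
}

#' @export
print.map_pool <- function(x, ...) {
  cat(sprintf("<map_pool> %d maps x %d channels from %d group(s)\n",
              nrow(x$maps), ncol(x$maps),
              length(unique(x$info$group))))
  invisible(x)
}

# spatial correlation between unit-GFP average-referenced map rows:
# r = mean(u * v) elementwise (population moments, zero means, unit SDs)
map_correlation <- function(a, b) {
  tcrossprod(a, b) / ncol(a)
}

# correlation -> assignment score under the polarity convention
assign_score <- function(r, polarity_sensitive) {
  if (polarity_sensitive) r else abs(r)
}

#' Identify microstate templates by atomize-and-agglomerate hierarchical
#' clustering
#'
#' Starts from every map as its own cluster and iteratively dissolves the
#' cluster contributing the least explained variance, reassigning its
#' members to the remaining cluster with the most similar template
#' (distance 1 - spatial correlation; polarity-sensitive by default, the
#' ERP convention). Each cluster's template is the GFP-weighted,
#' orientation-consistent mean of its members, renormalized to unit GFP.
#'
#' @param maps A `map_pool` from [pool_consistent_maps()] or a numeric
#'   matrix (maps x channels).
#' @param k Number of microstates to return.
#' @param polarity_sensitive Treat opposite-polarity maps as different
#'   states (default TRUE).
#' @param weights Optional per-map weights (defaults to the pool's GFP).
#' @return An object of class `microstate_set`: `templates` (k x channels,
#'   unit GFP, average-referenced, ids `MS1..MSk` ordered by cluster mass),
#'   `k`, `polarity_sensitive` and provenance.
#' @export
cluster_microstates <- function(maps, k, polarity_sensitive = TRUE,
                                weights = NULL) {
  pool <- prepare_pool(maps, weights)
  fits <- aahc(pool$maps, pool$w, k_keep = k,
               polarity_sensitive = polarity_sensitive)
  new_microstate_set(fits[[as.character(k)]], pool$montage,
                     polarity_sensitive,
                     provenance = list(n_maps = nrow(pool$maps), k = k))
}

prepare_pool <- function(maps, weights = NULL) {
  if (inherits(maps, "map_pool")) {
    w <- if (is.null(weights)) maps$info$gfp else weights
    list(maps = maps$maps, w = w, montage = maps$montage)
  } else {
    m <- as.matrix(maps)
    m <- m - rowMeans(m)
    g <- apply(m, 1, gfp)
    if (any(g == 0)) abort("cannot cluster zero-GFP maps")
    list(maps = m / g, w = if (is.null(weights)) g else weights,
         montage = colnames(maps) %||% paste0("ch", seq_len(ncol(m))))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_microstate_set <- function(templates, montage, polarity_sensitive,
                               provenance = list()) {
  k <- nrow(templates)
  rownames(templates) <- paste0("MS", seq_len(k))
  colnames(templates) <- montage
  r <- map_correlation(templates, templates)
  diag(r) <- 0
  if (k > 1 && max(abs(r)) >= 1 - 1e-12) {
    abort("templates must be pairwise non-identical")
  }
  structure(list(templates = templates, k = k, montage = montage,
                 polarity_sensitive = polarity_sensitive,
                 provenance = provenance),
            class = "microstate_set")
}

#' @export
print.microstate_set <- function(x, ...) {
  cat(sprintf("<microstate_set> %d templates x %d channels (%s)\n", x$k,
              ncol(x$templates),
              if (x$polarity_sensitive) "polarity-sensitive"
              else "polarity-invariant"))
  invisible(x)
}

#' @export
tidy.microstate_set <- function(x, ...) {
  tibble::tibble(
    template_id = rep(rownames(x$templates), each = ncol(x$templates)),
    channel = rep(x$montage, times = x$k),
    loading = as.vector(t(x$templates))
  )
}

# AAHC descent from singletons down to min(k_keep); returns a named list of
# template matrices for every k in k_keep. Weighted variant: each map
# contributes (w * r)^2 to its cluster's explained variance.
aahc <- function(maps, w, k_keep, polarity_sensitive = TRUE) {
  n <- nrow(maps)
  k_keep <- sort(unique(as.integer(k_keep)), decreasing = TRUE)
  if (max(k_keep) > n) abort("k exceeds the number of maps")
  assign <- seq_len(n)
  templates <- maps
  active <- rep(TRUE, n)
  out <- list()
  template_of <- function(members) {
    m <- maps[members, , drop = FALSE]
    ref <- m[which.max(w[members]), ]
    if (!polarity_sensitive) {
      flip <- sign(map_correlation(m, matrix(ref, 1)))
      flip[flip == 0] <- 1
      m <- m * as.vector(flip)
    }
    tm <- colSums(m * w[members]) / sum(w[members])
    tm <- tm - mean(tm)
    g <- gfp(tm)
    if (g == 0) tm <- ref else tm <- tm / g
    tm
  }
  cluster_ev <- function(cl) {
    members <- which(assign == cl)
    r <- map_correlation(maps[members, , drop = FALSE],
                         matrix(templates[cl, ], 1))
    sum((w[members] * assign_score(as.vector(r), polarity_sensitive))^2)
  }
  evs <- vapply(seq_len(n), cluster_ev, 0)
  n_clusters <- n
  if (n %in% k_keep) {
    out[[as.character(n)]] <- templates[active, , drop = FALSE]
  }
  while (n_clusters > min(k_keep)) {
    live <- which(active)
    worst <- live[which.min(evs[live])]
    members <- which(assign == worst)
    active[worst] <- FALSE
    n_clusters <- n_clusters - 1
    live <- which(active)
    r <- map_correlation(maps[members, , drop = FALSE],
                         templates[live, , drop = FALSE])
    target <- live[max.col(assign_score(r, polarity_sensitive),
                           ties.method = "first")]
    assign[members] <- target
    for (cl in unique(target)) {
      templates[cl, ] <- template_of(which(assign == cl))
      evs[cl] <- cluster_ev(cl)
    }
    if (n_clusters %in% k_keep) {
      tm <- templates[live, , drop = FALSE]
      sizes <- vapply(live, function(cl) sum(w[assign == cl]), 0)
      out[[as.character(n_clusters)]] <-
        tm[order(sizes, decreasing = TRUE), , drop = FALSE]
    }
  }
  out
}

#' Choose the number of microstates by split-half cross-validation
#'
#' Repeatedly splits subjects in half within every group: templates are
#' identified on the training half's consistent-timepoint average maps and
#' the signal they explain is measured on the held-out half's maps
#' (GFP-weighted explained variance). The optimal `k*` is the largest k
#' before the mean cross-validated gain of adding one more template drops
#' below `gain_threshold` (default one percentage point) -- the marginal
#' elbow of the CV curve.
#'
#' @param groups Named list of [epoch_set()]s.
#' @param tct_results Matching list of [tct()] results identifying the
#'   consistent timepoints.
#' @param k_range Candidate numbers of microstates (default 2:12).
#' @param n_iter Number of random split-half iterations (default 100).
#' @param split Fraction of subjects in the training half (default 0.5).
#' @param seed Integer seed.
#' @param gain_threshold Minimum mean explained-variance gain (fraction,
#'   default 0.01) for an extra template to be worth keeping.
#' @param polarity_sensitive Passed to the clustering.
#' @return List: `k_star`, `curve` (tibble of k, mean/sd held-out explained
#'   variance, mean gain) and the call parameters.
#' @export
select_k <- function(groups, tct_results, k_range = 2:12, n_iter = 100,
                     split = 0.5, seed = 1L, gain_threshold = 0.01,
                     polarity_sensitive = TRUE) {
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  n_sub <- vapply(groups, function(g) dim(g$data)[1], 0L)
  if (any(n_sub < 4)) abort("split-half selection needs at least 4 subjects per group")
  k_range <- sort(unique(as.integer(k_range)))
  keep_idx <- lapply(names(groups), function(g) which(tct_results[[g]]$significant))
  names(keep_idx) <- names(groups)
  if (all(vapply(keep_idx, length, 0L) == 0)) {
    abort("no topographically consistent timepoints to pool")
  }
  windows <- lapply(names(groups), function(g) {
    res <- tct_results[[g]]
    window_epochs(groups[[g]],
                  c(res$times_ms[1],
                    res$times_ms[length(res$times_ms)] +
                      1000 / groups[[g]]$fs_hz))
  })
  names(windows) <- names(groups)
  half_maps <- function(g, subjects) {
    avg <- grand_average(windows[[g]], subjects)
    idx <- keep_idx[[g]]
    gv <- gfp_columns(avg)
    idx <- idx[gv[idx] > 0]
    m <- t(avg[, idx, drop = FALSE])
    m <- m - rowMeans(m)
    list(maps = m / apply(m, 1, gfp), w = gv[idx])
  }
  with_seed(seed, {
    ev <- matrix(NA_real_, n_iter, length(k_range),
                 dimnames = list(NULL, k_range))
    for (it in seq_len(n_iter)) {
      train <- list()
      test <- list()
      for (g in names(groups)) {
        ns <- n_sub[[g]]
        tr <- sample.int(ns, max(2, round(split * ns)))
        train[[g]] <- half_maps(g, tr)
        test[[g]] <- half_maps(g, setdiff(seq_len(ns), tr))
      }
      tr_maps <- do.call(rbind, lapply(train, `[[`, "maps"))
      tr_w <- unlist(lapply(train, `[[`, "w"))
      te_maps <- do.call(rbind, lapply(test, `[[`, "maps"))
      te_w <- unlist(lapply(test, `[[`, "w"))
      fits <- aahc(tr_maps, tr_w, k_keep = k_range,
                   polarity_sensitive = polarity_sensitive)
      for (k in k_range) {
        tm <- fits[[as.character(k)]]
        if (is.null(tm)) next
        r <- assign_score(map_correlation(te_maps, tm), polarity_sensitive)
        best <- apply(r, 1, max)
        ev[it, as.character(k)] <- sum((te_w * best)^2) / sum(te_w^2)
      }
    }
    curve <- tibble::tibble(
      k = k_range,
      mean_ev = colMeans(ev, na.rm = TRUE),
      sd_ev = apply(ev, 2, sd, na.rm = TRUE)
    )
    curve$gain <- c(NA, diff(curve$mean_ev))
    below <- which(!is.na(curve$gain) & curve$gain < gain_threshold)
    k_star <- if (length(below)) {
      if (min(below) == 2) k_range[1] else k_range[min(below) - 1]
    } else {
      k_range[length(k_range)]
    }
    list(k_star = k_star, curve = curve, n_iter = n_iter, split = split,
         gain_threshold = gain_threshold, seed = seed)
  })
}

#' Back-fit microstate templates to a group-average response
#'
#' Projects every timepoint's average map onto each template: the
#' activation `c_m(t)` is the squared spatial correlation between the map
#' and template m (under the polarity-sensitive convention, negative
#' correlations explain nothing). The total explained variance over the
#' window is the GFP-weighted best-template share,
#' `sum_t (GFP_t^2 max_m c_m(t)) / sum_t GFP_t^2`.
#'
#' @param x An [epoch_set()] (averaged across subjects first) or a
#'   channels x time matrix of an average response.
#' @param set A [cluster_microstates()] `microstate_set`.
#' @param times_ms Time axis (taken from the epoch set if omitted).
#' @return An object of class `activation_series`: `c` (templates x time,
#'   in `[0, 1]`, `NA` at zero-GFP timepoints), `gfp`, `times_ms`,
#'   `explained_variance`.
#' @export
fit_microstates <- function(x, set, times_ms = NULL) {
  stopifnot(inherits(set, "microstate_set"))
  if (inherits(x, "epoch_set")) {
    if (!identical(x$montage, set$montage)) abort("montage mismatch")
    times_ms <- x$times_ms
    avg <- grand_average(x)
  } else {
    avg <- as.matrix(x)
    if (nrow(avg) != ncol(set$templates)) abort("montage mismatch")
    if (is.null(times_ms)) times_ms <- seq_len(ncol(avg)) - 1
  }
  avg <- sweep(avg, 2, colMeans(avg))
  g <- gfp_columns(avg)
  ok <- g > 0
  cmat <- matrix(NA_real_, set$k, ncol(avg),
                 dimnames = list(rownames(set$templates), NULL))
  if (any(ok)) {
    norm <- sweep(avg[, ok, drop = FALSE], 2, g[ok], "/")
    r <- map_correlation(set$templates, t(norm))
    sc <- if (set$polarity_sensitive) pmax(r, 0) else abs(r)
    cmat[, ok] <- sc^2
  }
  best <- apply(cmat, 2, function(v) if (all(is.na(v))) 0 else max(v, na.rm = TRUE))
  ev <- if (sum(g^2) > 0) sum(g^2 * best) / sum(g^2) else 0
  structure(list(c = cmat, gfp = g, times_ms = times_ms,
                 template_ids = rownames(set$templates),
                 polarity_sensitive = set$polarity_sensitive,
                 explained_variance = ev),
            class = "activation_series")
}

#' @export
print.activation_series <- function(x, ...) {
  cat(sprintf("<activation_series> %d templates x %d timepoints; %.1f%% of signal explained\n",
              nrow(x$c), ncol(x$c), 100 * x$explained_variance))
  invisible(x)
}

#' @export
tidy.activation_series <- function(x, ...) {
  out <- tibble::tibble(
    template_id = rep(x$template_ids, times = ncol(x$c)),
    time_ms = rep(x$times_ms, each = nrow(x$c)),
    activation = as.vector(x$c),
    gfp = rep(x$gfp, each = nrow(x$c))
  )
  if (!is.null(x$active)) out$active <- as.vector(x$active)
  out
}

#' @export
glance.activation_series <- function(x, ...) {
  tibble::tibble(n_templates = nrow(x$c), n_timepoints = ncol(x$c),
                 explained_variance = x$explained_variance)
}

#' Pool baseline topographies as the activation null set
#'
#' Collects every subject's map at every baseline timepoint across the
#' supplied groups; these "random" topographies define the null level of
#' explained variance for [activation_significance()].
#'
#' @param groups List of [epoch_set()]s.
#' @param baseline_window_ms Baseline period, default `c(-500, 0)` ms.
#' @return Matrix (maps x channels) of average-referenced baseline maps.
#' @export
baseline_map_pool <- function(groups, baseline_window_ms = c(-500, 0)) {
  if (inherits(groups, "epoch_set")) groups <- list(groups)
  pool <- list()
  for (es in groups) {
    w <- window_epochs(es, baseline_window_ms)
    d <- w$data
    m <- matrix(aperm(d, c(2, 1, 3)), nrow = dim(d)[2])  # ch x (sub*time)
    pool[[length(pool) + 1]] <- t(m)
  }
  out <- do.call(rbind, pool)
  out - rowMeans(out)
}

#' Test microstate activations against a baseline-topography null
#'
#' At every timepoint the observed activation of each template is compared
#' with the activation achieved by random baseline topographies (sampled
#' with replacement from the baseline pool) against the same average map.
#' A template is active where its observed activation exceeds the null's
#' 95th percentile in continuous runs of at least `min_run_ms`
#' (default 5% of the 1 s postlance period, i.e. 50 ms).
#'
#' @param series An `activation_series` from [fit_microstates()].
#' @param x The fitted average (the same [epoch_set()] or matrix passed to
#'   [fit_microstates()]).
#' @param baseline_pool Matrix of baseline maps from [baseline_map_pool()].
#' @param alpha Right-tailed level (default 0.05).
#' @param n_iter Null draws per timepoint (default 5000).
#' @param seed Integer seed.
#' @param min_run_ms Minimum continuous run; default 5% of
#'   `postlance_ms`.
#' @param postlance_ms Duration of the postlance period used for the
#'   run-length rule (default 1000 ms).
#' @return The series with `active` (templates x time logical mask),
#'   `null_q` (the per-timepoint null quantile) and run parameters
#'   attached.
#' @export
activation_significance <- function(series, x, baseline_pool,
                                    alpha = 0.05, n_iter = 5000, seed = 1L,
                                    min_run_ms = NULL, postlance_ms = 1000) {
  stopifnot(inherits(series, "activation_series"))
  if (is.null(dim(baseline_pool)) || nrow(baseline_pool) == 0) {
    abort("baseline pool is empty")
  }
  if (is.null(min_run_ms)) min_run_ms <- 0.05 * postlance_ms
  dt <- series$times_ms[2] - series$times_ms[1]
  if (min_run_ms > length(series$times_ms) * dt) {
    warn("minimum run exceeds the fitted window: no activation can survive")
  }
  avg <- if (inherits(x, "epoch_set")) grand_average(x) else as.matrix(x)
  avg <- sweep(avg, 2, colMeans(avg))
  g <- gfp_columns(avg)
  ok <- g > 0
  bp <- baseline_pool - rowMeans(baseline_pool)
  bg <- apply(bp, 1, gfp)
  bp <- bp[bg > 0, , drop = FALSE] / bg[bg > 0]
  with_seed(seed, {
    draw <- bp[sample.int(nrow(bp), n_iter, replace = TRUE), , drop = FALSE]
    q <- rep(NA_real_, ncol(avg))
    if (any(ok)) {
      norm <- sweep(avg[, ok, drop = FALSE], 2, g[ok], "/")
      r <- map_correlation(draw, t(norm))
      sc <- if (series$polarity_sensitive) pmax(r, 0) else abs(r)
      q[ok] <- apply(sc^2, 2, null_threshold, alpha = alpha)
    }
    active <- matrix(FALSE, nrow(series$c), ncol(series$c),
                     dimnames = dimnames(series$c))
    for (m in seq_len(nrow(series$c))) {
      raw <- !is.na(series$c[m, ]) & !is.na(q) & series$c[m, ] > q
      active[m, ] <- run_length_filter(raw, series$times_ms, min_run_ms)$keep
    }
    series$active <- active
    series$null_q <- q
    series$alpha <- alpha
    series$min_run_ms <- min_run_ms
    series$n_iter <- n_iter
    series$seed <- seed
    series
  })
}

#' Extract microstate events (onset, duration, power) from activation masks
#'
#' Contiguous active runs of one template are candidate events; two runs
#' merge into one event when the gap between them is no larger than that
#' template's mean run duration (pooled across occurrences -- and across
#' groups when `mean_durations` from [pooled_mean_durations()] is given,
#' mirroring the rule that repeat visits are separate events only if the
#' separation exceeds the microstate's average duration). Onset is the
#' first active sample's latency (negative onsets are legitimate: the
#' tested window starts before the stimulus), duration the covered time,
#' and power the integral of `GFP(t) * c_m(t)` over the event, in
#' microvolt-milliseconds.
#'
#' @param series An `activation_series` with masks from
#'   [activation_significance()].
#' @param mean_durations Optional named vector (template id -> mean run
#'   duration in ms) pooled across groups; computed from this series when
#'   missing.
#' @return Tibble: `template_id`, `occurrence`, `onset_ms`, `duration_ms`,
#'   `power_uvms`.
#' @export
extract_events <- function(series, mean_durations = NULL) {
  stopifnot(inherits(series, "activation_series"))
  if (is.null(series$active)) {
    abort("run activation_significance() before extracting events")
  }
  dt <- series$times_ms[2] - series$times_ms[1]
  if (is.null(mean_durations)) {
    mean_durations <- pooled_mean_durations(list(series))
  }
  out <- list()
  for (m in seq_len(nrow(series$active))) {
    id <- rownames(series$active)[m]
    runs <- mask_runs(series$active[m, ])
    if (!nrow(runs)) next
    md <- mean_durations[[id]] %||% (mean(runs$len) * dt)
    merged <- merge_runs(runs, gap_max = md / dt)
    for (i in seq_len(nrow(merged))) {
      idx <- merged$start[i]:merged$end[i]
      cvals <- series$c[m, idx]
      cvals[is.na(cvals)] <- 0
      act <- series$active[m, idx]
      out[[length(out) + 1]] <- tibble::tibble(
        template_id = id, occurrence = i,
        onset_ms = series$times_ms[merged$start[i]],
        duration_ms = (merged$end[i] - merged$start[i] + 1) * dt,
        power_uvms = sum(series$gfp[idx] * cvals * act) * dt
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(template_id = character(), occurrence = integer(),
                          onset_ms = numeric(), duration_ms = numeric(),
                          power_uvms = numeric()))
  }
  dplyr::bind_rows(out)
}

mask_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 len = r$lengths[keep])
}

# merge runs whose inter-run gap (samples) is <= gap_max samples
merge_runs <- function(runs, gap_max) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, ]
  for (i in 2:nrow(runs)) {
    gap <- runs$start[i] - out$end[nrow(out)] - 1
    if (gap <= gap_max) {
      out$end[nrow(out)] <- runs$end[i]
      out$len[nrow(out)] <- out$end[nrow(out)] - out$start[nrow(out)] + 1
    } else {
      out <- dplyr::bind_rows(out, runs[i, ])
    }
  }
  out
}

#' Mean activation-run duration per template, pooled across groups
#'
#' @param series_list List of `activation_series` with masks (typically one
#'   per group fitted with the same template set).
#' @return Named numeric vector: template id -> mean run duration (ms).
#' @export
pooled_mean_durations <- function(series_list) {
  durs <- list()
  for (s in series_list) {
    dt <- s$times_ms[2] - s$times_ms[1]
    for (m in seq_len(nrow(s$active))) {
      id <- rownames(s$active)[m]
      runs <- mask_runs(s$active[m, ])
      if (nrow(runs)) {
        durs[[id]] <- c(durs[[id]], runs$len * dt)
      }
    }
  }
  vapply(durs, mean, 0)
}

#' Mean global field power of an average response over a window
#'
#' The total field power summarizes the overall strength of the average
#' pain-related cortical response: the mean GFP of the group average over
#' the window (default the first second after the lance), in microvolts.
#'
#' @param x An [epoch_set()] or channels x time matrix average.
#' @param times_ms Time axis when `x` is a matrix.
#' @param window_ms Averaging window, default `c(0, 1000)` ms.
#' @return Scalar mean GFP (microvolts).
#' @export
total_field_power <- function(x, times_ms = NULL, window_ms = c(0, 1000)) {
  if (inherits(x, "epoch_set")) {
    times_ms <- x$times_ms
    avg <- grand_average(x)
  } else {
    avg <- as.matrix(x)
  }
  idx <- which(times_ms >= window_ms[1] & times_ms < window_ms[2])
  if (!length(idx)) abort("window contains no samples")
  mean(gfp_columns(avg[, idx, drop = FALSE]))
}
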