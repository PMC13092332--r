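# Place-field detection and per-lap field dynamics.

# strict local maxima on a circular series; plateaus contribute their leftmost
# bin only
local_peaks_circ <- function(y) {
  n <- length(y)
  peaks <- integer(0)
  for (i in seq_len(n)) {
    # previous differing value (circularly)
    j <- i
    repeat {
      j <- wrap_bin(j - 1L, n)
      if (j == i || y[j] != y[i]) break
    }
    if (j == i || y[j] >= y[i]) next          # not rising into i, or constant
    if (y[wrap_bin(i - 1L, n)] == y[i]) next  # plateau: keep leftmost bin only
    k <- i
    repeat {
      k <- wrap_bin(k + 1L, n)
      if (k == i || y[k] != y[i]) break
    }
    if (y[k] < y[i]) peaks <- c(peaks, i)
  }
  peaks
}

# scan outward from `peak` in direction `dir` (+1/-1); boundary is the nearer
# of (a) the first bin below `med`, or (b) the first local trough beyond which
# the trace reaches below 70% of the peak value
scan_boundary <- function(y, peak, dir, med, peak_val) {
  n <- length(y)
  horizon <- floor(n / 2)
  for (d in seq_len(n - 1L)) {
    b <- wrap_bin(peak + dir * d, n)
    if (y[b] < med) return(d)
    prv <- wrap_bin(b - dir, n)
    nxt <- wrap_bin(b + dir, n)
    if (y[b] <= y[prv] && y[b] <= y[nxt]) {
      ahead <- y[wrap_bin(b + dir * (0:horizon), n)]
      if (min(ahead) < 0.7 * peak_val) return(d)
    }
  }
  n - 1L
}

#' Detect place fields in a lap-by-bin activity matrix
#'
#' Three-step criterion on one cell's occupancy-normalized dF/F matrix.
#' Step 1: the lap-averaged tuning curve is smoothed with a 5-bin raised-cosine
#' window; local peaks exceeding `peak_thresh` times its 50th percentile are
#' candidate fields, with boundaries at the nearer of the first bin below the
#' 50th percentile or the first trough beyond which the curve falls below 70%
#' of the peak. Overlapping candidates are merged, keeping the higher peak.
#' Step 2: the within-boundary per-lap peak must exceed `peak_thresh` times the
#' baseline (50th minus 5th percentile of all bins and laps) on at least
#' `max(ceiling(laps/3), 5)` laps. Step 3: fields narrower than 20 cm or wider
#' than 150 cm are discarded. A cell may own several fields.
#'
#' @param binned a `binned_activity` (dF/F) for one cell, >= 10 laps.
#' @param peak_thresh multiplier on the 50th percentile / baseline (3.5).
#' @param smooth_bins smoothing window for the lap average (5 bins).
#' @param min_size_cm,max_size_cm field-extent limits in cm.
#' @param min_lap_frac,min_laps_active lap-consistency requirement:
#'   `max(ceiling(laps * min_lap_frac), min_laps_active)` active laps.
#' @return data frame of class `place_field_table`, one row per field, with a
#'   list-column `bins` (field bins in track order), `peak_bin`, `extent_cm`,
#'   `onset_lap`, `n_active_laps` and `baseline`. Attributes `n_candidates`
#'   (fields entering the size filter) and `n_removed_size` (fields it
#'   removed) support filter-consistency audits.
#' @export
detect_fields <- function(binned, peak_thresh = 3.5, smooth_bins = 5,
                          min_size_cm = 20, max_size_cm = 150,
                          min_lap_frac = 1 / 3, min_laps_active = 5) {
  rate <- binned$rate
  n_laps <- nrow(rate)
  n_bins <- ncol(rate)
  bin_size <- binned$bin_size_cm
  if (n_laps < 10L) {
    stop("inclusion criterion not met: fewer than 10 laps in this environment")
  }
  empty <- data.frame(peak_bin = integer(0), start_bin = integer(0),
                      end_bin = integer(0), n_bins = integer(0),
                      extent_cm = numeric(0), onset_lap = integer(0),
                      n_active_laps = integer(0), peak_rate = numeric(0),
                      baseline = numeric(0))
  empty$bins <- vector("list", 0L)
  class(empty) <- c("place_field_table", "data.frame")
  avg <- colMeans(rate, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  if (all(is.na(avg))) return(empty)
  avg_s <- smooth_circular(avg, smooth_bins)
  med <- stats::median(avg_s)
  peaks <- local_peaks_circ(avg_s)
  peaks <- peaks[avg_s[peaks] > peak_thresh * med]
  if (!length(peaks)) {
    attr(empty, "n_candidates") <- 0L
    attr(empty, "n_removed_size") <- 0L
    return(empty)
  }
  cand <- lapply(peaks, function(p) {
    # the field is the span strictly inside the two stopping bins (the
    # stopping bins themselves are already below threshold / past the trough)
    dl <- scan_boundary(avg_s, p, -1L, med, avg_s[p])
    dr <- scan_boundary(avg_s, p, +1L, med, avg_s[p])
    bins <- wrap_bin(seq(p - max(dl - 1L, 0L), p + max(dr - 1L, 0L)), n_bins)
    span <- wrap_bin(seq(p - dl, p + dr), n_bins)  # incl. boundary bins
    list(peak = p, bins = bins, span = span, peak_val = avg_s[p])
  })
  # merge candidates whose boundaries overlap by >= 1 bin: keep the higher peak
  ord <- order(vapply(cand, `[[`, numeric(1), "peak_val"), decreasing = TRUE)
  kept <- list()
  used <- logical(n_bins)
  for (i in ord) {
    b <- cand[[i]]$span
    if (!any(used[b])) {
      kept[[length(kept) + 1L]] <- cand[[i]]
      used[b] <- TRUE
    }
  }
  # step 2: per-lap activity criterion
  baseline <- stats::quantile(rate, 0.5, na.rm = TRUE, names = FALSE) -
    stats::quantile(rate, 0.05, na.rm = TRUE, names = FALSE)
  need <- max(ceiling(n_laps * min_lap_frac), min_laps_active)
  rows <- list()
  n_candidates <- 0L
  n_removed_size <- 0L
  for (f in kept) {
    sub <- rate[, f$bins, drop = FALSE]
    lap_peak <- apply(sub, 1L, function(z) {
      if (all(is.na(z))) -Inf else max(z, na.rm = TRUE)
    })
    active <- lap_peak > peak_thresh * baseline
    if (sum(active) < need) next
    n_candidates <- n_candidates + 1L
    extent <- length(f$bins) * bin_size
    if (extent < min_size_cm || extent > max_size_cm) {
      n_removed_size <- n_removed_size + 1L
      next
    }
    rows[[length(rows) + 1L]] <- list(
      peak_bin = f$peak, start_bin = f$bins[1L],
      end_bin = f$bins[length(f$bins)], n_bins = length(f$bins),
      extent_cm = extent, onset_lap = which(active)[1L],
      n_active_laps = sum(active), peak_rate = f$peak_val,
      baseline = baseline, bins = list(f$bins)
    )
  }
  out <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) {
      d <- data.frame(r[setdiff(names(r), "bins")])
      d$bins <- r["bins"]$bins
      d
    }))
  } else empty
  class(out) <- c("place_field_table", "data.frame")
  attr(out, "n_candidates") <- n_candidates
  attr(out, "n_removed_size") <- n_removed_size
  attr(out, "bin_size_cm") <- bin_size
  out
}

#' Detect fields for every cell of a session in one environment
#'
#' @param session a `vr_session`.
#' @param dff list of per-cell dF/F series (from [preprocess_session()]).
#' @param env environment label, `"fam"` or `"nov"`.
#' @param ... passed on to [detect_fields()].
#' @return a `place_field_table` with a `cell` and `env` column (zero rows if
#'   no cell has a field).
#' @export
detect_fields_session <- function(session, dff, env, ...) {
  out <- list()
  for (ci in seq_along(dff)) {
    binned <- bin_by_position(session, dff[[ci]], env = env)
    ft <- detect_fields(binned, ...)
    if (nrow(ft)) {
      ft$cell <- ci
      ft$env <- env
      out[[length(out) + 1L]] <- ft
    }
  }
  if (!length(out)) {
    res <- detect_fields(bin_by_position(session, rep(0, nrow(session$frames)),
                                         env = env), ...)
    res$cell <- integer(0)
    res$env <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  class(res) <- c("place_field_table", "data.frame")
  res
}

#' Skaggs spatial information (bits per event)
#'
#' `SI = sum_i p_i (f_i / fbar) log2(f_i / fbar)` with `fbar = sum_i p_i f_i`;
#' bins with zero activity contribute zero.
#'
#' @param lap_avg_events non-negative activity per bin (lap-averaged event
#'   amplitude rate).
#' @param occupancy_prob occupancy probability per bin, summing to 1.
#' @return spatial information in bits per event (`>= 0`).
#' @export
spatial_information <- function(lap_avg_events, occupancy_prob) {
  f <- lap_avg_events
  p <- occupancy_prob
  if (length(f) != length(p)) stop("activity and occupancy lengths differ")
  ok <- !is.na(f) & !is.na(p)
  f <- f[ok]; p <- p[ok]
  if (any(f < 0) || any(p < 0)) stop("activity and occupancy must be >= 0")
  if (abs(sum(p) - 1) > 1e-6) stop("occupancy probabilities must sum to 1")
  if (all(f == 0)) stop("spatial information undefined for all-zero activity")
  fbar <- sum(p * f)
  pos <- f > 0 & p > 0
  sum(p[pos] * (f[pos] / fbar) * log2(f[pos] / fbar))
}

#' Circular-shift null distribution for spatial information
#'
#' Each shuffle independently rotates every lap's bin series by a uniformly
#' random offset, then the lap-averaged (2-bin smoothed) map's SI is
#' recomputed, yielding a null distribution against which the observed SI is
#' ranked.
#'
#' @param binned a `binned_activity` of (unthresholded) event amplitudes.
#' @param n_shuffles number of shuffles (default 100).
#' @param seed optional RNG seed.
#' @param smooth_bins smoothing applied to the lap-averaged map before SI
#'   (2-bin raised cosine, matching the rate-map convention).
#' @return list of class `si_curve`: `si`, `null` (length `n_shuffles`),
#'   `percentile` of the observed SI within the null.
#' @export
si_shuffle_null <- function(binned, n_shuffles = 100, seed = NULL,
                            smooth_bins = 2) {
  if (nrow(binned$rate) < 2L) stop("need at least 2 laps")
  if (!is.null(seed)) set.seed(seed)
  n_bins <- ncol(binned$rate)
  p <- colSums(binned$occupancy)
  p <- p / sum(p)
  map_si <- function(rate) {
    avg <- colMeans(rate, na.rm = TRUE)
    avg[!is.finite(avg)] <- NA_real_
    avg <- smooth_circular(avg, smooth_bins)
    avg <- pmax(avg, 0)
    if (all(avg == 0)) return(0)
    spatial_information(avg, p)
  }
  si <- map_si(binned$rate)
  null <- vapply(seq_len(n_shuffles), function(s) {
    shifts <- sample.int(n_bins, nrow(binned$rate), replace = TRUE)
    shuf <- binned$rate
    for (l in seq_len(nrow(shuf))) {
      shuf[l, ] <- shuf[l, wrap_bin(seq_len(n_bins) - shifts[l], n_bins)]
    }
    map_si(shuf)
  }, numeric(1))
  structure(list(si = si, null = null,
                 percentile = mean(null < si) * 100),
            class = "si_curve")
}

#' @export
print.si_curve <- function(x, ...) {
  cat(sprintf("<si_curve> SI = %.3f bits/event; %d shuffles, percentile %.1f\n",
              x$si, length(x$null), x$percentile))
  invisible(x)
}

# signed in-field bin offsets (cm) relative to the field peak, in track order
field_offsets_cm <- function(field, n_bins, bin_size) {
  bins <- field$bins[[1L]]
  arc <- seq_along(bins) - match(field$peak_bin, bins)
  arc * bin_size
}

#' Per-lap center-of-mass deviation of a place field
#'
#' On each lap the COM is the amplitude-weighted mean of in-boundary bin
#' positions (expressed as signed offsets from the field peak, so fields that
#' wrap the track seam average correctly). Laps before the field's onset lap or
#' with fewer than `min_events` in-boundary events are `NA`. Reported values
#' are deviations from the across-lap mean COM; negative deviations are
#' backward (opposite to the direction of motion).
#'
#' @param field one-row subset of a `place_field_table`.
#' @param events_binned `binned_activity` from [bin_events_by_position()] on
#'   amplitude-thresholded events (must carry a `counts` matrix).
#' @param min_events minimum in-boundary events per lap (default 2).
#' @return numeric vector of per-lap COM deviations in cm (`NA` = excluded).
#' @export
field_com_per_lap <- function(field, events_binned, min_events = 2) {
  bins <- field$bins[[1L]]
  n_bins <- ncol(events_binned$rate)
  off <- field_offsets_cm(field, n_bins, events_binned$bin_size_cm)
  n_laps <- nrow(events_binned$rate)
  onset <- field$onset_lap %||% 1L
  com <- rep(NA_real_, n_laps)
  for (l in seq_len(n_laps)) {
    if (l < onset) next
    w <- events_binned$rate[l, bins]
    k <- events_binned$counts[l, bins]
    w[is.na(w)] <- 0
    if (sum(k) < min_events || sum(w) <= 0) next
    com[l] <- sum(w * off) / sum(w)
  }
  if (all(is.na(com))) {
    warning("field has no laps passing the event criterion")
    return(com)
  }
  com - mean(com, na.rm = TRUE)
}

#' Per-lap field size from deconvolved events
#'
#' Size on each included lap is the distance between the first and the last
#' in-boundary event-containing bin (in track order through the field), in cm.
#' Laps with fewer than `min_events` in-boundary events (or before onset) are
#' `NA`; a lap with all events in one bin has size 0.
#'
#' @inheritParams field_com_per_lap
#' @return numeric vector of per-lap sizes in cm.
#' @export
field_size_per_lap_dce <- function(field, events_binned, min_events = 2) {
  bins <- field$bins[[1L]]
  n_laps <- nrow(events_binned$rate)
  onset <- field$onset_lap %||% 1L
  size <- rep(NA_real_, n_laps)
  for (l in seq_len(n_laps)) {
    if (l < onset) next
    k <- events_binned$counts[l, bins]
    if (sum(k) < min_events) next
    hit <- which(k > 0)
    size[l] <- (max(hit) - min(hit)) * events_binned$bin_size_cm
  }
  size
}

#' Per-lap field size and COM from dF/F activity
#'
#' The dF/F analogue of the event-based estimators: on each lap, size is the
#' bin size times the number of in-boundary bins with activity at least half
#' the lap's in-boundary peak (width at half max), and the COM deviation is the
#' dF/F-weighted mean offset from the peak. Laps whose in-boundary peak does
#' not exceed `peak_thresh` times the detection baseline are `NA` (fields are
#' only analyzed after their formation).
#'
#' @param field one-row subset of a `place_field_table`.
#' @param binned_dff `binned_activity` of dF/F for the same environment.
#' @param baseline detection baseline (50th minus 5th percentile); defaults to
#'   the value stored on the field row.
#' @param peak_thresh activity multiplier (3.5).
#' @return data frame with columns `lap`, `size_cm`, `com_dev_cm`.
#' @export
field_metrics_dff <- function(field, binned_dff, baseline = NULL,
                              peak_thresh = 3.5) {
  bins <- field$bins[[1L]]
  baseline <- baseline %||% field$baseline
  n_bins <- ncol(binned_dff$rate)
  off <- field_offsets_cm(field, n_bins, binned_dff$bin_size_cm)
  n_laps <- nrow(binned_dff$rate)
  size <- rep(NA_real_, n_laps)
  com <- rep(NA_real_, n_laps)
  for (l in seq_len(n_laps)) {
    y <- binned_dff$rate[l, bins]
    if (all(is.na(y))) next
    pk <- max(y, na.rm = TRUE)
    if (!is.finite(pk) || pk <= peak_thresh * baseline) next
    size[l] <- sum(y >= pk / 2, na.rm = TRUE) * binned_dff$bin_size_cm
    w <- pmax(y, 0)
    w[is.na(w)] <- 0
    if (sum(w) > 0) com[l] <- sum(w * off) / sum(w)
  }
  if (any(!is.na(com))) com <- com - mean(com, na.rm = TRUE)
  data.frame(lap = seq_len(n_laps), size_cm = size, com_dev_cm = com)
}

#' Classify a field's across-lap COM shift
#'
#' Compares the COM on the first `early_laps` included laps against all later
#' included laps with a directional pooled-variance two-sample t-test at level
#' `alpha` per direction (the pooled test is exact under the null even with
#' very few early laps). A significant decrease (later mean below early mean, i.e.
#' movement opposite to the direction of travel) is `"backward"`, a
#' significant increase `"forward"`, otherwise `"none"`.
#'
#' @param per_lap_com per-lap COM deviations (cm), `NA` = excluded laps.
#' @param early_laps number of leading included laps in the early group.
#' @param alpha per-direction significance level (default 0.025).
#' @return one of `"backward"`, `"forward"`, `"none"`, with attributes `p`
#'   (directional p-value) and, when laps are insufficient, `insufficient =
#'   TRUE`.
#' @export
classify_shift <- function(per_lap_com, early_laps = 3, alpha = 0.025) {
  x <- per_lap_com[!is.na(per_lap_com)]
  if (length(x) < early_laps + 2L) {
    return(structure("none", insufficient = TRUE))
  }
  early <- x[seq_len(early_laps)]
  late <- x[-seq_len(early_laps)]
  if (length(early) < 2L || length(late) < 2L ||
      (stats::sd(early) == 0 && stats::sd(late) == 0)) {
    return(structure("none", insufficient = TRUE))
  }
  tt <- stats::t.test(early, late, var.equal = TRUE)
  p_dir <- tt$p.value / 2
  cls <- if (p_dir < alpha) {
    if (mean(late) < mean(early)) "backward" else "forward"
  } else "none"
  structure(cls, p = p_dir, t = unname(tt$statistic))
}

#' In-field versus out-of-field activity ratio per lap
#'
#' Ratio of the mean activity in the circular `in_field_cm` window centered on
#' the peak bin to the mean activity over all other bins, per lap, normalized
#' by the mean ratio over familiar-environment laps. Must be given a
#' whole-session binned matrix (both environments) so the familiar
#' normalization is defined.
#'
#' @param binned a `binned_activity` spanning both environments.
#' @param peak_bin peak bin index (1-based).
#' @param in_field_cm width of the in-field window, cm (default 30).
#' @return data frame with `lap`, `env`, `ratio`, `normalized`.
#' @export
in_out_ratio <- function(binned, peak_bin, in_field_cm = 30) {
  n_bins <- ncol(binned$rate)
  if (peak_bin < 1L || peak_bin > n_bins) stop("invalid `peak_bin`")
  centers <- bin_centers_cm(n_bins, binned$bin_size_cm)
  d <- circ_dist_cm(centers, centers[peak_bin], binned$track_length_cm)
  infield <- d <= in_field_cm / 2
  ratio <- apply(binned$rate, 1L, function(z) {
    inm <- mean(z[infield], na.rm = TRUE)
    outm <- mean(z[!infield], na.rm = TRUE)
    if (!is.finite(outm) || outm <= 0) return(NA_real_)
    inm / outm
  })
  fam_mean <- mean(ratio[binned$lap_env == "fam"], na.rm = TRUE)
  data.frame(lap = seq_len(nrow(binned$rate)), env = binned$lap_env,
             ratio = ratio, normalized = ratio / fam_mean)
}
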