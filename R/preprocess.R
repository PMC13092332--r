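#' Neuropil correction of a somatic fluorescence trace
#'
#' Subtracts a scaled copy of the surrounding neuropil signal from the somatic
#' signal, `F(t) = F_soma(t) - coefficient * F_neuropil(t)`, with the
#' conventional coefficient of 0.7.
#'
#' @param soma,neuropil equal-length numeric fluorescence series.
#' @param coefficient neuropil contamination coefficient.
#' @return corrected fluorescence series.
#' @export
neuropil_correct <- function(soma, neuropil, coefficient = 0.7) {
  if (length(soma) != length(neuropil)) {
    stop("`soma` and `neuropil` must have the same length")
  }
  soma - coefficient * neuropil
}

#' Relative fluorescence change with a running-minimum baseline
#'
#' The baseline `F0(t)` is the minimum, over a trailing window of `t2` seconds,
#' of the trailing `t1`-second running average of the trace; dF/F is
#' `(F - F0) / F0`. Windows are truncated to the available history at the start
#' of the trace (no padding). Frames where `F0 <= 0` are reported in the
#' `flagged` element and carry `NA` dF/F.
#'
#' @param trace numeric fluorescence series (finite).
#' @param frame_rate sampling rate, Hz.
#' @param t1 smoothing window, seconds.
#' @param t2 trailing minimum window, seconds; must exceed `t1`.
#' @return list of class `dff_trace` with elements `dff`, `f0`, `smoothed`,
#'   `flagged`, `t1`, `t2`, `frame_rate`.
#' @export
compute_dff <- function(trace, frame_rate, t1 = 5, t2 = 60) {
  if (!is.numeric(trace) || any(!is.finite(trace))) {
    stop("`trace` must be finite numeric")
  }
  if (frame_rate <= 0) stop("`frame_rate` must be > 0")
  if (t1 >= t2) stop("`t1` must be smaller than `t2`")
  w1 <- max(1L, round(t1 * frame_rate))
  w2 <- max(1L, round(t2 * frame_rate))
  sm <- roll_mean_trailing(trace, w1)
  f0 <- roll_min_trailing(sm, w2)
  flagged <- which(f0 <= 0)
  dff <- (trace - f0) / f0
  dff[flagged] <- NA_real_
  structure(list(dff = dff, f0 = f0, smoothed = sm, flagged = flagged,
                 t1 = t1, t2 = t2, frame_rate = frame_rate),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d frames @ %.3g Hz (t1=%gs, t2=%gs), %d flagged\n",
              length(x$dff), x$frame_rate, x$t1, x$t2, length(x$flagged)))
  invisible(x)
}

#' Remove low-amplitude deconvolved calcium events
#'
#' Marks the lower half of events by amplitude as filtered: events with
#' amplitude greater than or equal to the per-cell median amplitude are
#' retained. Ties at the median are retained, so a train with all-equal
#' amplitudes passes through unchanged.
#'
#' @param train data frame with columns `frame` and `amplitude`.
#' @return the same data frame with a logical `filtered` column (`TRUE` =
#'   removed). Use `events_kept()` to subset the retained events.
#' @export
threshold_events <- function(train) {
  stopifnot(is.data.frame(train), all(c("frame", "amplitude") %in% names(train)))
  if (nrow(train) == 0L) {
    train$filtered <- logical(0)
    return(train)
  }
  if (any(train$amplitude < 0)) stop("event amplitudes must be >= 0")
  med <- stats::median(train$amplitude)
  train$filtered <- train$amplitude < med
  train
}

#' @rdname threshold_events
#' @param events an event train, optionally carrying a `filtered` column.
#' @export
events_kept <- function(events) {
  if (is.null(events$filtered)) events else events[!events$filtered, , drop = FALSE]
}

# shared frame filter: frames of the requested environment moving at or above
# min_speed, with lap indices relabeled 1..m within the environment
frame_selection <- function(session, env = NULL, min_speed = 1) {
  fr <- session$frames
  sel <- fr$speed >= min_speed
  if (!is.null(env)) sel <- sel & fr$env == env
  lap_ids <- if (is.null(env)) seq_along(session$lap_env) else which(session$lap_env == env)
  list(idx = which(sel), lap_ids = lap_ids,
       lap_local = match(fr$lap, lap_ids))
}

#' Occupancy-normalized lap-by-bin activity matrix
#'
#' Bins a per-frame signal by position: frames below `min_speed` (stops,
#' backward movement) are excluded; the remaining signal is summed per
#' (lap, bin) and divided by the occupancy time in seconds, giving a rate.
#' Entries with zero occupancy are `NA`. The first and last bins are spatially
#' adjacent (circular track).
#'
#' @param session a `vr_session`.
#' @param signal per-frame numeric series on the session frame clock.
#' @param n_bins number of position bins.
#' @param min_speed exclusion threshold, cm/s.
#' @param env optional environment label (`"fam"`/`"nov"`) restricting to that
#'   environment's laps (rows are then relabeled 1..laps-in-environment).
#' @return object of class `binned_activity`: list with `rate` (laps x bins),
#'   `occupancy` (seconds), `lap_env`, `bin_size_cm`, `track_length_cm`.
#' @export
bin_by_position <- function(session, signal, n_bins = session$n_bins,
                            min_speed = 1, env = NULL) {
  fr <- session$frames
  if (is.null(fr$lap)) stop("session has no lap labels")
  if (length(signal) != nrow(fr)) stop("`signal` must be on the session frame clock")
  sel <- frame_selection(session, env, min_speed)
  bin_size <- session$track_length_cm / n_bins
  dt <- 1 / session$frame_rate_hz
  n_laps <- length(sel$lap_ids)
  idx <- sel$idx
  lap_loc <- sel$lap_local[idx]
  bin <- pmin(floor(fr$position[idx] / bin_size) + 1L, n_bins)
  cellidx <- (lap_loc - 1L) * n_bins + bin
  occ_n <- tabulate(cellidx, nbins = n_laps * n_bins)
  sig_sum <- numeric(n_laps * n_bins)
  if (length(idx)) {
    rs <- rowsum(signal[idx], group = cellidx)
    sig_sum[as.integer(rownames(rs))] <- rs[, 1L]
  }
  occupancy <- occ_n * dt
  rate <- sig_sum / occupancy
  rate[occ_n == 0L] <- NA_real_
  structure(list(
    rate = matrix(rate, nrow = n_laps, byrow = TRUE),
    occupancy = matrix(occupancy, nrow = n_laps, byrow = TRUE),
    lap_env = session$lap_env[sel$lap_ids],
    bin_size_cm = bin_size, track_length_cm = session$track_length_cm
  ), class = "binned_activity")
}

#' Bin deconvolved events by position
#'
#' Like [bin_by_position()] but takes an event train: the occupancy-normalized
#' amplitude rate per (lap, bin) is returned together with a raw event-count
#' matrix (used by the per-lap field estimators that require a minimum number
#' of events).
#'
#' @inheritParams bin_by_position
#' @param events data frame with `frame` and `amplitude` columns (apply
#'   [threshold_events()]/[events_kept()] first where the analysis calls for
#'   thresholded events). A `filtered` column, if present, is respected.
#' @return `binned_activity` with an extra `counts` matrix.
#' @export
bin_events_by_position <- function(session, events, n_bins = session$n_bins,
                                   min_speed = 1, env = NULL) {
  events <- events_kept(events)
  n_frames <- nrow(session$frames)
  amp <- numeric(n_frames)
  cnt <- numeric(n_frames)
  if (nrow(events)) {
    rs <- rowsum(events$amplitude, group = events$frame)
    amp[as.integer(rownames(rs))] <- rs[, 1L]
    tb <- table(events$frame)
    cnt[as.integer(names(tb))] <- as.integer(tb)
  }
  out <- bin_by_position(session, amp, n_bins = n_bins,
                         min_speed = min_speed, env = env)
  cnts <- bin_by_position(session, cnt, n_bins = n_bins,
                          min_speed = min_speed, env = env)
  counts <- cnts$rate * cnts$occupancy  # back to raw counts per (lap, bin)
  counts[is.na(counts)] <- 0
  out$counts <- round(counts)
  out
}

#' @export
print.binned_activity <- function(x, ...) {
  cat(sprintf("<binned_activity> %d laps x %d bins (%.2g cm bins), %d NA entries\n",
              nrow(x$rate), ncol(x$rate), x$bin_size_cm, sum(is.na(x$rate))))
  invisible(x)
}

#' Circular smoothing with a raised-cosine (Hanning) window
#'
#' Circular convolution with a symmetric raised-cosine kernel of
#' `window_bins` taps, normalized to unit sum, so the total signal is
#' conserved. The kernel has nonzero endpoints (for a 2-bin window it
#' degenerates to `c(0.5, 0.5)`). `NA` entries are imputed by circular linear
#' interpolation before smoothing and come back as values, not `NA`.
#'
#' @param row numeric series over position bins (circular topology).
#' @param window_bins kernel length; `>= 1` and `< length(row)`.
#' @return smoothed series.
#' @export
smooth_circular <- function(row, window_bins) {
  n <- length(row)
  if (window_bins < 1 || window_bins >= n) {
    stop("`window_bins` must be >= 1 and < length(row)")
  }
  if (all(is.na(row))) stop("all-NA row cannot be smoothed")
  x <- circ_interp_na(row)
  if (window_bins == 1L) return(x)
  k <- hanning_kernel(window_bins)
  centre <- ceiling(window_bins / 2)
  out <- numeric(n)
  for (j in seq_len(window_bins)) {
    out <- out + k[j] * x[wrap_bin(seq_len(n) + (j - centre), n)]
  }
  out
}

#' Preprocess every cell of a session
#'
#' Runs the standard per-cell chain: neuropil correction, running-baseline
#' dF/F, and amplitude thresholding of the deconvolved events.
#'
#' @param session a `vr_session`.
#' @param coefficient neuropil coefficient passed to [neuropil_correct()].
#' @param t1,t2 dF/F baseline windows in seconds, see [compute_dff()].
#' @return list with `dff` (list of per-cell dF/F series), `events` (per-cell
#'   event trains with the `filtered` flag from [threshold_events()]).
#' @export
preprocess_session <- function(session, coefficient = 0.7, t1 = 5, t2 = 60) {
  fr <- session$frame_rate_hz
  dff <- vector("list", length(session$cells))
  events <- vector("list", length(session$cells))
  for (ci in seq_along(session$cells)) {
    cell <- session$cells[[ci]]
    corrected <- neuropil_correct(cell$soma, cell$neuropil, coefficient)
    dff[[ci]] <- compute_dff(corrected, fr, t1 = t1, t2 = t2)$dff
    events[[ci]] <- threshold_events(cell$events)
  }
  list(dff = dff, events = events)
}
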