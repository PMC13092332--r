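# Bayesian position decoding with leave-one-lap-out cross-validation.

#' Precompute decoder inputs for one environment
#'
#' Collects, once per session/environment, everything the decoder needs so
#' that repeated leave-one-lap-out and neuron-subsampling calls stay cheap:
#' per-frame population event amplitudes and their cumulative sums (for
#' trailing-window activity), per-cell lap-by-bin amplitude sums, and the
#' lap-by-bin occupancy.
#'
#' @param session a `vr_session`.
#' @param events list of per-cell event trains (all amplitudes, unthresholded:
#'   decoding uses the full train).
#' @param env environment label.
#' @param min_speed frames below this speed (cm/s) are not decoded and do not
#'   enter rate maps.
#' @param smooth_bins rate-map smoothing window (9 bins).
#' @return opaque list used by [bayes_decode()] / [decoder_error_session()].
#' @export
prep_decoder <- function(session, events, env, min_speed = 1, smooth_bins = 9) {
  fr <- session$frames
  env_idx <- which(fr$env == env)
  if (!length(env_idx)) stop("no frames in environment ", env)
  lap_ids <- which(session$lap_env == env)
  n_laps <- length(lap_ids)
  n_bins <- session$n_bins
  bin_size <- session$bin_size_cm
  dt <- 1 / session$frame_rate_hz
  n_cells <- length(events)
  lap_loc <- match(fr$lap[env_idx], lap_ids)
  bin <- pmin(floor(fr$position[env_idx] / bin_size) + 1L, n_bins)
  moving <- fr$speed[env_idx] >= min_speed
  cellbin <- (lap_loc - 1L) * n_bins + bin
  occ <- tabulate(cellbin[moving], nbins = n_laps * n_bins) * dt
  occ <- matrix(occ, nrow = n_laps, byrow = TRUE)
  # per-frame amplitude per cell, restricted to this environment's frames
  A <- matrix(0, length(env_idx), n_cells)
  frame_pos <- match(seq_len(nrow(fr)), env_idx)  # session frame -> env row
  amp3 <- array(0, dim = c(n_cells, n_laps, n_bins))
  for (ci in seq_len(n_cells)) {
    ev <- events[[ci]]
    if (!is.null(ev$filtered)) ev <- ev[, c("frame", "amplitude")]
    pos <- frame_pos[ev$frame]
    ok <- !is.na(pos)
    if (any(ok)) {
      rs <- rowsum(ev$amplitude[ok], group = pos[ok])
      A[as.integer(rownames(rs)), ci] <- rs[, 1L]
      mv <- ok & moving[pos]
      if (any(mv)) {
        rs2 <- rowsum(ev$amplitude[mv], group = cellbin[frame_pos[ev$frame[mv]]])
        flat <- numeric(n_laps * n_bins)
        flat[as.integer(rownames(rs2))] <- rs2[, 1L]
        amp3[ci, , ] <- matrix(flat, nrow = n_laps, byrow = TRUE)
      }
    }
  }
  csA <- apply(A, 2L, cumsum)
  if (is.null(dim(csA))) csA <- matrix(csA, ncol = n_cells)
  list(env = env, env_idx = env_idx, lap_ids = lap_ids, n_laps = n_laps,
       n_bins = n_bins, bin_size = bin_size, dt = dt, n_cells = n_cells,
       lap_loc = lap_loc, bin = bin, moving = moving, occ = occ,
       amp3 = amp3, csA = csA, time = fr$time[env_idx],
       K = circulant_smoother(n_bins, smooth_bins),
       track_length = session$track_length_cm)
}

# rate maps (amplitude/s, smoothed, floored) and prior for a set of train laps
decoder_model <- function(prep, train_laps, cells, epsilon = 1e-6) {
  occ_train <- colSums(prep$occ[train_laps, , drop = FALSE])
  num <- apply(prep$amp3[cells, train_laps, , drop = FALSE], c(1L, 3L), sum)
  rate <- sweep(num, 2L, occ_train, "/")
  rate[!is.finite(rate)] <- 0
  rate_s <- pmax(rate %*% prep$K, epsilon)
  prior <- occ_train / sum(occ_train)
  list(rate = rate_s, prior = prior)
}

#' Decode one lap with a Bayesian decoder trained on other laps
#'
#' The prior is the relative occupancy over the training laps; each cell's
#' rate map is its occupancy-normalized mean event amplitude per bin over the
#' training laps, circularly smoothed with a 9-bin raised-cosine window and
#' floored at `epsilon`. At each test frame the observed activity is the
#' summed population amplitude over a trailing `window_s` window, and the
#' posterior combines the prior with an independent-Poisson likelihood; the
#' decoded bin is the posterior argmax (ties to the lowest bin). Frames with
#' zero window activity fall back to the prior and are flagged. Errors are
#' reported both as circular distance (primary; the track is circular) and as
#' plain absolute difference.
#'
#' @param session a `vr_session`.
#' @param events list of per-cell event trains (all amplitudes).
#' @param train_laps,test_lap lap indices *within the environment* (1-based);
#'   `test_lap` must not be in `train_laps`.
#' @param env environment label.
#' @param window_s trailing activity window, seconds (default 2).
#' @param smooth_bins rate-map smoothing window (default 9).
#' @param min_speed decoding speed threshold, cm/s.
#' @param epsilon rate floor, events/s.
#' @param prep optional precomputed [prep_decoder()] result.
#' @param cells optional cell subset (indices).
#' @return object of class `decoder_result`: per-frame data frame (`time`,
#'   `true_bin`, `decoded_bin`, `error_cm`, `error_linear_cm`, `flagged`),
#'   `mean_error_cm`, `test_lap`.
#' @export
bayes_decode <- function(session, events, train_laps, test_lap, env,
                         window_s = 2, smooth_bins = 9, min_speed = 1,
                         epsilon = 1e-6, prep = NULL, cells = NULL) {
  if (is.null(prep)) {
    prep <- prep_decoder(session, events, env, min_speed = min_speed,
                         smooth_bins = smooth_bins)
  }
  if (test_lap %in% train_laps) stop("`test_lap` must not be in `train_laps`")
  if (prep$n_laps < 2L) stop("need at least 2 laps")
  cells <- cells %||% seq_len(prep$n_cells)
  model <- decoder_model(prep, train_laps, cells, epsilon)
  res <- decode_frames(prep, model, test_lap, cells, window_s)
  structure(c(res, list(test_lap = test_lap, env = env)),
            class = "decoder_result")
}

decode_frames <- function(prep, model, test_lap, cells, window_s) {
  tf <- which(prep$lap_loc == test_lap & prep$moving)
  w <- max(1L, round(window_s / prep$dt))
  lo <- pmax(tf - w, 0L)
  cs <- rbind(0, prep$csA[, cells, drop = FALSE])
  W <- cs[tf + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  R <- model$rate * window_s                      # cells x bins expected amp
  logR <- log(R)
  term2 <- colSums(R)
  logprior <- log(pmax(model$prior, 1e-12))
  LL <- W %*% logR
  LL <- sweep(LL, 2L, term2, "-")
  LL <- sweep(LL, 2L, logprior, "+")
  flagged <- rowSums(W) == 0
  if (any(flagged)) {
    LL[flagged, ] <- matrix(logprior, sum(flagged), prep$n_bins, byrow = TRUE)
  }
  decoded <- max.col(LL, ties.method = "first")
  centers <- bin_centers_cm(prep$n_bins, prep$bin_size)
  true_bin <- prep$bin[tf]
  err <- circ_dist_cm(centers[decoded], centers[true_bin], prep$track_length)
  err_lin <- abs(centers[decoded] - centers[true_bin])
  # normalized posterior (log-sum-exp), kept for posterior-sanity checks
  mx <- apply(LL, 1L, max)
  post <- exp(LL - mx)
  post <- post / rowSums(post)
  list(frames = data.frame(time = prep$time[tf], true_bin = true_bin,
                           decoded_bin = decoded, error_cm = err,
                           error_linear_cm = err_lin, flagged = flagged),
       posterior = post,
       mean_error_cm = mean(err))
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> lap %d (%s): %d frames, mean circular error %.1f cm\n",
              x$test_lap, x$env, nrow(x$frames), x$mean_error_cm))
  invisible(x)
}

#' Session decoder error with neuron subsampling
#'
#' Repeats leave-one-lap-out decoding of every lap on random subsets of
#' `n_neurons` cells, `n_repeats` times, and averages the per-lap mean errors
#' across repeats (the cross-dataset comparison protocol). Sessions whose
#' familiar-environment mean error exceeds 30 cm are flagged for exclusion.
#'
#' @inheritParams bayes_decode
#' @param n_neurons neurons per subsample (default 146); reduced with a
#'   warning when the session has fewer cells.
#' @param n_repeats number of random subsamples (default 100).
#' @param seed optional RNG seed for the subsampling.
#' @return object of class `decoder_summary`: `per_lap` data frame (`lap`,
#'   `mean_error_cm`), `session_mean_cm`, `n_neurons`, `n_repeats`, `exclude`
#'   (familiar error gate, > 30 cm).
#' @export
decoder_error_session <- function(session, events, env, n_neurons = 146,
                                  n_repeats = 100, seed = NULL, window_s = 2,
                                  smooth_bins = 9, min_speed = 1,
                                  epsilon = 1e-6, prep = NULL) {
  if (is.null(prep)) {
    prep <- prep_decoder(session, events, env, min_speed = min_speed,
                         smooth_bins = smooth_bins)
  }
  if (!is.null(seed)) set.seed(seed)
  n_cells <- prep$n_cells
  if (n_cells < n_neurons) {
    warning(sprintf("only %d cells available; subsample size reduced", n_cells))
    n_neurons <- n_cells
  }
  n_laps <- prep$n_laps
  errs <- matrix(NA_real_, n_repeats, n_laps)
  for (r in seq_len(n_repeats)) {
    cells <- sort(sample.int(n_cells, n_neurons))
    for (l in seq_len(n_laps)) {
      model <- decoder_model(prep, setdiff(seq_len(n_laps), l), cells, epsilon)
      errs[r, l] <- decode_frames(prep, model, l, cells, window_s)$mean_error_cm
    }
  }
  per_lap <- data.frame(lap = seq_len(n_laps), mean_error_cm = colMeans(errs))
  session_mean <- mean(per_lap$mean_error_cm)
  structure(list(per_lap = per_lap, session_mean_cm = session_mean,
                 n_neurons = n_neurons, n_repeats = n_repeats, env = env,
                 exclude = env == "fam" && session_mean > 30),
            class = "decoder_summary")
}

#' @export
print.decoder_summary <- function(x, ...) {
  cat(sprintf("<decoder_summary> %s: session mean %.1f cm (%d neurons x %d repeats)%s\n",
              x$env, x$session_mean_cm, x$n_neurons, x$n_repeats,
              if (isTRUE(x$exclude)) " [exclude: familiar error > 30 cm]" else ""))
  invisible(x)
}
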