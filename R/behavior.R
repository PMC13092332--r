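# Behavioral scoring: lick precision, cell categories, transition activity.

#' Lick matrix and anticipatory lick precision
#'
#' Licks occurring within `exclusion_s` seconds after any reward delivery are
#' removed (consumption licks); the remaining licks are binarized per
#' (lap, bin) so bursts are not over-weighted. The `zone_bins` bins
#' immediately preceding each reward bin (half-open, excluding the delivery
#' bin) form the anticipatory zone of that lap's environment. Per-lap
#' precision is the number of anticipatory licked bins divided by the number
#' of licked bins remaining after exclusion; laps with no remaining licks
#' score 0. The session-level precision pools licked bins across laps. With
#' uniform licking over 100 bins and two 10-bin zones, chance level is 0.2.
#'
#' @param session a `vr_session` with reward deliveries.
#' @param exclusion_s post-reward exclusion window, seconds (default 4; 0
#'   disables).
#' @param zone_bins anticipatory zone width per reward site (default 10).
#' @return object of class `lick_matrix`: `matrix` (laps x bins, post-reward
#'   excluded), `per_lap` data frame (`lap`, `env`, `precision`),
#'   `session_precision`, `anticipatory_bins` (per environment),
#'   `excluded_licks` count.
#' @export
lick_precision <- function(session, exclusion_s = 4, zone_bins = 10) {
  fr <- session$frames
  if (is.null(session$reward_bins) || !length(unlist(session$reward_bins))) {
    stop("no reward sites defined for this session")
  }
  n_bins <- session$n_bins
  n_laps <- length(session$lap_env)
  bin <- pmin(floor(fr$position / session$bin_size_cm) + 1L, n_bins)
  lick_idx <- which(fr$lick)
  reward_t <- sort(fr$time[fr$reward > 0L])
  excluded <- rep(FALSE, length(lick_idx))
  if (exclusion_s > 0 && length(reward_t)) {
    last_rw <- findInterval(fr$time[lick_idx], reward_t)
    has_prev <- last_rw > 0L
    dt_rw <- fr$time[lick_idx][has_prev] - reward_t[last_rw[has_prev]]
    excluded[has_prev] <- dt_rw <= exclusion_s
  }
  keep_idx <- lick_idx[!excluded]
  M <- matrix(FALSE, n_laps, n_bins)
  if (length(keep_idx)) {
    M[cbind(fr$lap[keep_idx], bin[keep_idx])] <- TRUE
  }
  ant <- lapply(session$reward_bins, function(rb) {
    sort(unique(unlist(lapply(rb, function(r) {
      wrap_bin(r - seq_len(zone_bins), n_bins)
    }))))
  })
  per_lap <- data.frame(lap = seq_len(n_laps), env = session$lap_env,
                        precision = NA_real_)
  num_tot <- 0L
  den_tot <- 0L
  for (l in seq_len(n_laps)) {
    zones <- ant[[session$lap_env[l]]]
    den <- sum(M[l, ])
    num <- sum(M[l, zones])
    per_lap$precision[l] <- if (den > 0L) num / den else 0
    num_tot <- num_tot + num
    den_tot <- den_tot + den
  }
  structure(list(matrix = M, per_lap = per_lap,
                 session_precision = if (den_tot > 0L) num_tot / den_tot else 0,
                 anticipatory_bins = ant,
                 excluded_licks = sum(excluded)),
            class = "lick_matrix")
}

#' @export
print.lick_matrix <- function(x, ...) {
  cat(sprintf("<lick_matrix> %d laps x %d bins; session precision %.3f (%d licks excluded)\n",
              nrow(x$matrix), ncol(x$matrix), x$session_precision,
              x$excluded_licks))
  invisible(x)
}

#' Categorize cells by the environments in which they have fields
#'
#' @param fields_fam,fields_nov `place_field_table`s (with `cell` columns)
#'   from the two environments.
#' @param n_cells size of the cell universe.
#' @return factor with levels `familiar_only`, `novel_only`, `both`,
#'   `neither`, one entry per cell.
#' @export
categorize_cells <- function(fields_fam, fields_nov, n_cells) {
  fam <- seq_len(n_cells) %in% fields_fam$cell
  nov <- seq_len(n_cells) %in% fields_nov$cell
  out <- rep("neither", n_cells)
  out[fam & !nov] <- "familiar_only"
  out[!fam & nov] <- "novel_only"
  out[fam & nov] <- "both"
  factor(out, levels = c("familiar_only", "novel_only", "both", "neither"))
}

#' Z-scored lap-averaged activity and per-category lap series
#'
#' Each cell's activity is averaged per lap (mean over bins), then z-scored
#' against the mean and standard deviation of the lap-averaged activity of
#' all cells and all laps in the session (removing between-animal fluorescence
#' differences while preserving between-cell differences within a session).
#'
#' @param binned_list list of per-cell `binned_activity` spanning both
#'   environments.
#' @param categories factor from [categorize_cells()] (optional).
#' @return object of class `cell_category_activity`: `z` (cells x laps),
#'   `lap_env`, `categories`, and `category_series` (per-category mean
#'   z-activity per lap) when categories are given.
#' @export
zscore_lap_activity <- function(binned_list, categories = NULL) {
  lap_means <- t(vapply(binned_list, function(b) {
    m <- rowMeans(b$rate, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_
    m
  }, numeric(nrow(binned_list[[1L]]$rate))))
  mu <- mean(lap_means, na.rm = TRUE)
  sdv <- stats::sd(as.vector(lap_means), na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) {
    stop("session-wide standard deviation is zero; z-scores undefined")
  }
  z <- (lap_means - mu) / sdv
  out <- list(z = z, lap_env = binned_list[[1L]]$lap_env,
              categories = categories)
  if (!is.null(categories)) {
    out$category_series <- t(vapply(levels(categories), function(cat) {
      rows <- which(categories == cat)
      if (!length(rows)) return(rep(NA_real_, ncol(z)))
      colMeans(z[rows, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(z))))
  }
  structure(out, class = "cell_category_activity")
}

#' Hierarchical averaging of per-category lap series across sessions
#'
#' Averages first across cells within a session (already done by
#' [zscore_lap_activity()]), then across sessions of the same animal, then
#' across animals.
#'
#' @param series_list list of `category_series` matrices (categories x laps,
#'   identical shapes).
#' @param animal_ids animal identifier per session.
#' @return matrix categories x laps of grand means.
#' @export
aggregate_category_series <- function(series_list, animal_ids) {
  stopifnot(length(series_list) == length(animal_ids))
  per_animal <- lapply(unique(animal_ids), function(a) {
    ms <- series_list[animal_ids == a]
    Reduce(`+`, ms) / length(ms)
  })
  Reduce(`+`, per_animal) / length(per_animal)
}

#' Activity contrast across the environment transition
#'
#' Per-category mean z-scored activity over the last `pre_laps` familiar laps
#' versus the first `post_laps` novel laps.
#'
#' @param activity a `cell_category_activity` with categories.
#' @param pre_laps,post_laps laps on each side of the transition (default 3).
#' @return data frame with `category`, `pre_mean`, `post_mean`, `difference`.
#' @export
transition_contrast <- function(activity, pre_laps = 3, post_laps = 3) {
  env <- activity$lap_env
  fam_laps <- which(env == "fam")
  nov_laps <- which(env == "nov")
  if (length(fam_laps) < pre_laps || length(nov_laps) < post_laps) {
    stop("not enough laps on one side of the transition")
  }
  pre <- utils::tail(fam_laps, pre_laps)
  post <- utils::head(nov_laps, post_laps)
  cs <- activity$category_series
  if (is.null(cs)) stop("activity must carry categories")
  data.frame(
    category = rownames(cs),
    pre_mean = rowMeans(cs[, pre, drop = FALSE], na.rm = TRUE),
    post_mean = rowMeans(cs[, post, drop = FALSE], na.rm = TRUE),
    difference = rowMeans(cs[, post, drop = FALSE], na.rm = TRUE) -
      rowMeans(cs[, pre, drop = FALSE], na.rm = TRUE),
    row.names = NULL
  )
}

#' Per-lap running-speed profile
#'
#' @param session a `vr_session`.
#' @param min_speed stop threshold, cm/s (default 1).
#' @return data frame with `lap`, `env`, `mean_speed_cm_s` (over moving
#'   frames) and `stop_time_s` (total time below threshold).
#' @export
lap_speed_profile <- function(session, min_speed = 1) {
  fr <- session$frames
  dt <- 1 / session$frame_rate_hz
  n_laps <- length(session$lap_env)
  out <- data.frame(lap = seq_len(n_laps), env = session$lap_env,
                    mean_speed_cm_s = NA_real_, stop_time_s = 0)
  for (l in seq_len(n_laps)) {
    s <- fr$speed[fr$lap == l]
    moving <- s >= min_speed
    out$mean_speed_cm_s[l] <- if (any(moving)) mean(s[moving]) else NA_real_
    out$stop_time_s[l] <- sum(!moving) * dt
  }
  out
}
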