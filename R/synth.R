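#' Configuration for a synthetic virtual-reality session
#'
#' Builds and validates the parameter set for [generate_session()]. Defaults
#' emulate a typical head-fixed VR experiment: a circular track of 100 position
#' bins (3--5 cm each), imaging at ~7 Hz, 20 laps in a familiar environment
#' followed by an instantaneous teleport to a novel environment for 15 laps,
#' with place-tuned cells, global remapping between environments, and
#' anticipatory licking at two hidden reward sites per environment.
#'
#' @param n_cells number of simulated cells.
#' @param frac_tuned fraction of cells carrying a place field in each
#'   environment (applied per environment).
#' @param track_length_cm track circumference in cm; with `n_bins = 100` the
#'   default 400 cm gives 4 cm bins.
#' @param n_bins number of position bins the track is divided into.
#' @param frame_rate_hz imaging frame rate in Hz.
#' @param n_laps_familiar,n_laps_novel complete laps per environment
#'   (`n_laps_novel` may be 0 for single-environment sessions).
#' @param field_width_cm named vector `c(median=, sdlog=)`: place-field widths
#'   are drawn log-normal with this median and log-scale dispersion.
#' @param field_amplitude named vector `c(infield=, outfield=)`: peak in-field
#'   and baseline out-of-field deconvolved event rates, events/s.
#' @param reliability probability that a field is expressed on a given lap.
#' @param drift_cm_per_lap signed per-lap displacement of every field's center
#'   (negative = backward, i.e. opposite to the direction of motion).
#' @param remap_overlap target fraction of cells tuned in *both* environments;
#'   `NULL` (default) uses the chance level `frac_tuned^2`.
#' @param speed_profile named vector `c(mean_cm_s=, stop_prob=)`: mean running
#'   speed and per-lap probability of a pause (speed < 1 cm/s, so that the
#'   low-speed exclusion in binning is exercised).
#' @param lick_precision_target expected fraction of licked bins that fall in
#'   the anticipatory zones, in `[0, 1]`.
#' @param reward_bins list with elements `fam` and `nov`, each two bin indices
#'   (1-based) where rewards are delivered.
#' @param noise_sd additive Gaussian noise on the simulated dF/F traces.
#' @param seed integer seed; fully determines the generated session.
#' @return A validated list of class `session_config`.
#' @seealso [generate_session()], [generate_cohort()]
#' @export
session_config <- function(n_cells = 100L,
                           frac_tuned = 0.5,
                           track_length_cm = 400,
                           n_bins = 100L,
                           frame_rate_hz = 7,
                           n_laps_familiar = 20L,
                           n_laps_novel = 15L,
                           field_width_cm = c(median = 50, sdlog = 0.25),
                           field_amplitude = c(infield = 2, outfield = 0.1),
                           reliability = 0.8,
                           drift_cm_per_lap = 0,
                           remap_overlap = NULL,
                           speed_profile = c(mean_cm_s = 12, stop_prob = 0.1),
                           lick_precision_target = 0.55,
                           reward_bins = list(fam = c(25L, 75L), nov = c(40L, 90L)),
                           noise_sd = 0.1,
                           seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), frac_tuned = frac_tuned,
    track_length_cm = track_length_cm, n_bins = as.integer(n_bins),
    frame_rate_hz = frame_rate_hz,
    n_laps_familiar = as.integer(n_laps_familiar),
    n_laps_novel = as.integer(n_laps_novel),
    field_width_cm = field_width_cm, field_amplitude = field_amplitude,
    reliability = reliability, drift_cm_per_lap = drift_cm_per_lap,
    remap_overlap = remap_overlap %||% frac_tuned^2,
    speed_profile = speed_profile,
    lick_precision_target = lick_precision_target,
    reward_bins = reward_bins, noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid `%s`: %s", field, why), call. = FALSE)
  }
  if (is.na(cfg$n_cells) || cfg$n_cells < 0L) bad("n_cells", "must be >= 0")
  if (cfg$track_length_cm <= 0) bad("track_length_cm", "must be > 0")
  if (cfg$n_bins < 10L) bad("n_bins", "must be >= 10")
  if (cfg$frame_rate_hz <= 0) bad("frame_rate_hz", "must be > 0")
  for (f in c("frac_tuned", "reliability", "lick_precision_target")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) bad(f, "must be in [0, 1]")
  }
  if (cfg$remap_overlap < 0 || cfg$remap_overlap > 1) {
    bad("remap_overlap", "must be in [0, 1]")
  }
  if (cfg$remap_overlap > cfg$frac_tuned + 1e-12) {
    bad("remap_overlap", "cannot exceed frac_tuned")
  }
  if (2 * cfg$frac_tuned - cfg$remap_overlap > 1 + 1e-12) {
    bad("remap_overlap", "implies a negative untuned fraction")
  }
  if (cfg$n_laps_familiar + cfg$n_laps_novel < 1L) {
    bad("n_laps_familiar", "session must have at least one lap")
  }
  if (!all(c("median", "sdlog") %in% names(cfg$field_width_cm)) ||
      cfg$field_width_cm[["median"]] <= 0 || cfg$field_width_cm[["sdlog"]] < 0) {
    bad("field_width_cm", "needs positive `median` and non-negative `sdlog`")
  }
  if (!all(c("infield", "outfield") %in% names(cfg$field_amplitude)) ||
      any(cfg$field_amplitude < 0) ||
      cfg$field_amplitude[["infield"]] < cfg$field_amplitude[["outfield"]]) {
    bad("field_amplitude", "needs `infield` >= `outfield` >= 0")
  }
  if (!all(c("mean_cm_s", "stop_prob") %in% names(cfg$speed_profile)) ||
      cfg$speed_profile[["mean_cm_s"]] <= 1 ||
      cfg$speed_profile[["stop_prob"]] < 0 || cfg$speed_profile[["stop_prob"]] > 1) {
    bad("speed_profile", "needs `mean_cm_s` > 1 and `stop_prob` in [0, 1]")
  }
  if (!is.list(cfg$reward_bins) || !all(c("fam", "nov") %in% names(cfg$reward_bins)) ||
      any(vapply(cfg$reward_bins, length, 1L) != 2L) ||
      any(unlist(cfg$reward_bins) < 1L) || any(unlist(cfg$reward_bins) > cfg$n_bins)) {
    bad("reward_bins", "needs `fam` and `nov`, two bin indices each, within 1..n_bins")
  }
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  invisible(cfg)
}

# largest-remainder apportionment of n cells into category counts with the
# given target probabilities (stratified allocation: realized fractions match
# the configured targets up to integer rounding)
apportion_counts <- function(n, probs) {
  raw <- n * probs
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    take <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[take] <- cnt[take] + 1L
  }
  as.integer(cnt)
}

#' Generate a synthetic VR session with ground truth
#'
#' Simulates behavior (position, speed with occasional sub-threshold pauses,
#' licks, rewards) on a circular track and per-cell calcium activity: tuned
#' cells emit Poisson deconvolved events at a rate given by a wrapped-Gaussian
#' tuning curve (expressed on a random subset of laps controlled by
#' `reliability`, optionally drifting lap by lap), events are convolved with a
#' single-exponential calcium kernel (1.5 s decay, GCaMP6s-like) to produce
#' dF/F, and raw soma/neuropil fluorescence channels share a common low-pass
#' contaminant so that neuropil correction is exercised downstream.
#'
#' Cells are allocated to the familiar-only / novel-only / both / untuned
#' categories by stratified (exact-count) assignment so realized tuned
#' fractions match `frac_tuned` and `remap_overlap` up to rounding.
#'
#' @param config a [session_config()].
#' @return A list with elements `session` (class `vr_session`) and
#'   `ground_truth` (class `vr_ground_truth`).
#' @examples
#' out <- generate_session(session_config(n_cells = 5, n_laps_familiar = 12,
#'                                        n_laps_novel = 0, seed = 3))
#' nrow(out$ground_truth$cells)
#' @export
generate_session <- function(config) {
  validate_session_config(config)
  set.seed(config$seed)
  L <- config$track_length_cm
  fr <- config$frame_rate_hz
  dt <- 1 / fr
  n_bins <- config$n_bins
  bin_size <- L / n_bins
  n_fam <- config$n_laps_familiar
  n_nov <- config$n_laps_novel
  n_laps <- n_fam + n_nov
  lap_env <- c(rep("fam", n_fam), rep("nov", n_nov))

  ## ---- behavior: per-frame speed, position, lap ----
  v_mean <- config$speed_profile[["mean_cm_s"]]
  stop_prob <- config$speed_profile[["stop_prob"]]
  speed <- unlist(lapply(seq_len(n_laps), function(l) {
    v <- max(2, stats::rnorm(1, v_mean, 0.1 * v_mean))
    n_run <- max(2L, ceiling(L / (v * dt)))
    s <- rep(v, n_run)
    if (stats::runif(1) < stop_prob) {
      n_stop <- max(1L, round(stats::rexp(1, 1 / 2) * fr))
      at <- sample.int(n_run, 1L)
      s <- append(s, rep(0.5, n_stop), after = at)
    }
    s
  }), use.names = FALSE)
  dist <- cumsum(speed * dt)
  keep <- dist < n_laps * L
  speed <- speed[keep]
  dist <- dist[keep]
  n_frames <- length(dist)
  lap <- pmin(floor(dist / L) + 1L, n_laps)
  position <- dist %% L
  time <- (seq_len(n_frames) - 1L) * dt
  bin <- pmin(floor(position / bin_size) + 1L, n_bins)
  env <- lap_env[lap]

  ## ---- rewards: first frame entering each reward bin on each lap ----
  reward <- integer(n_frames)
  for (l in seq_len(n_laps)) {
    rb <- config$reward_bins[[lap_env[l]]]
    in_lap <- which(lap == l)
    for (r in rb) {
      hit <- in_lap[bin[in_lap] == r]
      if (length(hit)) reward[hit[1L]] <- r
    }
  }
  reward_times <- time[reward > 0L]

  ## ---- licks: Bernoulli per (lap, bin), elevated in anticipatory zones ----
  q <- config$lick_precision_target
  zone <- 10L
  p_out <- 0.08
  n_zone <- 2L * zone
  n_out <- n_bins - n_zone
  p_ant <- if (q >= 1) 0.95 else min(0.95, p_out * (n_out / n_zone) * q / (1 - q))
  if (q <= 0) p_ant <- 0
  lick <- logical(n_frames)
  for (l in seq_len(n_laps)) {
    rb <- config$reward_bins[[lap_env[l]]]
    ant <- unique(unlist(lapply(rb, function(r) wrap_bin(r - seq_len(zone), n_bins))))
    p_bin <- rep(p_out, n_bins)
    p_bin[ant] <- p_ant
    licked <- which(stats::runif(n_bins) < p_bin)
    in_lap <- which(lap == l)
    for (b in licked) {
      cand <- in_lap[bin[in_lap] == b]
      if (length(cand)) lick[cand[sample.int(length(cand), 1L)]] <- TRUE
    }
  }

  frames <- data.frame(
    time = time, position = position, speed = speed,
    lap = lap, env = env, lick = lick, reward = reward
  )

  ## ---- ground truth: stratified category allocation ----
  n_cells <- config$n_cells
  f <- config$frac_tuned
  q_both <- config$remap_overlap
  probs <- c(both = q_both, fam_only = f - q_both, nov_only = f - q_both,
             none = 1 - 2 * f + q_both)
  counts <- apportion_counts(n_cells, probs)
  category <- rep(names(probs), counts)
  if (n_cells > 0L) category <- sample(category)
  tuned_fam <- category %in% c("both", "fam_only")
  tuned_nov <- category %in% c("both", "nov_only")
  wmed <- config$field_width_cm[["median"]]
  wsd <- config$field_width_cm[["sdlog"]]
  draw_width <- function(k) pmin(200, pmax(10, stats::rlnorm(k, log(wmed), wsd)))
  gt <- data.frame(
    cell = seq_len(n_cells),
    category = category,
    tuned_fam = tuned_fam, tuned_nov = tuned_nov,
    center_fam_cm = ifelse(tuned_fam, stats::runif(n_cells, 0, L), NA_real_),
    width_fam_cm = ifelse(tuned_fam, draw_width(n_cells), NA_real_),
    center_nov_cm = ifelse(tuned_nov, stats::runif(n_cells, 0, L), NA_real_),
    width_nov_cm = ifelse(tuned_nov, draw_width(n_cells), NA_real_),
    amplitude_infield = rep(config$field_amplitude[["infield"]], n_cells),
    amplitude_outfield = rep(config$field_amplitude[["outfield"]], n_cells),
    reliability = rep(config$reliability, n_cells),
    drift_cm_per_lap = rep(config$drift_cm_per_lap, n_cells),
    stringsAsFactors = FALSE
  )

  ## ---- per-cell events and fluorescence ----
  decay <- exp(-dt / 1.5)
  common <- stats::filter(stats::rnorm(n_frames), rep(1 / 25, 25), sides = 1)
  common <- as.numeric(common)
  common[is.na(common)] <- 0
  common <- 2 * common
  amp_out <- config$field_amplitude[["outfield"]]
  cells <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    rate <- rep(amp_out, n_frames)
    for (e in c("fam", "nov")) {
      tuned <- if (e == "fam") gt$tuned_fam[ci] else gt$tuned_nov[ci]
      if (!tuned) next
      centre <- if (e == "fam") gt$center_fam_cm[ci] else gt$center_nov_cm[ci]
      width <- if (e == "fam") gt$width_fam_cm[ci] else gt$width_nov_cm[ci]
      sigma <- width / 4
      env_laps <- which(lap_env == e)
      expressed <- stats::runif(length(env_laps)) < gt$reliability[ci]
      for (k in seq_along(env_laps)) {
        if (!expressed[k]) next
        l <- env_laps[k]
        idx <- which(lap == l)
        c_l <- (centre + gt$drift_cm_per_lap[ci] * (k - 1)) %% L
        d <- circ_dist_cm(position[idx], c_l, L)
        rate[idx] <- amp_out +
          (gt$amplitude_infield[ci] - amp_out) * exp(-d^2 / (2 * sigma^2))
      }
    }
    n_ev <- stats::rpois(n_frames, rate * dt)
    ev_frames <- which(n_ev > 0L)
    amp <- vapply(ev_frames, function(i) {
      sum(stats::rlnorm(n_ev[i], 0, 0.5))
    }, numeric(1))
    events <- data.frame(frame = ev_frames, amplitude = amp)
    spikes <- numeric(n_frames)
    spikes[ev_frames] <- amp
    dff_clean <- as.numeric(stats::filter(0.3 * spikes, decay, method = "recursive"))
    soma <- 100 * (1 + dff_clean + stats::rnorm(n_frames, 0, config$noise_sd)) +
      0.7 * common
    neuropil <- 70 + common
    cells[[ci]] <- list(soma = soma, neuropil = neuropil, events = events)
  }

  session <- structure(list(
    frames = frames, cells = cells, config = config,
    track_length_cm = L, n_bins = n_bins, bin_size_cm = bin_size,
    frame_rate_hz = fr, reward_bins = config$reward_bins,
    n_laps = c(fam = n_fam, nov = n_nov), lap_env = lap_env,
    reward_times = reward_times
  ), class = "vr_session")
  ground_truth <- structure(list(cells = gt, config = config),
                            class = "vr_ground_truth")
  list(session = session, ground_truth = ground_truth)
}

#' Generate a cohort of independent synthetic sessions
#'
#' Seeds are offset deterministically from each configuration's own seed, so a
#' cohort is reproducible as a whole while its sessions are independent.
#'
#' @param configs list of [session_config()] objects.
#' @return list of `list(session, ground_truth)` pairs, one per config.
#' @export
generate_cohort <- function(configs) {
  if (!length(configs)) stop("need at least one config")
  lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    validate_session_config(cfg)
    cfg$seed <- as.integer((cfg$seed + 10007 * (i - 1)) %% .Machine$integer.max)
    generate_session(cfg)
  })
}

#' @export
print.vr_session <- function(x, ...) {
  cat(sprintf(
    "<vr_session> %d cells, %d frames @ %.3g Hz, %d+%d laps (fam+nov), track %.0f cm / %d bins\n",
    length(x$cells), nrow(x$frames), x$frame_rate_hz,
    x$n_laps[["fam"]], x$n_laps[["nov"]], x$track_length_cm, x$n_bins
  ))
  invisible(x)
}

#' @export
print.vr_ground_truth <- function(x, ...) {
  cat(sprintf("<vr_ground_truth> %d cells: %s\n", nrow(x$cells),
              paste(names(table(x$cells$category)),
                    table(x$cells$category), sep = "=", collapse = ", ")))
  invisible(x)
}
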