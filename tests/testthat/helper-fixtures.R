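# Shared fixture builders. Sessions are generated in code (no stored data);
# small cached fixtures avoid regenerating the same session across tests in a
# file.

`%||%` <- function(a, b) if (is.null(a)) b else a
wrap_bin <- function(b, n_bins) ((b - 1L) %% n_bins) + 1L

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small default-style session: 40 cells, 12 + 10 laps
small_session <- function() {
  fixture("small_session", function() {
    generate_session(session_config(n_cells = 40, n_laps_familiar = 12,
                                    n_laps_novel = 10, seed = 101))
  })
}

# behavior-only session (no cells), familiar laps only
behavior_session <- function() {
  fixture("behavior_session", function() {
    generate_session(session_config(n_cells = 0, n_laps_familiar = 12,
                                    n_laps_novel = 8, seed = 202))$session
  })
}

# hand-build a binned_activity from a rate matrix (uniform occupancy)
make_binned <- function(rate, counts = NULL, bin_size_cm = 4,
                        lap_env = rep("fam", nrow(rate)), occupancy = NULL) {
  structure(list(
    rate = rate,
    occupancy = occupancy %||% matrix(0.3, nrow(rate), ncol(rate)),
    counts = counts,
    lap_env = lap_env, bin_size_cm = bin_size_cm,
    track_length_cm = bin_size_cm * ncol(rate)
  ), class = "binned_activity")
}

# one-row place_field_table-like field descriptor
make_field <- function(peak_bin, bins, onset_lap = 1L, baseline = 0) {
  fld <- data.frame(peak_bin = peak_bin, onset_lap = onset_lap,
                    baseline = baseline)
  fld$bins <- list(bins)
  fld
}

# noiseless Gaussian lap x bin activity bump (circular), identical every lap;
# tails below 1% of the amplitude are truncated to the exact background level
# (as in event-rate maps, where far-from-field bins are exactly zero)
gaussian_bump_matrix <- function(n_laps = 20, n_bins = 100, centre = 50,
                                 sigma_bins = 5, amp = 1, background = 0.01) {
  d <- pmin(abs(seq_len(n_bins) - centre), n_bins - abs(seq_len(n_bins) - centre))
  g <- amp * exp(-d^2 / (2 * sigma_bins^2))
  g[g < 0.01 * amp] <- 0
  matrix(rep(background + g, each = n_laps), nrow = n_laps)
}

# one-hot population session for decoder tests: cell b fires amplitude `amp`
# on every frame spent in bin b
one_hot_session <- function(n_laps = 10, amp = 10, seed = 2) {
  fixture(sprintf("one_hot_%d_%d_%d", n_laps, amp, seed), function() {
    cfg <- session_config(n_cells = 0, n_laps_familiar = n_laps,
                          n_laps_novel = 0, seed = seed,
                          speed_profile = c(mean_cm_s = 12, stop_prob = 0))
    s <- generate_session(cfg)$session
    bin <- pmin(floor(s$frames$position / s$bin_size_cm) + 1L, s$n_bins)
    events <- lapply(seq_len(s$n_bins), function(b) {
      data.frame(frame = which(bin == b), amplitude = amp)
    })
    s$cells <- lapply(events, function(e) {
      list(soma = numeric(nrow(s$frames)), neuropil = numeric(nrow(s$frames)),
           events = e)
    })
    list(session = s, events = events)
  })
}
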