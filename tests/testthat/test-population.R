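# Population analyses: sequence ordering, PV correlations, remapping
# statistics and the Bayesian decoder.

test_that("peak ordering sorts one-hot cells by field position", {
  rate_list <- lapply(seq(5, 95, by = 10), function(b) {
    m <- matrix(0, 15, 100)
    m[, b] <- 1
    make_binned(m)
  })
  so <- sort_by_peak(rate_list, seed = 1)
  expect_equal(so$order, 1:10)
  expect_equal(so$peak_bin, seq(5, 95, by = 10))
  # reproducible under a fixed seed
  so2 <- sort_by_peak(rate_list, seed = 1)
  expect_identical(so, so2)
})

test_that("display matrix of stably tuned cells shows a monotone ridge", {
  set.seed(2)
  centres <- sort(sample(1:100, 60, replace = TRUE))
  rate_list <- lapply(centres, function(b) {
    m <- gaussian_bump_matrix(20, centre = b, sigma_bins = 3, background = 0)
    make_binned(m + matrix(rnorm(2000, 0, 0.05), 20, 100))
  })
  so <- sort_by_peak(rate_list, seed = 3)
  ridge <- apply(so$display, 1, which.max)
  expect_gt(cor(seq_along(ridge), ridge, method = "spearman"), 0.9)
})

test_that("PV correlation of an interval with itself has unit diagonal", {
  set.seed(4)
  rate_list <- lapply(1:30, function(i) make_binned(matrix(rexp(600), 6, 100)))
  pv <- pv_correlate(rate_list, 1:3, 1:3)
  expect_equal(unname(diag(pv$matrix)), rep(1, 100), tolerance = 1e-9)
  expect_equal(pv$matrix, t(pv$matrix), tolerance = 1e-9)
  expect_true(all(pv$matrix[is.finite(pv$matrix)] >= -1 - 1e-12 &
                    pv$matrix[is.finite(pv$matrix)] <= 1 + 1e-12))
})

test_that("independent populations decorrelate along the diagonal", {
  set.seed(5)
  rate_list <- lapply(1:500, function(i) make_binned(matrix(rexp(600), 6, 100)))
  pv <- pv_correlate(rate_list, 1:3, 4:6)
  expect_lt(abs(pv$diag_mean), 0.05)
})

test_that("lap-interval series behaves in reference and lagged modes", {
  set.seed(6)
  rate_list <- lapply(1:40, function(i) {
    make_binned(gaussian_bump_matrix(15, centre = sample(100, 1), sigma_bins = 4,
                                     background = 0) +
                  matrix(rnorm(1500, 0, 0.05), 15, 100))
  })
  ref <- 13:15
  ser <- lap_interval_series(rate_list, reference = ref)
  expect_equal(ser$diag_mean[ser$start_lap == 13], 1, tolerance = 1e-9)
  # stationary representation: regression slope CI contains 0
  fit <- linear_trend(ser$start_lap[1:4], ser$diag_mean[1:4])
  expect_gt(fit$p_slope, 0.05)
  lag7 <- lap_interval_series(rate_list, mode = "lagged", lag = 7)
  expect_equal(nrow(lag7), 15 - 3 + 1 - 7)
})

test_that("field-location correlation and end-bin exclusion work", {
  tbl <- function(cells, peaks) {
    data.frame(cell = cells, peak_bin = peaks)
  }
  # identical maps: r = 1
  fam <- tbl(1:30, seq(2, 60, by = 2))
  out <- field_location_correlation(fam, fam)
  expect_equal(out$all$r, 1, tolerance = 1e-12)
  # independent uniform positions: |r| small
  set.seed(7)
  fam2 <- tbl(1:500, sample(100, 500, replace = TRUE))
  nov2 <- tbl(1:500, sample(100, 500, replace = TRUE))
  out2 <- field_location_correlation(fam2, nov2)
  expect_lt(abs(out2$all$r), 0.1)
  # a shared landmark cluster at the track ends drives r; exclusion reduces it
  n_land <- 150
  ends <- sample(c(1:5, 96:100), n_land, replace = TRUE)
  fam3 <- tbl(1:500, c(ends, sample(6:95, 500 - n_land, replace = TRUE)))
  nov3 <- tbl(1:500, c(ends, sample(6:95, 500 - n_land, replace = TRUE)))
  out3 <- field_location_correlation(fam3, nov3)
  expect_gt(out3$all$r, out3$interior$r)
  # cells with two fields are excluded from the analysis
  dup <- rbind(fam, tbl(1, 80))
  expect_equal(field_location_correlation(dup, fam)$all$n, 29)
})

test_that("overlap bookkeeping matches expectation under independence", {
  set.seed(8)
  f <- runif(10000) < 0.3
  g <- runif(10000) < 0.3
  ov <- overlap_expected_vs_actual(f, g)
  expect_equal(ov$expected, mean(f) * mean(g))
  expect_lt(abs(ov$actual - 0.09), 3 * sqrt(0.09 * 0.91 / 10000) + 0.005)
  # identical flags: actual q, expected q^2
  ov2 <- overlap_expected_vs_actual(f, f)
  expect_equal(ov2$actual, mean(f))
  expect_equal(ov2$expected, mean(f)^2)
  # disjoint flags
  ov3 <- overlap_expected_vs_actual(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(ov3$actual, 0)
  expect_error(overlap_expected_vs_actual(logical(0), logical(0)), "empty")
})

test_that("one-hot noiseless populations decode perfectly", {
  oh <- one_hot_session()
  prep <- prep_decoder(oh$session, oh$events, "fam")
  r <- bayes_decode(oh$session, oh$events, train_laps = 2:10, test_lap = 1,
                    env = "fam", window_s = 1 / oh$session$frame_rate_hz,
                    prep = prep)
  expect_equal(r$mean_error_cm, 0)
  expect_equal(r$frames$decoded_bin, r$frames$true_bin)
  # posterior rows normalize to 1
  expect_equal(rowSums(r$posterior), rep(1, nrow(r$frames)), tolerance = 1e-9)
  expect_error(bayes_decode(oh$session, oh$events, 1:10, 1, "fam", prep = prep),
               "train")
})

test_that("decoding is invariant to cell relabeling and rotates with the track", {
  oh <- one_hot_session()
  s <- oh$session
  prep <- prep_decoder(s, oh$events, "fam")
  r0 <- bayes_decode(s, oh$events, 2:10, 1, "fam", prep = prep)
  # relabeling cells leaves errors unchanged
  perm <- sample(seq_along(oh$events))
  prep_p <- prep_decoder(s, oh$events[perm], "fam")
  r1 <- bayes_decode(s, oh$events[perm], 2:10, 1, "fam", prep = prep_p)
  expect_equal(r1$frames$error_cm, r0$frames$error_cm)
  # rotating the track origin rotates decoded bins, errors unchanged
  shift <- 27
  s_rot <- s
  s_rot$frames$position <- (s$frames$position + shift * s$bin_size_cm) %%
    s$track_length_cm
  ev_rot <- oh$events[wrap_bin(seq_len(100) - shift, 100)]
  prep_r <- prep_decoder(s_rot, ev_rot, "fam")
  r2 <- bayes_decode(s_rot, ev_rot, 2:10, 1, "fam", prep = prep_r)
  expect_equal(r2$frames$error_cm, r0$frames$error_cm)
  expect_equal(r2$frames$decoded_bin,
               wrap_bin(r0$frames$decoded_bin + shift, 100))
})

test_that("decoder error grows to chance for spatially random activity", {
  cfg <- session_config(n_cells = 80, n_laps_familiar = 8, n_laps_novel = 0,
                        seed = 91)
  s <- generate_session(cfg)$session
  set.seed(92)
  nfr <- nrow(s$frames)
  ev <- lapply(s$cells, function(cl) {
    e <- cl$events
    e$frame <- sort(sample.int(nfr, nrow(e), replace = TRUE))
    e
  })
  prep <- prep_decoder(s, ev, "fam")
  errs <- vapply(1:8, function(l) {
    bayes_decode(s, ev, setdiff(1:8, l), l, "fam", prep = prep)$mean_error_cm
  }, numeric(1))
  expect_lt(abs(mean(errs) - s$track_length_cm / 4), 0.1 * s$track_length_cm / 4)
})

test_that("session-level decoding with subsampling is reproducible", {
  oh <- one_hot_session()
  prep <- prep_decoder(oh$session, oh$events, "fam")
  d1 <- decoder_error_session(oh$session, oh$events, "fam", n_neurons = 100,
                              n_repeats = 1, seed = 5, prep = prep)
  # full population, one repeat: equals the per-lap bayes_decode aggregate
  l3 <- bayes_decode(oh$session, oh$events, setdiff(1:10, 3), 3, "fam",
                     prep = prep)
  expect_equal(d1$per_lap$mean_error_cm[3], l3$mean_error_cm)
  d2 <- decoder_error_session(oh$session, oh$events, "fam", n_neurons = 100,
                              n_repeats = 1, seed = 5, prep = prep)
  expect_identical(d1, d2)
  expect_false(d1$exclude)
  # requesting more neurons than cells warns and reduces
  expect_warning(
    decoder_error_session(oh$session, oh$events, "fam", n_neurons = 146,
                          n_repeats = 1, seed = 5, prep = prep),
    "reduced"
  )
})
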