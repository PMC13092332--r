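# Population-level analyses: sequence ordering, PV correlations, remapping.

# cells x bins matrix of per-cell mean rate over a lap interval
population_matrix <- function(binned_list, laps) {
  t(vapply(binned_list, function(b) {
    m <- colMeans(b$rate[laps, , drop = FALSE], na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_
    m
  }, numeric(ncol(binned_list[[1L]]$rate))))
}

#' Order cells by the position of peak activity
#'
#' A random half of the final `final_laps` laps determines each cell's peak
#' bin (so sequence plots are cross-validated); the complementary laps are
#' averaged, z-scored per cell, and returned as a display matrix with rows in
#' peak order.
#'
#' @param binned_list list of `binned_activity`, one per cell, same laps.
#' @param final_laps number of final laps to split (default 10).
#' @param half laps drawn for the sort (default 5).
#' @param seed optional RNG seed for the lap draw.
#' @return list of class `peak_ordering`: `order` (cell indices), `peak_bin`
#'   per cell, `sort_laps`, `display` (cells x bins, rows in `order`).
#' @export
sort_by_peak <- function(binned_list, final_laps = 10, half = 5, seed = NULL) {
  n_laps <- nrow(binned_list[[1L]]$rate)
  if (n_laps < final_laps) stop("need at least `final_laps` laps")
  if (!is.null(seed)) set.seed(seed)
  pool <- (n_laps - final_laps + 1L):n_laps
  sort_laps <- sort(sample(pool, half))
  disp_laps <- setdiff(seq_len(n_laps), sort_laps)
  P_sort <- population_matrix(binned_list, sort_laps)
  peak_bin <- apply(P_sort, 1L, function(z) {
    if (all(is.na(z))) NA_integer_ else which.max(z)
  })
  ord <- order(peak_bin)
  P_disp <- population_matrix(binned_list, disp_laps)
  z <- t(apply(P_disp, 1L, function(r) {
    s <- stats::sd(r, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(r)))
    (r - mean(r, na.rm = TRUE)) / s
  }))
  structure(list(order = ord, peak_bin = peak_bin, sort_laps = sort_laps,
                 display = z[ord, , drop = FALSE]),
            class = "peak_ordering")
}

#' Population-vector correlation matrix between two lap intervals
#'
#' The population vector at a bin is every cell's mean activity over the
#' interval; entry (i, j) is the Pearson correlation of the PV at bin i in
#' interval A with the PV at bin j in interval B. The diagonal mean summarizes
#' how similar the representation of the *same* positions is across the two
#' intervals.
#'
#' @param binned_list list of `binned_activity`, one per cell (same cell set
#'   and lap frame for both intervals).
#' @param lapsA,lapsB lap index vectors for the two intervals.
#' @return object of class `pv_corr`: `matrix` (bins x bins), `diag_mean`,
#'   `lapsA`, `lapsB`, `n_na` (zero-variance entries).
#' @export
pv_correlate <- function(binned_list, lapsA, lapsB) {
  if (!length(lapsA) || !length(lapsB)) stop("lap intervals must be non-empty")
  PA <- population_matrix(binned_list, lapsA)
  PB <- population_matrix(binned_list, lapsB)
  suppressWarnings(C <- stats::cor(PA, PB, use = "pairwise.complete.obs"))
  n_na <- sum(is.na(C))
  structure(list(matrix = C, diag_mean = mean(diag(C), na.rm = TRUE),
                 lapsA = lapsA, lapsB = lapsB, n_na = n_na),
            class = "pv_corr")
}

#' @export
print.pv_corr <- function(x, ...) {
  cat(sprintf("<pv_corr> %dx%d, diagonal mean %.3f (%d NA entries)\n",
              nrow(x$matrix), ncol(x$matrix), x$diag_mean, x$n_na))
  invisible(x)
}

#' Series of PV diagonal means across lap intervals
#'
#' In `"reference"` mode every non-overlapping `step`-lap interval is
#' correlated against a fixed reference interval; in `"lagged"` mode each
#' interval is correlated against the interval starting `lag` laps later
#' (a drift-versus-stabilization control).
#'
#' @param binned_list list of per-cell `binned_activity`.
#' @param reference lap indices of the reference interval (reference mode).
#' @param step interval width in laps (default 3).
#' @param mode `"reference"` or `"lagged"`.
#' @param lag lap offset for lagged mode (default 7).
#' @return data frame with `start_lap` and `diag_mean`.
#' @export
lap_interval_series <- function(binned_list, reference = NULL, step = 3,
                                mode = c("reference", "lagged"), lag = 7) {
  mode <- match.arg(mode)
  n_laps <- nrow(binned_list[[1L]]$rate)
  if (mode == "reference") {
    if (is.null(reference)) stop("`reference` laps required in reference mode")
    starts <- seq(1L, n_laps - step + 1L, by = step)
    vals <- vapply(starts, function(s) {
      pv_correlate(binned_list, s:(s + step - 1L), reference)$diag_mean
    }, numeric(1))
  } else {
    starts <- seq_len(max(0L, n_laps - step + 1L - lag))
    if (!length(starts)) stop("not enough laps for the lagged comparison")
    vals <- vapply(starts, function(s) {
      pv_correlate(binned_list, s:(s + step - 1L),
                   (s + lag):(s + lag + step - 1L))$diag_mean
    }, numeric(1))
  }
  data.frame(start_lap = starts, diag_mean = vals)
}

#' Correlation of field locations across environments
#'
#' For cells with exactly one field in each environment, the Pearson
#' correlation between familiar and novel peak bins, reported both for all
#' such cells and after excluding fields peaking within `exclude_end_bins`
#' bins of either track end (the landmark-control analysis).
#'
#' @param fields_fam,fields_nov `place_field_table`s with `cell` columns.
#' @param n_bins number of track bins (default 100).
#' @param exclude_end_bins end-exclusion width in bins (default 5).
#' @return list with elements `all` and `interior`, each `list(r, p, n)`
#'   (`NA` when fewer than 3 pairs).
#' @export
field_location_correlation <- function(fields_fam, fields_nov, n_bins = 100,
                                       exclude_end_bins = 5) {
  single <- function(tbl) {
    tb <- table(tbl$cell)
    cells <- as.integer(names(tb)[tb == 1L])
    tbl[tbl$cell %in% cells, c("cell", "peak_bin")]
  }
  a <- single(fields_fam)
  b <- single(fields_nov)
  m <- merge(a, b, by = "cell", suffixes = c("_fam", "_nov"))
  corr <- function(d) {
    if (nrow(d) < 3L) return(list(r = NA_real_, p = NA_real_, n = nrow(d)))
    ct <- stats::cor.test(d$peak_bin_fam, d$peak_bin_nov)
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
  }
  near_end <- function(b) b <= exclude_end_bins | b > n_bins - exclude_end_bins
  interior <- m[!near_end(m$peak_bin_fam) & !near_end(m$peak_bin_nov), ]
  list(all = corr(m), interior = corr(interior))
}

#' Actual versus expected overlap of position-correlated cells
#'
#' Under independent random allocation of fields, the expected fraction of
#' cells with fields in both environments is the product of the
#' per-environment fractions; the actual fraction measures departures from
#' chance-level overlap.
#'
#' @param pcc_flags_fam,pcc_flags_nov per-cell logicals over the same cell
#'   universe.
#' @return list with `actual`, `expected`, `ratio` and `n`.
#' @export
overlap_expected_vs_actual <- function(pcc_flags_fam, pcc_flags_nov) {
  if (length(pcc_flags_fam) != length(pcc_flags_nov)) {
    stop("flag vectors must cover the same cell universe")
  }
  n <- length(pcc_flags_fam)
  if (n == 0L) stop("empty cell universe")
  actual <- mean(pcc_flags_fam & pcc_flags_nov)
  expected <- mean(pcc_flags_fam) * mean(pcc_flags_nov)
  list(actual = actual, expected = expected,
       ratio = if (expected > 0) actual / expected else NA_real_, n = n)
}
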