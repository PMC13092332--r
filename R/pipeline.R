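# End-to-end orchestration of the analysis stages, with the standard
# inclusion gates applied up front.

#' Run the full analysis pipeline on a session
#'
#' Executes preprocessing, place-field detection, spatial information,
#' remapping statistics, Bayesian decoding, behavioral scoring and lap trends
#' in order, applying the inclusion gates first: at least 10 laps per visited
#' environment, at least 50 detected cells, and (flagged, not fatal) familiar
#' decoder error of at most 30 cm. Gate failures are reported as exclusions
#' with reasons, never as crashes.
#'
#' @param config a [session_config()]; a session is simulated from it when
#'   `session` is not supplied.
#' @param session optionally, an existing `vr_session` (takes precedence).
#' @param out_dir optional output directory for tidy CSV tables and a JSON
#'   summary.
#' @param seed seed for the pipeline's randomized steps (shuffles, decoder
#'   subsampling); defaults to the session's own seed.
#' @param decoder_repeats,decoder_neurons decoder subsampling settings
#'   (desk-scale defaults; the cross-dataset protocol uses 100 x 146).
#' @param si_shuffles circular-shift shuffles per cell for the SI null.
#' @return list of class `pfr_report`; when gates fail, `excluded = TRUE`
#'   with `reasons`.
#' @export
run_pipeline <- function(config = NULL, session = NULL, out_dir = NULL,
                         seed = NULL, decoder_repeats = 3,
                         decoder_neurons = 146, si_shuffles = 50) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }
  ground_truth <- NULL
  if (is.null(session)) {
    if (is.null(config)) stop("supply `config` or `session`")
    gen <- generate_session(config)
    session <- gen$session
    ground_truth <- gen$ground_truth
  }
  seed <- as.integer(seed %||% session$config$seed %||% 1L)
  set.seed(seed)
  tick("simulate")

  ## ---- inclusion gates ----
  reasons <- character(0)
  envs <- names(which(session$n_laps > 0L))
  for (e in envs) {
    if (session$n_laps[[e]] < 10L) {
      reasons <- c(reasons, sprintf("ran less than 10 laps in %s (%d)",
                                    e, session$n_laps[[e]]))
    }
  }
  if (length(session$cells) < 50L) {
    reasons <- c(reasons, sprintf("fewer than 50 cells detected (%d)",
                                  length(session$cells)))
  }
  if (length(reasons)) {
    report <- structure(list(excluded = TRUE, reasons = reasons,
                             seed = seed, timings = timings),
                        class = "pfr_report")
    if (!is.null(out_dir)) write_report(report, out_dir)
    return(report)
  }

  ## ---- preprocessing ----
  pre <- preprocess_session(session)
  n_cells <- length(session$cells)
  tick("preprocess")

  ## ---- per-environment maps, fields, SI ----
  fields <- list()
  si <- list()
  binned_dff_all <- lapply(seq_len(n_cells), function(ci) {
    bin_by_position(session, pre$dff[[ci]])
  })
  for (e in envs) {
    fields[[e]] <- detect_fields_session(session, pre$dff, env = e)
    si[[e]] <- vapply(seq_len(n_cells), function(ci) {
      be <- bin_events_by_position(session, session$cells[[ci]]$events, env = e)
      tryCatch(si_shuffle_null(be, n_shuffles = si_shuffles)$si,
               error = function(err) NA_real_)
    }, numeric(1))
  }
  tick("fields")

  ## ---- remapping statistics (both environments present) ----
  remap <- NULL
  categories <- NULL
  if (all(c("fam", "nov") %in% envs)) {
    categories <- categorize_cells(fields$fam, fields$nov, n_cells)
    flags_fam <- seq_len(n_cells) %in% fields$fam$cell
    flags_nov <- seq_len(n_cells) %in% fields$nov$cell
    binned_fam <- lapply(seq_len(n_cells), function(ci) {
      bin_by_position(session, pre$dff[[ci]], env = "fam")
    })
    binned_nov <- lapply(seq_len(n_cells), function(ci) {
      bin_by_position(session, pre$dff[[ci]], env = "nov")
    })
    late <- function(b) {
      n <- nrow(b[[1L]]$rate)
      (n - 2L):n
    }
    cross <- pv_cross_env(binned_fam, binned_nov, late(binned_fam), late(binned_nov))
    within_fam <- pv_correlate(binned_fam,
                               utils::head(seq_len(nrow(binned_fam[[1L]]$rate)), 3),
                               late(binned_fam))$diag_mean
    remap <- list(
      overlap = overlap_expected_vs_actual(flags_fam, flags_nov),
      pv_cross_env_diag = cross,
      pv_within_fam_diag = within_fam,
      field_location = field_location_correlation(fields$fam, fields$nov,
                                                  n_bins = session$n_bins)
    )
  }
  tick("remap")

  ## ---- decoding ----
  decode <- list()
  for (e in envs) {
    prep <- prep_decoder(session, lapply(session$cells, `[[`, "events"), e)
    decode[[e]] <- decoder_error_session(
      session, NULL, e, n_neurons = min(decoder_neurons, n_cells),
      n_repeats = decoder_repeats, seed = seed + 1L, prep = prep
    )
  }
  if (!is.null(decode$fam) && decode$fam$exclude) {
    reasons <- c(reasons, sprintf(
      "familiar decoder error greater than 30 cm (%.1f cm)",
      decode$fam$session_mean_cm))
  }
  tick("decode")

  ## ---- behavior ----
  licks <- lick_precision(session)
  speed <- lap_speed_profile(session)
  zact <- NULL
  contrast <- NULL
  if (!is.null(categories)) {
    zact <- zscore_lap_activity(binned_dff_all, categories)
    contrast <- tryCatch(transition_contrast(zact), error = function(e) NULL)
  }
  tick("behavior")

  ## ---- lap trends ----
  trends <- list()
  if (!is.null(decode$nov) && nrow(decode$nov$per_lap) >= 4L) {
    pl <- decode$nov$per_lap
    trends$decoder_error_novel <- list(
      linear = linear_trend(pl$lap, pl$mean_error_cm),
      exp = exp_decay_fit(pl$lap, pl$mean_error_cm)
    )
  }
  lp <- licks$per_lap[licks$per_lap$env == "nov", ]
  if (nrow(lp) >= 3L) {
    trends$lick_precision_novel <- linear_trend(lp$lap, lp$precision)
  }
  tick("trends")

  report <- structure(list(
    excluded = FALSE, reasons = reasons, seed = seed,
    n_cells = n_cells, n_laps = session$n_laps,
    fields = fields, si = si, categories = categories,
    remap = remap, decode = decode, licks = licks, speed = speed,
    transition = contrast, trends = trends,
    ground_truth = ground_truth, timings = timings
  ), class = "pfr_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# cross-environment PV diagonal: per-cell tuning averaged over late laps in
# each environment, correlated bin-by-bin
pv_cross_env <- function(binned_fam, binned_nov, lapsA, lapsB) {
  PA <- population_matrix(binned_fam, lapsA)
  PB <- population_matrix(binned_nov, lapsB)
  suppressWarnings(C <- stats::cor(PA, PB, use = "pairwise.complete.obs"))
  mean(diag(C), na.rm = TRUE)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    excluded = report$excluded, reasons = report$reasons, seed = report$seed,
    timings_s = as.list(report$timings)
  )
  if (!report$excluded) {
    summ <- c(summ, list(
      n_cells = report$n_cells,
      n_laps = as.list(report$n_laps),
      n_fields = lapply(report$fields, nrow),
      pcc_fraction = lapply(report$fields, function(f) {
        length(unique(f$cell)) / report$n_cells
      }),
      mean_si = lapply(report$si, function(s) mean(s, na.rm = TRUE)),
      decoder_error_cm = lapply(report$decode, `[[`, "session_mean_cm"),
      lick_precision = report$licks$session_precision
    ))
    if (!is.null(report$remap)) {
      summ$overlap <- report$remap$overlap
      summ$pv_cross_env_diag <- report$remap$pv_cross_env_diag
    }
    for (e in names(report$fields)) {
      f <- report$fields[[e]]
      if (nrow(f)) {
        utils::write.csv(f[, setdiff(names(f), "bins")],
                         file.path(out_dir, sprintf("fields_%s.csv", e)),
                         row.names = FALSE)
      }
    }
    utils::write.csv(report$licks$per_lap,
                     file.path(out_dir, "lick_precision_per_lap.csv"),
                     row.names = FALSE)
    utils::write.csv(report$speed, file.path(out_dir, "speed_per_lap.csv"),
                     row.names = FALSE)
    for (e in names(report$decode)) {
      utils::write.csv(report$decode[[e]]$per_lap,
                       file.path(out_dir, sprintf("decoder_error_%s.csv", e)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pfr_report <- function(x, ...) {
  if (x$excluded) {
    cat("<pfr_report> EXCLUDED:\n")
    for (r in x$reasons) cat("  - ", r, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<pfr_report> %d cells, laps fam=%d nov=%d (seed %d)\n",
              x$n_cells, x$n_laps[["fam"]], x$n_laps[["nov"]], x$seed))
  for (e in names(x$fields)) {
    cat(sprintf("  %s: %d fields in %d cells; mean SI %.2f bits/event; decoder %.1f cm\n",
                e, nrow(x$fields[[e]]), length(unique(x$fields[[e]]$cell)),
                mean(x$si[[e]], na.rm = TRUE),
                x$decode[[e]]$session_mean_cm))
  }
  cat(sprintf("  lick precision %.3f\n", x$licks$session_precision))
  if (!is.null(x$remap)) {
    cat(sprintf("  overlap actual/expected = %.3f/%.3f; cross-env PV diag %.3f\n",
                x$remap$overlap$actual, x$remap$overlap$expected,
                x$remap$pv_cross_env_diag))
  }
  if (length(x$reasons)) {
    for (r in x$reasons) cat("  flag: ", r, "\n", sep = "")
  }
  invisible(x)
}
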