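# Session container: one directory per session, plain-text tables plus a JSON
# manifest with checksums. A ground-truth JSON sidecar travels with synthetic
# sessions.

#' Write a session to a directory container
#'
#' Layout: `manifest.json` (configuration echo, geometry, seed, table
#' checksums), `frames.csv` (time, position, speed, lap, env, lick, reward),
#' `cells/cell_###_trace.csv` and `cells/cell_###_events.csv` per cell, and an
#' optional `ground_truth.json` sidecar.
#'
#' @param session a `vr_session`.
#' @param path directory to create/populate.
#' @param ground_truth optional `vr_ground_truth` to store alongside.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, ground_truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "cells"), showWarnings = FALSE)
  utils::write.csv(session$frames, file.path(path, "frames.csv"),
                   row.names = FALSE)
  files <- "frames.csv"
  for (ci in seq_along(session$cells)) {
    cell <- session$cells[[ci]]
    tf <- sprintf("cells/cell_%04d_trace.csv", ci)
    ef <- sprintf("cells/cell_%04d_events.csv", ci)
    utils::write.csv(data.frame(soma = cell$soma, neuropil = cell$neuropil),
                     file.path(path, tf), row.names = FALSE)
    utils::write.csv(cell$events[, c("frame", "amplitude")],
                     file.path(path, ef), row.names = FALSE)
    files <- c(files, tf, ef)
  }
  sums <- as.list(tools::md5sum(file.path(path, files)))
  names(sums) <- files
  manifest <- list(
    format = "placefieldr-session", version = 1L,
    n_frames = nrow(session$frames), n_cells = length(session$cells),
    n_laps = as.list(session$n_laps), lap_env = session$lap_env,
    frame_rate_hz = session$frame_rate_hz,
    track_length_cm = session$track_length_cm, n_bins = session$n_bins,
    reward_bins = session$reward_bins,
    seed = session$config$seed %||% NA,
    config = unclass(session$config),
    checksums = sums
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(ground_truth)) {
    gt_out <- list(cells = ground_truth$cells,
                   config = unclass(ground_truth$config))
    jsonlite::write_json(gt_out,
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Read a session container
#'
#' Validates the manifest, verifies table checksums and frame-clock
#' consistency across all streams before reconstructing the session.
#'
#' @param path session directory written by [write_session()].
#' @return a `vr_session`.
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("missing manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$format, "placefieldr-session")) {
    stop("not a session container: ", path)
  }
  for (f in names(mf$checksums)) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing stream: ", f)
    if (!identical(unname(tools::md5sum(fp)), mf$checksums[[f]])) {
      stop("checksum failure for ", f)
    }
  }
  frames <- utils::read.csv(file.path(path, "frames.csv"),
                            stringsAsFactors = FALSE)
  if (nrow(frames) != mf$n_frames) {
    stop("clock mismatch: frames table has ", nrow(frames),
         " rows, manifest says ", mf$n_frames)
  }
  cells <- vector("list", mf$n_cells)
  for (ci in seq_len(mf$n_cells)) {
    tr <- utils::read.csv(file.path(path, sprintf("cells/cell_%04d_trace.csv", ci)))
    ev <- utils::read.csv(file.path(path, sprintf("cells/cell_%04d_events.csv", ci)))
    if (nrow(tr) != mf$n_frames) {
      stop("clock mismatch: cell ", ci, " trace has ", nrow(tr), " frames")
    }
    if (nrow(ev) && (any(ev$frame < 1L) || any(ev$frame > mf$n_frames))) {
      stop("clock mismatch: cell ", ci, " events outside the frame clock")
    }
    cells[[ci]] <- list(soma = tr$soma, neuropil = tr$neuropil, events = ev)
  }
  cfg <- mf$config
  reward_bins <- lapply(mf$reward_bins, as.integer)
  structure(list(
    frames = frames, cells = cells, config = cfg,
    track_length_cm = mf$track_length_cm, n_bins = as.integer(mf$n_bins),
    bin_size_cm = mf$track_length_cm / mf$n_bins,
    frame_rate_hz = mf$frame_rate_hz, reward_bins = reward_bins,
    n_laps = c(fam = as.integer(mf$n_laps$fam), nov = as.integer(mf$n_laps$nov)),
    lap_env = mf$lap_env,
    reward_times = frames$time[frames$reward > 0L]
  ), class = "vr_session")
}
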