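#' Read / write BIDS-style event tables
#'
#' Events are TSV with columns `onset`, `duration`, `trial_type`.
#'
#' @param path file path
#' @return for the reader, a data frame
#' @export
read_events <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_events
#' @param events data frame with `onset`, `duration` and a label column
#'   (`trial_type` or `label`)
#' @export
write_events <- function(events, path) {
  if (is.null(events$trial_type) && !is.null(events$label))
    events$trial_type <- as.character(events$label)
  write.table(events[, c("onset", "duration", "trial_type")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write seizure interval tables (TSV: start, end)
#'
#' @param path file path
#' @return for the reader, a data frame with `start`, `end`
#' @export
read_intervals <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' @rdname read_intervals
#' @param intervals data frame with `start`, `end`
#' @export
write_intervals <- function(intervals, path) {
  write.table(intervals[, c("start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-region statistics as TSV
#'
#' @param stats a `region_stats` data frame
#' @param path file path
#' @export
write_region_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 4D volumes as NIfTI-1
#'
#' @param path file path (.nii or .nii.gz)
#' @return for the reader, a 4D array
#' @export
read_volumes <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' @rdname read_volumes
#' @param vol4d 4D array
#' @param TR volume time (s), stored in the header
#' @export
write_volumes <- function(vol4d, path, TR = 2) {
  img <- RNifti::asNifti(vol4d, pixdim = c(1, 1, 1, TR))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write motion parameter tables (TSV, 6 columns)
#'
#' @param path file path
#' @return for the reader, a data frame of 3 translations (mm) and 3
#'   rotations (deg)
#' @export
read_motion <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' @rdname read_motion
#' @param motion 6-column data frame
#' @export
write_motion <- function(motion, path) {
  write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a long-format simulation time-series table
#'
#' TSV columns: `time`, `region`, `variable`, `value`.
#'
#' @param sim a `simulation_result` from [simulate_network()]
#' @param path file path
#' @param variables which state variables to include
#' @param regions optional subset of region labels
#' @export
write_simulation_tsv <- function(sim, path,
                                 variables = c("nu_e", "nu_i", "W", "mu_V"),
                                 regions = NULL) {
  if (is.null(regions)) regions <- sim$labels
  ridx <- match(regions, sim$labels)
  rows <- list()
  for (v in variables) {
    m <- sim[[v]][ridx, , drop = FALSE]
    rows[[v]] <- data.frame(
      time = rep(sim$time, each = length(ridx)),
      region = rep(regions, times = length(sim$time)),
      variable = v, value = as.vector(m))
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
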