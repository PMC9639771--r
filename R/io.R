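#' Export spike trains as CSV
#'
#' Plain-text persistence: columns \code{unit_id}, \code{sample_index},
#' with the sampling rate in a JSON sidecar (\code{<file>.json}) when
#' jsonlite is available.
#'
#' @param spikes a \linkS4class{SpikeTrainSet}.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
exportSpikesCsv <- function(spikes, file) {
  rows <- do.call(rbind, lapply(seq_along(spikes@units), function(i) {
    if (!length(spikes@units[[i]])) return(NULL)
    data.frame(unit_id = spikes@unit_ids[i],
               sample_index = spikes@units[[i]])
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(fs = spikes@fs, n_samples = spikes@n_samples),
                         paste0(file, ".json"), auto_unbox = TRUE)
  }
  invisible(file)
}

#' Read spike trains from CSV
#'
#' @param file CSV written by \code{\link{exportSpikesCsv}}.
#' @param fs sampling rate; read from the JSON sidecar when present.
#' @param n_samples recording length; sidecar or max index.
#' @return a \linkS4class{SpikeTrainSet}.
#' @export
readSpikesCsv <- function(file, fs = NULL, n_samples = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  side <- paste0(file, ".json")
  if (file.exists(side) && requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- jsonlite::read_json(side)
    if (is.null(fs)) fs <- meta$fs
    if (is.null(n_samples)) n_samples <- meta$n_samples
  }
  if (is.null(fs)) stop("fs unknown: pass it or provide the sidecar")
  if (is.null(n_samples)) n_samples <- max(tab$sample_index)
  ids <- unique(tab$unit_id)
  units <- lapply(ids, function(u)
    sort(as.integer(tab$sample_index[tab$unit_id == u])))
  spikeTrainSet(units, fs = fs, n_samples = n_samples, unit_ids = ids)
}

#' Export a fascicle trace as CSV
#'
#' Columns: frame, length_mm, pennation_deg, delta_mm.
#'
#' @param trace a \linkS4class{FascicleTrace}.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
exportTraceCsv <- function(trace, file) {
  utils::write.csv(data.frame(frame = seq_along(trace@length_mm),
                              length_mm = trace@length_mm,
                              pennation_deg = trace@pennation_deg,
                              delta_mm = deltaLength(trace)),
                   file, row.names = FALSE)
  invisible(file)
}

#' Write an image sequence as multi-page TIFF
#'
#' @param frames list of matrices in [0, 1] (e.g. \code{TrialRecording@frames}).
#' @param file output TIFF path.
#' @return the file path, invisibly.
#' @export
writeFramesTiff <- function(frames, file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write TIFF sequences")
  tiff::writeTIFF(frames, file)
  invisible(file)
}

#' Read an image sequence from multi-page TIFF
#'
#' @param file TIFF path.
#' @return list of grayscale matrices.
#' @export
readFramesTiff <- function(file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to read TIFF sequences")
  fr <- tiff::readTIFF(file, all = TRUE)
  lapply(fr, function(f) if (length(dim(f)) == 3L) f[, , 1L] else f)
}

#' Write pipeline report tables to a directory
#'
#' Writes \code{xcorr.csv}, \code{thresholds.csv}, \code{rates.csv}, a
#' \code{contrasts.csv} summary and (when jsonlite is available)
#' \code{report.json} with the contrast summaries and the log.
#'
#' @param report a \code{"PipelineReport"} from \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePipelineReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$xcorr, file.path(dir, "xcorr.csv"),
                   row.names = FALSE)
  utils::write.csv(report$thresholds, file.path(dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(report$rates, file.path(dir, "rates.csv"),
                   row.names = FALSE)
  cs <- do.call(rbind, lapply(names(report$contrasts), function(nm) {
    cr <- report$contrasts[[nm]]
    data.frame(contrast = nm, mean_diff = cr@mean_diff,
               ci_lo = cr@ci95[1], ci_hi = cr@ci95[2], p = cr@p, n = cr@n)
  }))
  utils::write.csv(cs, file.path(dir, "contrasts.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(contrasts = cs, log = report$log),
                         file.path(dir, "report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
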