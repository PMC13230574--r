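# On-disk formats of the dataset: "adcData" / "featureMatrix" MAT files, the
# two-header-row physiology CSV, SAM rating CSVs, processed-signal CSVs and
# the folder layout helpers.

# numeric text at full round-trip precision (byte-stable golden files)
fmt_num <- function(x) sprintf("%.17g", x)

#' Format a trial key
#'
#' Participants are 2-digit zero-padded identifiers; clips run 1-18.
#'
#' @param participant Participant number (1-99).
#' @param clip Clip identifier in 1-18.
#' @return List with `participant_id` (e.g. `"01"`) and `clip_id`.
#' @export
trial_key <- function(participant, clip) {
  stopifnot(participant >= 1, participant <= 99, clip >= 1, clip <= 18)
  list(participant_id = sprintf("%02d", as.integer(participant)),
       clip_id = as.integer(clip))
}

#' Dataset folder-layout paths
#'
#' Mirrors the dataset's directory structure: `mmwave/Pxx/<clip>.mat`,
#' `ppg_and_gsr/Pxx/<clip>.csv`, `self_assessment/SAM/SAM_Pxx.csv`, and
#' feature files `<kind>Fea_Pxx_<clip>.mat`.
#'
#' @param root Dataset root directory.
#' @param kind One of `"mmwave"`, `"ppg_and_gsr"`, `"sam"`, `"mmwaveFea"`,
#'   `"ppgFea"`, `"gsrFea"`.
#' @param participant,clip Trial coordinates (clip unused for `"sam"`).
#' @return File path (directories not created).
#' @export
dataset_path <- function(root, kind, participant, clip = NULL) {
  key <- trial_key(participant, if (is.null(clip)) 1 else clip)
  pid <- key$participant_id
  switch(kind,
    mmwave = file.path(root, "mmwave", paste0("P", pid),
                       paste0(key$clip_id, ".mat")),
    ppg_and_gsr = file.path(root, "ppg_and_gsr", paste0("P", pid),
                            paste0(key$clip_id, ".csv")),
    sam = file.path(root, "self_assessment", "SAM",
                    paste0("SAM_P", pid, ".csv")),
    mmwaveFea = file.path(root, "features", "mmwave",
                          sprintf("mmwaveFea_P%s_%02d.mat", pid, key$clip_id)),
    ppgFea = file.path(root, "features", "ppg",
                       sprintf("ppgFea_P%s_%02d.mat", pid, key$clip_id)),
    gsrFea = file.path(root, "features", "gsr",
                       sprintf("gsrFea_P%s_%02d.mat", pid, key$clip_id)),
    stop("unknown dataset path kind: ", kind))
}

#' Write a raw ADC cube as an "adcData" MAT file
#'
#' Rows are virtual channels; the ADC samples of one chirp are followed by
#' those of the next (chirp-sequential layout), so the column count is
#' `adc_samples * n_chirps`.
#'
#' @param path Output path.
#' @param cube An `adc_cube`.
#' @export
write_adc_mat <- function(path, cube) {
  d <- dim(cube)
  # column-major flattening of [channel, fast, slow] puts each channel's
  # samples chirp-sequentially along its row
  m <- matrix(unclass(cube), d[1], d[2] * d[3])
  write_mat5(path, m, "adcData")
}

#' Read an "adcData" MAT file into an ADC cube
#'
#' Validates the layout against the configuration: the row count must equal
#' `n_tx * n_rx` and the column count must be divisible by
#' `adc_samples * chirp_loops * frame_rate` (the clip duration is inferred
#' from the column count, not taken on trust from the file name).
#'
#' @param path MAT file containing matrix `"adcData"`.
#' @param config A [radar_config()].
#' @return An `adc_cube` array `[n_virtual, adc_samples, n_chirps]`.
#' @export
read_adc_mat <- function(path, config) {
  mats <- read_mat5(path)
  if (!"adcData" %in% names(mats)) stop("file contains no matrix 'adcData'")
  m <- mats$adcData
  if (nrow(m) != config$n_virtual)
    stop(sprintf("adcData has %d rows; config declares %d virtual channels",
                 nrow(m), config$n_virtual))
  if (ncol(m) %% config$adc_samples != 0)
    stop("adcData column count is not divisible by adc_samples")
  n_chirp <- ncol(m) %/% config$adc_samples
  per_second <- config$adc_samples * config$chirp_loops * config$frame_rate
  if ((ncol(m) %% per_second) != 0)
    stop("adcData column count does not correspond to a whole number of seconds")
  cube <- array(0i, dim = c(nrow(m), config$adc_samples, n_chirp))
  for (ch in seq_len(nrow(m)))
    cube[ch, , ] <- m[ch, ]
  structure(cube, config = config, class = c("adc_cube", "array"))
}

#' Write the two-header-row physiology CSV
#'
#' Row 1 carries the sampling frequency (both columns), row 2 the data-type
#' labels (`PPG,GSR`), then two numeric columns: PPG first, GSR second.
#'
#' @param path Output path.
#' @param ppg,gsr [physio_signal()]s of equal length and rate.
#' @export
write_physio_csv <- function(path, ppg, gsr) {
  stopifnot(length(ppg$samples) == length(gsr$samples), ppg$fs == gsr$fs)
  lines <- c(paste(fmt_num(ppg$fs), fmt_num(gsr$fs), sep = ","),
             "PPG,GSR",
             paste(fmt_num(ppg$samples), fmt_num(gsr$samples), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read the two-header-row physiology CSV
#'
#' @param path File path.
#' @return List with elements `ppg` and `gsr`, both [physio_signal()]s
#'   tagged with the parsed sampling frequency (GSR in kOhm).
#' @export
read_physio_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("physiology CSV truncated: no data rows")
  fs <- suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1]))
  if (is.na(fs) || fs <= 0) stop("malformed sampling-frequency header")
  # row 2 identifies the data type; any text is accepted there
  cells <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
  if (any(lengths(cells) != 2)) stop("physiology CSV must have exactly 2 columns")
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(2)))
  if (anyNA(vals)) stop("non-numeric cell in physiology CSV")
  list(ppg = physio_signal(vals[1, ], fs, "a.u."),
       gsr = physio_signal(vals[2, ], fs, "kOhm"))
}

#' Write a SAM rating table
#'
#' Header row, then one row per clip: clip ID, valence, arousal, dominance.
#'
#' @param path Output path.
#' @param sam Data frame with columns `clip_id`, `valence`, `arousal`,
#'   `dominance` (one participant).
#' @export
write_sam_csv <- function(path, sam) {
  stopifnot(all(c("clip_id", "valence", "arousal", "dominance") %in% names(sam)))
  utils::write.csv(sam[, c("clip_id", "valence", "arousal", "dominance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SAM rating table
#'
#' @param path CSV with header then rows of clip, valence, arousal, dominance.
#' @return Validated data frame (ratings are integers in 1-9).
#' @export
read_sam_csv <- function(path) {
  sam <- utils::read.csv(path)
  names(sam) <- c("clip_id", "valence", "arousal", "dominance")
  r <- as.matrix(sam[, 2:4])
  if (anyNA(r) || any(r < 1) || any(r > 9) || any(r != round(r)))
    stop("SAM ratings must be integers in [1, 9]")
  sam$clip_id <- as.integer(sam$clip_id)
  sam
}

#' Write a feature matrix as a "featureMatrix" MAT file
#'
#' @param path Output path.
#' @param features Numeric matrix `windows x features`, non-empty.
#' @export
write_feature_matrix <- function(path, features) {
  features <- as.matrix(features)
  if (nrow(features) == 0 || ncol(features) == 0)
    stop("empty feature matrix (no windows)")
  write_mat5(path, unname(features * 1.0), "featureMatrix")
}

#' Read a "featureMatrix" MAT file
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_feature_matrix <- function(path) {
  mats <- read_mat5(path)
  if (!"featureMatrix" %in% names(mats))
    stop("file contains no matrix 'featureMatrix'")
  Re(mats$featureMatrix)
}

#' Write processed vital-sign signals (mmWave CSV dialect)
#'
#' Header row then three columns: vital-sign phase, respiration, heartbeat.
#'
#' @param path Output path.
#' @param bundle A `vital_sign_bundle`.
#' @export
write_vitals_csv <- function(path, bundle) {
  lines <- c("vital_sign_phase,respiration,heartbeat",
             paste(fmt_num(bundle$vital_sign), fmt_num(bundle$respiration),
                   fmt_num(bundle$heartbeat), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a single-column processed-signal CSV (no header)
#'
#' The dialect of the processed PPG / GSR files.
#'
#' @param path Output path.
#' @param x Numeric series.
#' @export
write_single_column_csv <- function(path, x) {
  writeLines(fmt_num(x), path)
  invisible(path)
}
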