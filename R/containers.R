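#' Epoched multichannel EEG
#'
#' Container for a set of trials from one subject and condition.
#'
#' @param data Numeric array `trials x channels x samples` (microvolts).
#' @param rate Sampling rate in Hz.
#' @param times Numeric vector of sample times in ms (length = samples).
#' @param layout An [sensor_layout()] whose channel count matches `data`.
#' @param subject_id,condition Identifiers carried through the pipeline.
#' @return An object of class `"eeg_epochs"`.
#' @export
eeg_epochs <- function(data, rate, times, layout, subject_id = NA_character_,
                       condition = NA_character_) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a trials x channels x samples array")
  if (!all(is.finite(data))) stop("epoch data must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a positive scalar")
  if (length(times) != dim(data)[3L])
    stop("length(times) must equal the number of samples")
  if (dim(data)[2L] != layout$n_channels)
    stop("channel count does not match the layout")
  structure(
    list(data = data, rate = rate, times = as.numeric(times), layout = layout,
         subject_id = subject_id, condition = condition),
    class = "eeg_epochs")
}

#' Averaged event-related potential
#'
#' @param data Numeric matrix `channels x samples` (microvolts).
#' @param n_trials_averaged Number of trials that went into the average.
#' @inheritParams eeg_epochs
#' @return An object of class `"eeg_erp"`.
#' @export
eeg_erp <- function(data, rate, times, layout, subject_id = NA_character_,
                    condition = NA_character_, n_trials_averaged = 1L) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("ERP data must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a positive scalar")
  if (length(times) != ncol(data))
    stop("length(times) must equal the number of samples")
  if (nrow(data) != layout$n_channels)
    stop("channel count does not match the layout")
  rownames(data) <- layout$channel_names
  structure(
    list(data = data, rate = rate, times = as.numeric(times), layout = layout,
         subject_id = subject_id, condition = condition,
         n_trials_averaged = as.integer(n_trials_averaged)),
    class = "eeg_erp")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %s/%s: %d trials x %d channels x %d samples @ %g Hz (%g..%g ms)\n",
              x$subject_id, x$condition, d[1], d[2], d[3], x$rate,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> %s/%s: %d channels x %d samples @ %g Hz, average of %d trial(s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$rate,
              x$n_trials_averaged))
  invisible(x)
}

#' Write / read an ERP as a delimited matrix with a JSON sidecar
#'
#' The matrix file holds one row per sample and one column per channel
#' (tab-separated, header = channel names). The sidecar (`<path>.json`) records
#' subject, condition, sampling rate, time axis and the number of averaged
#' trials.
#'
#' @param erp An `"eeg_erp"`.
#' @param path Path of the matrix file (sidecar written next to it).
#' @param layout Layout to attach on read (defaults to the built-in montage
#'   matched by channel names in the header).
#' @return `write_erp()` returns `path` invisibly; `read_erp()` an `"eeg_erp"`.
#' @export
write_erp <- function(erp, path) {
  stopifnot(inherits(erp, "eeg_erp"))
  m <- t(erp$data)
  utils::write.table(format(as.data.frame(m), digits = 17), path,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  meta <- list(subject_id = erp$subject_id, condition = erp$condition,
               rate = erp$rate, times = erp$times,
               n_trials_averaged = erp$n_trials_averaged)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_erp
#' @export
read_erp <- function(path, layout = NULL) {
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(layout)) {
    full <- layout_1020()
    if (all(colnames(m) %in% full$channel_names) && ncol(m) >= 2) {
      i <- .chan_index(full, colnames(m))
      layout <- sensor_layout(colnames(m), full$positions[i, , drop = FALSE])
    } else stop("cannot infer a layout for these channels; pass 'layout'")
  }
  eeg_erp(t(m), rate = meta$rate, times = meta$times, layout = layout,
          subject_id = meta$subject_id, condition = meta$condition,
          n_trials_averaged = meta$n_trials_averaged)
}

# internal: extract the channels x samples voltage matrix
.voltage <- function(x) {
  if (inherits(x, "eeg_erp")) return(x$data)
  if (is.matrix(x)) return(x)
  stop("expected an 'eeg_erp' or a channels x samples matrix")
}

#' Write / read epoched trials as a delimited matrix
#'
#' One tab-separated file: columns `trial`, `time_ms`, then one column per
#' channel; one row per sample. The JSON sidecar records subject, condition
#' and sampling rate; the layout sidecar (`<path>.layout`) holds the montage.
#'
#' @param epochs An `"eeg_epochs"`.
#' @param path Path of the matrix file.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` an
#'   `"eeg_epochs"`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- epochs$data
  rows <- do.call(rbind, lapply(seq_len(dim(d)[1]), function(tr)
    data.frame(trial = tr, time_ms = epochs$times,
               t(matrix(d[tr, , ], dim(d)[2], dim(d)[3])))))
  names(rows) <- c("trial", "time_ms", epochs$layout$channel_names)
  utils::write.table(format(rows, digits = 17), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  jsonlite::write_json(list(subject_id = epochs$subject_id,
                            condition = epochs$condition, rate = epochs$rate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write_layout(epochs$layout, paste0(path, ".layout"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  m <- utils::read.table(path, header = TRUE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  layout <- read_layout(paste0(path, ".layout"))
  trials <- sort(unique(m$trial))
  times <- m$time_ms[m$trial == trials[1]]
  d <- array(0, c(length(trials), layout$n_channels, length(times)))
  for (i in seq_along(trials)) {
    sub <- m[m$trial == trials[i], layout$channel_names, drop = FALSE]
    d[i, , ] <- t(as.matrix(sub))
  }
  eeg_epochs(d, rate = meta$rate, times = times, layout = layout,
             subject_id = meta$subject_id, condition = meta$condition)
}
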