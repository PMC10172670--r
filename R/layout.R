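#' Sensor layout (montage)
#'
#' A sensor layout holds channel names and unit-sphere 3D positions for a scalp
#' montage. Positions drive bad-channel interpolation neighborhoods and the
#' dipolar prototype-map generator.
#'
#' @param channel_names Character vector of unique channel labels.
#' @param positions Numeric matrix with one row per channel and columns x, y, z
#'   (head coordinates: x right, y anterior, z superior). Each row must have
#'   unit Euclidean norm.
#' @return An object of class `"eeg_layout"`: a list with `channel_names`,
#'   `positions` (rownames set to the channel names) and `n_channels`.
#' @seealso [layout_1020()] for the built-in 64-channel montage,
#'   [read_layout()]/[write_layout()] for the sidecar file format.
#' @export
sensor_layout <- function(channel_names, positions) {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (length(channel_names) < 2L)
    stop("a layout needs at least 2 channels")
  if (nrow(positions) != length(channel_names) || ncol(positions) != 3L)
    stop("'positions' must be an n_channels x 3 matrix")
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("every sensor position must lie on the unit sphere")
  dimnames(positions) <- list(channel_names, c("x", "y", "z"))
  structure(
    list(channel_names = channel_names, positions = positions,
         n_channels = length(channel_names)),
    class = "eeg_layout")
}

#' Built-in 64-channel 10-20/10-10 montage
#'
#' Constructs an idealized spherical 64-channel extended 10-20 layout. Midline
#' electrodes sit on the nasion-inion arc at 18-degree steps; lateral chains are
#' obtained by rotating the corresponding midline position about the
#' anterior-posterior axis in 18-degree steps, the standard spherical
#' approximation of the 10-10 system.
#'
#' @return An `"eeg_layout"` with 64 channels, including the midline
#'   Fz/FCz/Cz/CPz/Pz electrodes used for waveform plotting.
#' @export
layout_1020 <- function() {
  rows <- list(
    # row label prefix, anterior angle (deg; + = front of vertex), labels left..right
    Fp  = list(a =  72, lab = c("Fp1", "Fpz", "Fp2"),              b = c(-18, 0, 18)),
    AF  = list(a =  54, lab = c("AF7", "AF3", "AFz", "AF4", "AF8"), b = c(-54, -27, 0, 27, 54)),
    F   = list(a =  36, lab = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
               b = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    FC  = list(a =  18, lab = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
               b = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    C   = list(a =   0, lab = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
               b = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    CP  = list(a = -18, lab = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
               b = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    P   = list(a = -36, lab = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
               b = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    PO  = list(a = -54, lab = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
               b = c(-54, -36, -18, 0, 18, 36, 54)),
    O   = list(a = -72, lab = c("O1", "Oz", "O2"), b = c(-18, 0, 18)),
    Iz  = list(a = -90, lab = "Iz", b = 0))
  nm <- unlist(lapply(rows, `[[`, "lab"), use.names = FALSE)
  pos <- do.call(rbind, lapply(rows, function(r) {
    a <- r$a * pi / 180
    t(vapply(r$b * pi / 180, function(b) {
      # midline point tilted by a, then rotated laterally by b about the y axis
      c(cos(a) * sin(b), sin(a), cos(a) * cos(b))
    }, numeric(3)))
  }))
  sensor_layout(nm, pos)
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat("<eeg_layout> ", x$n_channels, " channels: ",
      paste(utils::head(x$channel_names, 6), collapse = ", "),
      if (x$n_channels > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read / write a channel-layout sidecar file
#'
#' The sidecar is whitespace-delimited text with a header row and one line per
#' channel: `name x y z`.
#'
#' @param path File path.
#' @return `read_layout()` returns an `"eeg_layout"`; `write_layout()` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  sensor_layout(d$name, as.matrix(d[, c("x", "y", "z")]))
}

#' @rdname read_layout
#' @param layout An `"eeg_layout"`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "eeg_layout"))
  d <- data.frame(name = layout$channel_names, layout$positions,
                  row.names = NULL, check.names = FALSE)
  utils::write.table(format(d, digits = 17), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

# internal: validate channel subset, return indices
.chan_index <- function(layout, names) {
  i <- match(names, layout$channel_names)
  if (anyNA(i))
    stop("unknown channel name(s): ", paste(names[is.na(i)], collapse = ", "))
  i
}
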