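# SNIRF (HDF5) adapter. SNIRF is the acquisition-ecosystem standard
# container for NIRS recordings; this reader covers continuous-wave
# intensity data (dataType 1), which is what the preprocessing chain
# consumes, and classifies short-separation channels from the 3D optode
# geometry. Requires the rhdf5 package (Suggests); everything else in the
# package works without it.

.need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("SNIRF support needs the `rhdf5` package (Bioconductor); install ",
         "it or convert the recording to delimited text (see ",
         "read_group_dataset).", call. = FALSE)
}

#' Read a SNIRF recording
#'
#' Maps a continuous-wave SNIRF file to a [raw_recording()]: intensity
#' series from `/nirs/data1/dataTimeSeries`, sampling rate from the `time`
#' vector, wavelengths and optode positions from `/nirs/probe`. Channels are
#' classified short when their source-detector separation is at most
#' `short_threshold_cm`. Only measurement lists with two wavelengths per
#' source-detector pair and `dataType` 1 (CW amplitude) are supported.
#'
#' @param path SNIRF file.
#' @param short_threshold_cm separation at or below which a channel counts
#'   as short (default 1.0 cm; positions are assumed to be in cm).
#' @param participant identifier; defaults to the file name.
#' @return a [raw_recording()].
#' @export
read_snirf <- function(path, short_threshold_cm = 1.0, participant = NULL) {
  .need_rhdf5()
  if (!file.exists(path)) stop("file not found: '", path, "'.",
                               call. = FALSE)
  root <- rhdf5::h5read(path, "/")
  nirs <- root[["nirs"]]
  if (is.null(nirs)) nirs <- root[["nirs1"]]
  if (is.null(nirs)) stop("'", path, "' has no /nirs group; not a SNIRF ",
                          "file.", call. = FALSE)
  dat <- nirs[["data1"]]
  if (is.null(dat)) stop("'", path, "' has no /nirs/data1 group.",
                         call. = FALSE)
  ts <- dat[["dataTimeSeries"]]
  time <- as.numeric(dat[["time"]])
  if (is.null(ts) || is.null(time))
    stop("'", path, "' lacks dataTimeSeries/time.", call. = FALSE)
  ts <- as.matrix(ts)
  if (nrow(ts) != length(time) && ncol(ts) == length(time)) ts <- t(ts)
  if (nrow(ts) != length(time))
    stop("dataTimeSeries shape does not match the time vector.",
         call. = FALSE)
  fs <- .infer_fs(time, path)

  ml_names <- grep("^measurementList[0-9]+$", names(dat), value = TRUE)
  if (!length(ml_names))
    stop("'", path, "' uses an unsupported measurement-list layout; only ",
         "indexed measurementList groups are supported.", call. = FALSE)
  ml_names <- ml_names[order(as.integer(sub("measurementList", "",
                                            ml_names)))]
  ml <- do.call(rbind, lapply(ml_names, function(nm) {
    m <- dat[[nm]]
    data.frame(source = as.integer(m$sourceIndex),
               detector = as.integer(m$detectorIndex),
               wavelength = as.integer(m$wavelengthIndex),
               dataType = as.integer(m$dataType))
  }))
  if (nrow(ml) != ncol(ts))
    stop("measurement list length disagrees with dataTimeSeries columns.",
         call. = FALSE)
  if (any(ml$dataType != 1L))
    stop("unsupported SNIRF dataType ", ml$dataType[ml$dataType != 1L][1],
         "; only continuous-wave amplitude (dataType 1) is supported.",
         call. = FALSE)

  probe <- nirs[["probe"]]
  if (is.null(probe))
    stop("'", path, "' has no probe geometry; supply the recording as ",
         "delimited text with a manual channel manifest instead.",
         call. = FALSE)
  wavelengths <- as.numeric(probe$wavelengths)
  spos <- probe[["sourcePos3D"]]; dpos <- probe[["detectorPos3D"]]
  if (is.null(spos)) spos <- probe[["sourcePos2D"]]
  if (is.null(dpos)) dpos <- probe[["detectorPos2D"]]
  if (is.null(spos) || is.null(dpos))
    stop("'", path, "' probe lacks optode positions; supply a manual ",
         "channel manifest instead.", call. = FALSE)
  spos <- as.matrix(spos); dpos <- as.matrix(dpos)
  if (nrow(spos) < max(ml$source)) spos <- t(spos)
  if (nrow(dpos) < max(ml$detector)) dpos <- t(dpos)

  pair_key <- paste(ml$source, ml$detector, sep = "-")
  channels <- unique(pair_key)
  k <- length(channels)
  intens <- matrix(NA_real_, nrow(ts), 2L * k)
  sep <- numeric(k)
  for (i in seq_len(k)) {
    rows <- which(pair_key == channels[i])
    if (length(rows) != 2L || setequal(ml$wavelength[rows], 1:2) == FALSE)
      stop("channel ", channels[i], " does not have exactly one column per ",
           "wavelength.", call. = FALSE)
    rows <- rows[order(ml$wavelength[rows])]
    intens[, 2L * i - 1L] <- ts[, rows[1]]
    intens[, 2L * i] <- ts[, rows[2]]
    s <- ml$source[rows[1]]; d <- ml$detector[rows[1]]
    sep[i] <- sqrt(sum((spos[s, ] - dpos[d, ])^2))
  }
  geo <- data.frame(
    channel = paste0("S", sub("-.*", "", channels), "D",
                     sub(".*-", "", channels)),
    separation_cm = sep,
    role = ifelse(sep <= short_threshold_cm, "short", "long"),
    stringsAsFactors = FALSE)
  if (is.null(participant))
    participant <- tools::file_path_sans_ext(basename(path))
  raw_recording(intens, geo, fs = fs, wavelengths = wavelengths,
                participant = participant)
}

#' Write a minimal SNIRF file
#'
#' Serialises a [raw_recording()] as a minimal conformant continuous-wave
#' SNIRF file (one data block, indexed measurement lists, synthetic inline
#' probe geometry reproducing each channel's separation). Used for fixtures
#' and interchange; requires rhdf5.
#'
#' @param raw a [raw_recording()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_snirf <- function(raw, path) {
  .need_rhdf5()
  stopifnot(inherits(raw, "raw_recording"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5createGroup(path, "nirs/probe")
  h5w("1.0", "formatVersion")
  t_len <- nrow(raw$intensities)
  h5w(raw$intensities, "nirs/data1/dataTimeSeries")
  h5w((seq_len(t_len) - 1) / raw$fs, "nirs/data1/time")
  k <- nrow(raw$geometry)
  # one synthetic source/detector pair per channel, spaced along x
  spos <- cbind(10 * seq_len(k), 0, 0)
  dpos <- cbind(10 * seq_len(k) + raw$geometry$separation_cm, 0, 0)
  h5w(raw$wavelengths, "nirs/probe/wavelengths")
  h5w(spos, "nirs/probe/sourcePos3D")
  h5w(dpos, "nirs/probe/detectorPos3D")
  idx <- 0L
  for (i in seq_len(k)) for (w in 1:2) {
    idx <- idx + 1L
    grp <- paste0("nirs/data1/measurementList", idx)
    rhdf5::h5createGroup(path, grp)
    h5w(i, paste0(grp, "/sourceIndex"))
    h5w(i, paste0(grp, "/detectorIndex"))
    h5w(w, paste0(grp, "/wavelengthIndex"))
    h5w(1L, paste0(grp, "/dataType"))
    h5w(1L, paste0(grp, "/dataTypeIndex"))
  }
  invisible(path)
}
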