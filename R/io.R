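# Plain-text interchange: one TSV per participant (first column `time` in
# seconds, remaining columns channels) plus a channel-role manifest
# (`manifest.tsv`: columns channel, role[, separation_cm]). Values are
# written with 17 significant digits so write -> read round-trips to 1e-12.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a group dataset as per-participant delimited text
#'
#' @param group a [group_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_group_dataset <- function(group, dir) {
  stopifnot(inherits(group, "group_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  time <- group$t0 + (seq_len(group$n_frames) - 1L) / group$fs
  paths <- character(0)
  for (p in group$participants) {
    df <- data.frame(time = .fmt(time))
    for (ch in group$channel_ids) df[[ch]] <- .fmt(group$data[[p]][, ch])
    path <- file.path(dir, paste0(p, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  manifest <- data.frame(channel = group$channel_ids, role = "long",
                         stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, mpath))
}

# Sampling rate from a time column; errors on non-uniform sampling.
.infer_fs <- function(time, file, tol = 0.01) {
  dt <- diff(time)
  if (any(dt <= 0))
    stop("non-monotone time column in '", file, "'.", call. = FALSE)
  med <- stats::median(dt)
  if (max(abs(dt - med)) > tol * med)
    stop("non-uniform sampling in '", file, "': time steps deviate more ",
         "than ", 100 * tol, "% from the median interval.", call. = FALSE)
  1 / med
}

#' Read per-participant delimited text into a group dataset
#'
#' @param paths character vector of participant files, or a directory
#'   containing `*.tsv` participant files plus `manifest.tsv`.
#' @param manifest path to the channel-role manifest; defaults to
#'   `manifest.tsv` next to the first participant file.
#' @return a [group_dataset()] of the manifest's long channels.
#' @export
read_group_dataset <- function(paths, manifest = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    dir <- paths
    if (is.null(manifest)) manifest <- file.path(dir, "manifest.tsv")
    paths <- setdiff(list.files(dir, pattern = "\\.tsv$", full.names = TRUE),
                     manifest)
  }
  if (is.null(manifest))
    manifest <- file.path(dirname(paths[1]), "manifest.tsv")
  if (!file.exists(manifest))
    stop("channel manifest not found at '", manifest, "'.", call. = FALSE)
  man <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("channel", "role") %in% names(man)))
    stop("manifest needs columns `channel` and `role`.", call. = FALSE)
  long_ch <- man$channel[man$role == "long"]
  if (!length(long_ch)) stop("manifest lists no long channels.",
                             call. = FALSE)

  data <- list(); fs <- NULL; t0 <- NULL
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: '", path, "'.",
                                 call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    if (!("time" %in% names(df)))
      stop("'", path, "' lacks a `time` column.", call. = FALSE)
    missing_ch <- setdiff(long_ch, names(df))
    if (length(missing_ch))
      stop("'", path, "' is missing channel '", missing_ch[1], "'.",
           call. = FALSE)
    this_fs <- .infer_fs(df$time, path)
    if (is.null(fs)) { fs <- this_fs; t0 <- df$time[1] }
    else if (abs(this_fs - fs) > 0.01 * fs)
      stop("sampling rate of '", path, "' (", round(this_fs, 4),
           " Hz) disagrees with the first file (", round(fs, 4), " Hz).",
           call. = FALSE)
    data[[tools::file_path_sans_ext(basename(path))]] <-
      as.matrix(df[, long_ch, drop = FALSE])
  }
  t_lens <- vapply(data, nrow, integer(1))
  if (length(unique(t_lens)) != 1L)
    stop("participant files have unequal frame counts (",
         paste(unique(t_lens), collapse = ", "),
         "); align or truncate before analysis.", call. = FALSE)
  group_dataset(data, fs = fs, channel_ids = long_ch, t0 = t0)
}

#' Write raw dual-wavelength recordings as delimited text
#'
#' Columns: `time`, then `<channel>_<wavelength>` pairs. The manifest gains a
#' `separation_cm` column.
#'
#' @param recordings list of [raw_recording()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_raw_recordings <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geo <- recordings[[1]]$geometry
  wl <- recordings[[1]]$wavelengths
  paths <- character(0)
  for (r in recordings) {
    t_len <- nrow(r$intensities)
    df <- data.frame(time = .fmt((seq_len(t_len) - 1L) / r$fs))
    for (k in seq_len(nrow(geo))) for (w in 1:2)
      df[[paste0(geo$channel[k], "_", wl[w])]] <-
        .fmt(r$intensities[, 2L * (k - 1L) + w])
    path <- file.path(dir, paste0(r$participant, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(geo, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, mpath))
}

#' Read raw dual-wavelength recordings from delimited text
#'
#' @param paths participant files or a directory (as [read_group_dataset()]).
#' @param manifest manifest path with `channel`, `role`, `separation_cm`.
#' @param wavelengths the two wavelengths expected in the column names.
#' @return list of [raw_recording()].
#' @export
read_raw_recordings <- function(paths, manifest = NULL,
                                wavelengths = c(760, 850)) {
  if (length(paths) == 1L && dir.exists(paths)) {
    dir <- paths
    if (is.null(manifest)) manifest <- file.path(dir, "manifest.tsv")
    paths <- setdiff(list.files(dir, pattern = "\\.tsv$", full.names = TRUE),
                     manifest)
  }
  if (is.null(manifest))
    manifest <- file.path(dirname(paths[1]), "manifest.tsv")
  geo <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("channel", "role", "separation_cm") %in% names(geo)))
    stop("raw manifest needs columns channel, role, separation_cm.",
         call. = FALSE)
  lapply(paths, function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    fs <- .infer_fs(df$time, path)
    cols <- as.vector(t(outer(geo$channel, wavelengths, paste, sep = "_")))
    missing_col <- setdiff(cols, names(df))
    if (length(missing_col))
      stop("'", path, "' is missing intensity column '", missing_col[1],
           "'.", call. = FALSE)
    raw_recording(as.matrix(df[, cols]), geo, fs = fs,
                  wavelengths = wavelengths,
                  participant = tools::file_path_sans_ext(basename(path)))
  })
}

#' Read a key = value configuration file
#'
#' Lines of the form `module.parameter = value` (`#` comments allowed).
#' Values are parsed as numeric where possible, `TRUE`/`FALSE` as logical,
#' and comma-separated lists as vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'.",
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'.", call. = FALSE)
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(vals))
    if (!anyNA(parsed)) vals <- parsed
    else if (all(vals %in% c("TRUE", "FALSE"))) vals <- as.logical(vals)
    out[[key]] <- vals
  }
  out
}

# Pull `prefix.*` keys from a config list as arguments for `fn`'s formals.
.config_args <- function(config, prefix, fn) {
  if (is.null(config)) return(list())
  keys <- names(config)
  sel <- startsWith(keys, paste0(prefix, "."))
  args <- config[sel]
  names(args) <- sub(paste0("^", prefix, "\\."), "", names(args))
  unknown <- setdiff(names(args), names(formals(fn)))
  if (length(unknown))
    stop("unknown config parameter(s) for ", prefix, ": ",
         paste(unknown, collapse = ", "), ".", call. = FALSE)
  args
}
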