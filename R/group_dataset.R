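#' Aligned multi-participant hemodynamic dataset
#'
#' Bundles frame-aligned time-by-channel matrices, one per participant, with a
#' shared channel manifest and sampling rate. This is the unit of analysis for
#' the intersubject similarity statistic: at each frame, the rows across
#' participants are the multivariate "hemodynamic states" whose pairwise
#' distances define the participant graph.
#'
#' @param data named list of numeric matrices, one per participant, each
#'   `T x C` (frames by long channels). All matrices must have identical
#'   dimensions and finite values, with channels in manifest order.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_ids character vector of `C` long-channel labels. Defaults to
#'   the column names of the first matrix, or `"ch1" ... "chC"`.
#' @param participants character vector of participant identifiers. Defaults
#'   to `names(data)`, or `"p1" ... "pN"`.
#' @param t0 acquisition start offset in seconds (default 0), used when frame
#'   indices are converted to stimulus timestamps.
#'
#' @return an object of class `group_dataset` with fields `data`,
#'   `participants`, `channel_ids`, `fs`, `t0`, `n_frames`.
#' @examples
#' mats <- replicate(3, matrix(rnorm(40), 10, 4), simplify = FALSE)
#' g <- group_dataset(mats, fs = 7.81)
#' g
#' @export
group_dataset <- function(data, fs, channel_ids = NULL, participants = NULL,
                          t0 = 0) {
  if (!is.list(data) || length(data) < 3L)
    stop("`data` must be a list of >= 3 participant matrices; ",
         "closeness over fewer nodes is degenerate.", call. = FALSE)
  data <- lapply(data, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(data, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all participant matrices must share the same T x C dimensions ",
         "(found T in {", paste(unique(dims[1, ]), collapse = ","),
         "}, C in {", paste(unique(dims[2, ]), collapse = ","), "}).",
         call. = FALSE)
  n_frames <- as.integer(dims[1, 1])
  n_channels <- as.integer(dims[2, 1])
  if (n_frames < 2L) stop("need at least 2 frames.", call. = FALSE)
  if (n_channels < 1L) stop("need at least 1 channel.", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)

  if (is.null(participants)) participants <- names(data)
  if (is.null(participants)) participants <- paste0("p", seq_along(data))
  participants <- as.character(participants)
  if (length(participants) != length(data) || anyDuplicated(participants))
    stop("`participants` must uniquely label each matrix.", call. = FALSE)
  names(data) <- participants

  if (is.null(channel_ids)) channel_ids <- colnames(data[[1]])
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(n_channels))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != n_channels || anyDuplicated(channel_ids))
    stop("`channel_ids` must uniquely label the ", n_channels, " channels.",
         call. = FALSE)
  data <- lapply(data, function(m) { colnames(m) <- channel_ids; m })

  for (p in participants) {
    bad <- which(!is.finite(data[[p]]))
    if (length(bad)) {
      fr <- (bad[1] - 1L) %% n_frames + 1L
      ch <- (bad[1] - 1L) %/% n_frames + 1L
      stop("non-finite value for participant '", p, "', channel '",
           channel_ids[ch], "', frame ", fr - 1L,
           "; preprocessing must remove non-finite samples.", call. = FALSE)
    }
  }

  structure(
    list(data = data, participants = participants, channel_ids = channel_ids,
         fs = as.numeric(fs), t0 = as.numeric(t0), n_frames = n_frames),
    class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat("<group_dataset> ", length(x$participants), " participants, ",
      x$n_frames, " frames x ", length(x$channel_ids), " channels @ ",
      format(x$fs), " Hz\n", sep = "")
  cat("  participants: ", paste(utils::head(x$participants, 6),
                                collapse = ", "),
      if (length(x$participants) > 6) ", ..." else "", "\n", sep = "")
  cat("  channels:     ", paste(utils::head(x$channel_ids, 8),
                                collapse = ", "),
      if (length(x$channel_ids) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.group_dataset <- function(x) {
  c(frames = x$n_frames, channels = length(x$channel_ids),
    participants = length(x$participants))
}
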