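#' Most inter-individually consistent frames
#'
#' After the global test rejects, the frames carrying the similarity are the
#' ones with the highest closeness. Selects the `k = ceiling((1 - q) * T)`
#' top-closeness frames (count-based top-k; ties broken in favour of the
#' earlier frame). Purely descriptive -- no per-frame inference is performed.
#'
#' @param series a [closeness_series()].
#' @param threshold_quantile fraction in (0, 1); default 0.95 selects the top
#'   5% of frames.
#' @return object of class `frame_set`: list with `frames` (0-based, sorted
#'   ascending), `threshold_quantile`, `closeness_at_threshold` (smallest
#'   selected closeness), `fs`, `t0`.
#' @export
top_frames <- function(series, threshold_quantile = 0.95) {
  stopifnot(inherits(series, "closeness_series"))
  q <- threshold_quantile
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop("`threshold_quantile` must lie strictly in (0, 1).", call. = FALSE)
  t_len <- length(series$values)
  # epsilon guards against fp artifacts like (1 - 0.95) * 100 = 5.000000...4
  k <- max(1L, ceiling((1 - q) * t_len - 1e-9))
  ord <- order(-series$values, series$frame_indices)
  sel <- sort(series$frame_indices[ord[seq_len(k)]])
  structure(
    list(frames = sel, threshold_quantile = q,
         closeness_at_threshold = min(series$values[sel + 1L]),
         fs = series$fs, t0 = series$t0),
    class = "frame_set")
}

#' Map selected frames back to stimulus time
#'
#' The vascular response lags neural activity by roughly 5 s, so a frame
#' reflects the stimulus shown `hrf_delay` seconds earlier. Converts frame
#' indices to delay-corrected stimulus times `t0 + frame/fs - hrf_delay`,
#' clipped at 0, together with `"MM:SS"` renderings for matching against a
#' stimulus timeline.
#'
#' @param frames a [top_frames()] result, or a bare vector of 0-based frame
#'   indices (then `fs` must be given).
#' @param fs sampling rate in Hz; taken from `frames` when available.
#' @param hrf_delay hemodynamic delay in seconds (default 5).
#' @param t0 recording start offset in seconds.
#' @return data.frame with columns `frame`, `seconds`, `mmss`.
#' @examples
#' frame_timestamps(781, fs = 7.81)  # 95 s -> "01:35"
#' @export
frame_timestamps <- function(frames, fs = NULL, hrf_delay = 5.0, t0 = NULL) {
  if (inherits(frames, "frame_set")) {
    if (is.null(fs)) fs <- frames$fs
    if (is.null(t0)) t0 <- frames$t0
    frames <- frames$frames
  }
  if (is.null(t0)) t0 <- 0
  if (is.null(fs) || !is.numeric(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz.", call. = FALSE)
  if (!is.numeric(hrf_delay) || hrf_delay < 0)
    stop("`hrf_delay` must be >= 0 seconds.", call. = FALSE)
  secs <- pmax(0, t0 + frames / fs - hrf_delay)
  mmss <- sprintf("%02d:%02d", floor(secs) %/% 60L, floor(secs) %% 60L)
  data.frame(frame = frames, seconds = secs, mmss = mmss,
             stringsAsFactors = FALSE)
}

#' Leave-one-channel-out channel relevance mapping
#'
#' Which channels carry the intersubject similarity? For each channel the
#' closeness series is recomputed with that channel removed; the per-frame
#' *drop* `full - leave_one_out` measures how much that channel contributed
#' at that frame (removing a relevant channel lowers closeness). Per frame,
#' the `ceiling(top_fraction * C)` channels with the largest drop are marked
#' relevant (ties broken by channel order); a channel's relevance frequency
#' is the fraction of frames in which it was marked. Ranking by drop is
#' identical to ranking by ascending leave-one-out closeness, since the full
#' series is constant within a frame. Descriptive only: no per-channel
#' p-values are computed.
#'
#' @param group a [group_dataset()] with `C >= 2` channels.
#' @param top_fraction fraction in (0, 1) of channels marked per frame
#'   (default 0.25).
#' @return object of class `channel_relevance`: list with `channel_ids`,
#'   `relevance_frequency` (named, in frame fraction), `loo_values`
#'   (`T x C` leave-one-out closeness matrix), `full_series`, `top_fraction`,
#'   `k_per_frame`.
#' @export
channel_relevance <- function(group, top_fraction = 0.25) {
  stopifnot(inherits(group, "group_dataset"))
  n_ch <- length(group$channel_ids)
  if (n_ch < 2L) stop("channel relevance needs >= 2 channels.", call. = FALSE)
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1)
    stop("`top_fraction` must lie strictly in (0, 1).", call. = FALSE)

  full <- closeness_series(group)
  t_len <- group$n_frames
  loo <- matrix(NA_real_, t_len, n_ch,
                dimnames = list(NULL, group$channel_ids))
  for (c in seq_len(n_ch)) {
    keep <- setdiff(seq_len(n_ch), c)
    loo[, c] <- .closeness_engine(group$data, keep)
  }

  k <- max(1L, ceiling(top_fraction * n_ch - 1e-9))
  counts <- integer(n_ch)
  ch_seq <- seq_len(n_ch)
  for (t in seq_len(t_len)) {
    drop <- full$values[t] - loo[t, ]
    marked <- order(-drop, ch_seq)[seq_len(k)]
    counts[marked] <- counts[marked] + 1L
  }
  freq <- counts / t_len
  names(freq) <- group$channel_ids

  structure(
    list(channel_ids = group$channel_ids, relevance_frequency = freq,
         loo_values = loo, full_series = full, top_fraction = top_fraction,
         k_per_frame = k),
    class = "channel_relevance")
}

#' @export
print.channel_relevance <- function(x, ...) {
  cat("<channel_relevance> ", length(x$channel_ids), " channels, ",
      x$k_per_frame, " marked per frame (top ",
      format(100 * x$top_fraction), "%)\n", sep = "")
  ord <- order(-x$relevance_frequency)
  top <- utils::head(ord, 5)
  for (i in top)
    cat(sprintf("  %-8s in top set %5.1f%% of frames\n", x$channel_ids[i],
                100 * x$relevance_frequency[i]))
  invisible(x)
}
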