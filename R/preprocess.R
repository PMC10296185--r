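#' Raw dual-wavelength fNIRS recording
#'
#' Container for detected light intensities before hemodynamic conversion.
#' Columns are channel-major wavelength pairs: channel `k` occupies columns
#' `2k-1` (first wavelength) and `2k` (second wavelength).
#'
#' @param intensities `T x 2K` matrix of strictly positive intensities
#'   (arbitrary device units).
#' @param geometry data.frame with one row per optode channel and columns
#'   `channel` (label), `separation_cm` (source-detector distance) and `role`
#'   (`"long"` or `"short"`).
#' @param fs sampling rate in Hz.
#' @param wavelengths the two wavelengths in nm (default 760, 850).
#' @param participant identifier string.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(intensities, geometry, fs,
                          wavelengths = c(760, 850), participant = "p1") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  k <- nrow(geometry)
  if (ncol(intensities) != 2L * k)
    stop("expected ", 2L * k, " intensity columns (2 wavelengths x ", k,
         " channels), got ", ncol(intensities), ".", call. = FALSE)
  need <- c("channel", "separation_cm", "role")
  if (!all(need %in% names(geometry)))
    stop("`geometry` needs columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  if (!all(geometry$role %in% c("long", "short")))
    stop("geometry `role` must be 'long' or 'short'.", call. = FALSE)
  if (!any(geometry$role == "long"))
    stop("at least one long channel is required.", call. = FALSE)
  bad <- which(!(is.finite(intensities) & intensities > 0))
  if (length(bad)) {
    fr <- (bad[1] - 1L) %% nrow(intensities) + 1L
    ch <- ceiling(((bad[1] - 1L) %/% nrow(intensities) + 1L) / 2)
    stop("nonpositive/non-finite intensity at frame ", fr - 1L, ", channel '",
         geometry$channel[ch], "': optical density needs positive input.",
         call. = FALSE)
  }
  if (length(wavelengths) != 2L)
    stop("exactly two wavelengths are supported.", call. = FALSE)
  structure(list(intensities = intensities, geometry = geometry,
                 fs = as.numeric(fs), wavelengths = as.numeric(wavelengths),
                 participant = as.character(participant)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> '", x$participant, "': ", nrow(x$intensities),
      " frames, ", sum(x$geometry$role == "long"), " long + ",
      sum(x$geometry$role == "short"), " short channels @ ", format(x$fs),
      " Hz (", paste(x$wavelengths, collapse = "/"), " nm)\n", sep = "")
  invisible(x)
}

#' Preprocessing configuration
#'
#' Parameters of the conditioning chain. The packaged extinction coefficients
#' and differential pathlength factor are standard tabulated values; any site
#' with calibrated values for its device should replace them -- downstream
#' results are insensitive to this choice up to a near-linear rescaling that
#' the final variance normalisation removes.
#'
#' @param band band-pass edges in Hz, default `c(0.01, 0.08)` -- the slow
#'   hemodynamic band, excluding drift below 0.01 Hz and Mayer-wave /
#'   cardiac / respiratory components above 0.08 Hz.
#' @param wavelet_lambda despiking aggressiveness: two-sided tail probability
#'   of the per-level Gaussian coefficient model beyond which wavelet detail
#'   coefficients are treated as motion spikes and clipped (default 0.1).
#' @param dpf differential pathlength factor per wavelength (dimensionless),
#'   default `c(6, 6)`.
#' @param extinction `2 x 2` matrix of extinction coefficients, wavelengths in
#'   rows, chromophores (HbO, HbR) in columns, units 1/(mM*cm).
#' @param filter_order Butterworth order (default 3).
#' @param chromophore which chromophore(s) to keep: `"HbO"` (default),
#'   `"HbR"`, or `"both"`.
#' @param short_regression regress short-separation channels out of long
#'   channels (default TRUE).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(0.01, 0.08), wavelet_lambda = 0.1,
                              dpf = c(6, 6), extinction = NULL,
                              filter_order = 3L,
                              chromophore = c("HbO", "HbR", "both"),
                              short_regression = TRUE) {
  chromophore <- match.arg(chromophore)
  if (is.null(extinction))
    extinction <- matrix(c(0.5862, 1.5489,   # 760 nm: HbO, HbR
                           1.0584, 0.7816),  # 850 nm: HbO, HbR
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("760", "850"), c("HbO", "HbR")))
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2L, 2L)) || abs(det(extinction)) < 1e-12)
    stop("`extinction` must be an invertible 2 x 2 matrix ",
         "(wavelength x chromophore).", call. = FALSE)
  if (length(band) != 2L || !(band[1] > 0 && band[2] > band[1]))
    stop("`band` must be c(low, high) with 0 < low < high.", call. = FALSE)
  if (length(dpf) == 1L) dpf <- rep(dpf, 2)
  if (!is.numeric(wavelet_lambda) || wavelet_lambda <= 0 ||
      wavelet_lambda >= 1)
    stop("`wavelet_lambda` must lie in (0, 1).", call. = FALSE)
  structure(list(band = as.numeric(band),
                 wavelet_lambda = as.numeric(wavelet_lambda),
                 dpf = as.numeric(dpf), extinction = extinction,
                 filter_order = as.integer(filter_order),
                 chromophore = chromophore,
                 short_regression = isTRUE(short_regression)),
            class = "preprocess_config")
}

#' Optical density change from detected intensity
#'
#' `dOD(t) = -log10(I(t) / mean(I))`, per column, so the series is centred on
#' its own temporal mean (dOD has mean approximately 0).
#'
#' @param intensities strictly positive vector or `T x m` matrix.
#' @return same shape, optical density changes.
#' @export
optical_density <- function(intensities) {
  x <- as.matrix(intensities)
  bad <- which(!(is.finite(x) & x > 0))
  if (length(bad)) {
    fr <- (bad[1] - 1L) %% nrow(x) + 1L
    co <- (bad[1] - 1L) %/% nrow(x) + 1L
    stop("nonpositive intensity at frame ", fr - 1L, ", column ", co, ".",
         call. = FALSE)
  }
  out <- -log10(sweep(x, 2, colMeans(x), "/"))
  if (is.null(dim(intensities))) out[, 1] else out
}

#' Modified Beer-Lambert inversion
#'
#' Solves the two-wavelength system
#' `dOD_l = (e_l,HbO dHbO + e_l,HbR dHbR) * separation * dpf_l`
#' for the chromophore concentration changes at every frame.
#'
#' @param od `T x 2` matrix of optical-density changes (one column per
#'   wavelength, in the same order as the extinction rows).
#' @param separation source-detector separation in cm.
#' @param dpf differential pathlength factor, length 1 or 2.
#' @param extinction `2 x 2` extinction matrix (wavelength x chromophore),
#'   1/(mM*cm).
#' @return `T x 2` matrix with columns `HbO`, `HbR` (mM).
#' @export
beer_lambert <- function(od, separation, dpf = c(6, 6), extinction = NULL) {
  if (is.null(extinction)) extinction <- preprocess_config()$extinction
  od <- as.matrix(od)
  if (ncol(od) != 2L) stop("`od` must have two wavelength columns.",
                           call. = FALSE)
  if (!is.numeric(separation) || separation <= 0)
    stop("`separation` must be positive (cm).", call. = FALSE)
  if (length(dpf) == 1L) dpf <- rep(dpf, 2)
  A <- extinction * separation * dpf   # row l scaled by dpf[l] * separation
  if (abs(det(A)) < 1e-15) stop("singular extinction system.", call. = FALSE)
  conc <- t(solve(A, t(od)))
  colnames(conc) <- c("HbO", "HbR")
  conc
}

#' Z-transform a series to mean 0, sample variance 1
#'
#' @param x numeric vector with positive sample standard deviation.
#' @return standardised vector.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate channel: constant series cannot be z-scored.",
         call. = FALSE)
  (x - mean(x)) / s
}

#' Wavelet despiking for motion artifacts
#'
#' Decomposes the series with a periodized Daubechies-4 DWT and clips
#' implausibly large fine-scale detail coefficients to the scaled universal
#' threshold `lambda * sigma * sqrt(2 ln T)`, where `sigma` is the
#' MAD-based robust noise scale of the finest detail level (sign preserved,
#' "shrunk to the threshold"). Only the finest `spike_levels` detail levels
#' are thresholded: motion spikes are fast, high-amplitude excursions whose
#' energy concentrates at fine scales (at 7.81 Hz, levels 1-2 cover roughly
#' everything above 1 Hz), whereas the coarse levels carry the slow
#' hemodynamic band and are left untouched -- that is what makes `lambda`
#' as small as 0.1 remove *only* spikes while passing smooth signal through
#' essentially unchanged.
#'
#' @param x numeric vector, length >= 8.
#' @param lambda universal-threshold scale in (0, 1), default 0.1.
#' @param n_levels decomposition depth; default `floor(log2(T)) - 2`.
#' @param spike_levels number of finest detail levels subjected to
#'   thresholding (default 2).
#' @return despiked vector, same length.
#' @export
wavelet_despike <- function(x, lambda = 0.1, n_levels = NULL,
                            spike_levels = 2L) {
  t_len <- length(x)
  if (t_len < 8L) stop("need at least 8 samples for one decomposition level.",
                       call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0 || lambda >= 1)
    stop("`lambda` must lie in (0, 1).", call. = FALSE)
  J <- if (is.null(n_levels)) max(1L, floor(log2(t_len)) - 2L) else
    as.integer(n_levels)
  if (J < 1L || 2^J > t_len)
    stop("invalid decomposition depth for series of length ", t_len, ".",
         call. = FALSE)
  # reflect-pad to a multiple of 2^J so the periodized pyramid applies
  block <- 2^J
  t_pad <- ceiling(t_len / block) * block
  xp <- if (t_pad > t_len) c(x, rev(x)[seq_len(t_pad - t_len)]) else x

  dec <- .dwt_periodic(xp, J)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6744898
  thr <- lambda * sigma * sqrt(2 * log(t_len))
  for (j in seq_len(min(J, as.integer(spike_levels)))) {
    d <- dec$details[[j]]
    dec$details[[j]] <- sign(d) * pmin(abs(d), thr)
  }
  .idwt_periodic(dec)[seq_len(t_len)]
}

#' Zero-phase Butterworth band-pass
#'
#' Order-`order` Butterworth band-pass realised as second-order sections and
#' applied forward-backward (zero phase, squared magnitude response). DC is
#' rejected exactly.
#'
#' @param x numeric vector.
#' @param band `c(low, high)` in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 3).
#' @return filtered vector, same length.
#' @export
bandpass <- function(x, band = c(0.01, 0.08), fs, order = 3L) {
  if (missing(fs)) stop("`fs` is required.", call. = FALSE)
  sos <- .butter_bandpass_sos(band[1], band[2], fs, as.integer(order))
  .filtfilt_sos(sos, as.numeric(x))
}

#' Regress short-separation channels out of a long channel
#'
#' Ordinary least squares of the long channel onto all short channels plus an
#' intercept; returns the residuals, which are orthogonal to every short
#' regressor. Short channels sample only superficial (scalp/systemic)
#' hemodynamics, so the residual retains the cortical component.
#'
#' @param long numeric vector (T).
#' @param shorts `T x S` matrix of short-channel series.
#' @return residual vector (T).
#' @export
short_channel_regress <- function(long, shorts) {
  shorts <- as.matrix(shorts)
  t_len <- length(long)
  if (nrow(shorts) != t_len)
    stop("`shorts` must have one row per frame of `long`.", call. = FALSE)
  if (t_len <= ncol(shorts) + 1L)
    stop("need T > S + 1 frames for the regression.", call. = FALSE)
  X <- cbind(1, shorts)
  fit <- stats::lm.fit(X, long)
  if (fit$rank < ncol(X))
    warning("rank-deficient short-channel regressors; using pivoted ",
            "least-squares solution.", call. = FALSE)
  as.numeric(fit$residuals)
}

#' Full preprocessing chain: raw intensities to analysis-ready dataset
#'
#' Per participant and channel: optical density, modified Beer-Lambert
#' inversion, z-transform, wavelet despiking, zero-phase band-pass,
#' short-separation channel regression (longs on all shorts), and a final
#' rescale of every long channel to variance one so that between-participant
#' Euclidean distances are comparable. Recordings of unequal length are
#' truncated to the common minimum. Stage order follows the conditioning
#' chain this analysis was designed around.
#'
#' @param recordings list of [raw_recording()] sharing fs and geometry.
#' @param config a [preprocess_config()].
#' @return a [group_dataset()] of the retained chromophore's long channels
#'   (with `"both"`, channels appear twice, suffixed `_HbO` / `_HbR`).
#' @export
preprocess_pipeline <- function(recordings, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  if (!length(recordings) || !all(vapply(recordings, inherits, logical(1),
                                         "raw_recording")))
    stop("`recordings` must be a list of raw_recording objects.",
         call. = FALSE)
  fs <- recordings[[1]]$fs
  geo <- recordings[[1]]$geometry
  for (r in recordings) {
    if (abs(r$fs - fs) > 1e-9 * fs)
      stop("participant '", r$participant, "' has mismatched sampling rate.",
           call. = FALSE)
    if (!identical(as.character(r$geometry$channel),
                   as.character(geo$channel)) ||
        !identical(as.character(r$geometry$role), as.character(geo$role)))
      stop("participant '", r$participant, "' has mismatched channel ",
           "geometry.", call. = FALSE)
  }
  t_min <- min(vapply(recordings, function(r) nrow(r$intensities),
                      integer(1)))
  chroms <- if (config$chromophore == "both") c("HbO", "HbR") else
    config$chromophore

  long_idx <- which(geo$role == "long")
  short_idx <- which(geo$role == "short")

  condition_channel <- function(series) {
    x <- zscore(series)
    x <- wavelet_despike(x, lambda = config$wavelet_lambda)
    bandpass(x, band = config$band, fs = fs, order = config$filter_order)
  }

  data <- list()
  for (r in recordings) {
    intens <- r$intensities[seq_len(t_min), , drop = FALSE]
    conc <- vector("list", nrow(geo))
    for (k in seq_len(nrow(geo))) {
      od <- optical_density(intens[, c(2L * k - 1L, 2L * k), drop = FALSE])
      conc[[k]] <- tryCatch(
        beer_lambert(od, separation = geo$separation_cm[k],
                     dpf = config$dpf, extinction = config$extinction),
        error = function(e) stop("participant '", r$participant,
                                 "', channel '", geo$channel[k], "': ",
                                 conditionMessage(e), call. = FALSE))
    }
    out_cols <- list()
    for (chrom in chroms) {
      shorts <- NULL
      if (config$short_regression && length(short_idx))
        shorts <- vapply(short_idx,
                         function(k) condition_channel(conc[[k]][, chrom]),
                         numeric(t_min))
      for (k in long_idx) {
        x <- condition_channel(conc[[k]][, chrom])
        if (!is.null(shorts)) x <- short_channel_regress(x, shorts)
        x <- x - mean(x)
        s <- stats::sd(x)
        if (s == 0)
          stop("participant '", r$participant, "', channel '",
               geo$channel[k], "': zero variance after preprocessing.",
               call. = FALSE)
        lab <- if (length(chroms) > 1L)
          paste0(geo$channel[k], "_", chrom) else as.character(geo$channel[k])
        out_cols[[lab]] <- x / s
      }
    }
    data[[r$participant]] <- do.call(cbind, out_cols)
  }
  group_dataset(data, fs = fs, channel_ids = colnames(data[[1]]))
}
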