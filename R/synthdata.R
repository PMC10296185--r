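#' Configuration of the synthetic group generator
#'
#' Describes a simulated naturalistic group experiment: `n_participants`
#' recordings of correlated-noise channels, with an optional stimulus-locked
#' response shared across participants. Defaults mirror a typical pediatric
#' prefrontal montage: 19 participants, 20 long + 8 short channels, 7.81 Hz,
#' 2100 frames (about 4.5 min). Noise is AR(1) in time (coefficient
#' `ar_coefficient`) with equicorrelated innovations across channels
#' (`spatial_rho`) and unit stationary variance, so `effect_size` is the
#' shared response amplitude in noise-SD units.
#'
#' @param n_participants number of simulated participants (default 19).
#' @param n_long_channels long (cortical) channels (default 20).
#' @param n_short_channels short (superficial) channels (default 8).
#' @param n_frames recording length in frames (default 2100).
#' @param fs sampling rate in Hz (default 7.81).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)` (default 0.95).
#' @param spatial_rho pairwise cross-channel noise correlation in `[0, 1)`
#'   (default 0.3).
#' @param event_onsets stimulus onsets in seconds (may be empty).
#' @param event_duration event length in seconds (default 10).
#' @param responsive_channels indices (or ids) of long channels that carry
#'   the shared response.
#' @param effect_size response amplitude in noise-SD units (default 0: pure
#'   null).
#' @param gain_jitter SD of the per-participant multiplicative response gain
#'   (default 0.1): responses are shared but not identical.
#' @param superficial_amplitude amplitude of a per-participant superficial
#'   confound added to all long channels and emitted as the short channels
#'   (default 0).
#' @param seed RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 19L, n_long_channels = 20L,
                              n_short_channels = 8L, n_frames = 2100L,
                              fs = 7.81, ar_coefficient = 0.95,
                              spatial_rho = 0.3, event_onsets = numeric(0),
                              event_duration = 10,
                              responsive_channels = integer(0),
                              effect_size = 0, gain_jitter = 0.1,
                              superficial_amplitude = 0, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_long_channels = as.integer(n_long_channels),
              n_short_channels = as.integer(n_short_channels),
              n_frames = as.integer(n_frames), fs = as.numeric(fs),
              ar_coefficient = as.numeric(ar_coefficient),
              spatial_rho = as.numeric(spatial_rho),
              event_onsets = as.numeric(event_onsets),
              event_duration = as.numeric(event_duration),
              responsive_channels = responsive_channels,
              effect_size = as.numeric(effect_size),
              gain_jitter = as.numeric(gain_jitter),
              superficial_amplitude = as.numeric(superficial_amplitude),
              seed = as.integer(seed))
  with(cfg, {
    if (n_participants < 3L) stop("need >= 3 participants.", call. = FALSE)
    if (n_long_channels < 1L || n_frames < 8L || fs <= 0)
      stop("invalid channel/frame/fs configuration.", call. = FALSE)
    if (ar_coefficient < 0 || ar_coefficient >= 1 ||
        spatial_rho < 0 || spatial_rho >= 1)
      stop("`ar_coefficient` and `spatial_rho` must lie in [0, 1).",
           call. = FALSE)
    if (length(event_onsets) &&
        any(event_onsets < 0 | event_onsets >= n_frames / fs))
      stop("event onsets must fall inside [0, ", round(n_frames / fs, 2),
           ") seconds.", call. = FALSE)
  })
  rc <- cfg$responsive_channels
  if (is.character(rc)) rc <- match(rc, paste0("ch", seq_len(cfg$n_long_channels)))
  rc <- as.integer(rc)
  if (length(rc) && (anyNA(rc) || any(rc < 1L | rc > cfg$n_long_channels)))
    stop("`responsive_channels` must be a subset of the long channels.",
         call. = FALSE)
  cfg$responsive_channels <- rc
  structure(cfg, class = "simulation_config")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Impulse response of the vascular system to a brief neural event: a gamma
#' peak near 5 s minus a 1/6-amplitude undershoot gamma near 15 s, sampled at
#' `fs` over `[0, duration]` seconds and normalised to peak 1. `kernel[1]`
#' (t = 0) is 0 (causal response).
#'
#' @param fs sampling rate in Hz.
#' @param duration kernel support in seconds (default 30; nothing beyond is
#'   generated).
#' @return numeric kernel vector.
#' @export
canonical_hrf <- function(fs, duration = 30) {
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive.",
                                       call. = FALSE)
  t <- seq(0, duration, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Run `expr` under a private RNG stream; global RNG state is untouched.
.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# AR(1) noise matrix (T x C) with equicorrelated innovations, stationary
# variance 1 per channel.
.correlated_ar_noise <- function(t_len, n_ch, phi, rho) {
  R <- matrix(rho, n_ch, n_ch); diag(R) <- 1
  L <- chol(R)
  innov <- matrix(stats::rnorm(t_len * n_ch), t_len, n_ch) %*% L
  x0 <- drop(matrix(stats::rnorm(n_ch), 1, n_ch) %*% L)  # stationary start
  if (phi == 0) return(innov)
  innov <- innov * sqrt(1 - phi^2)
  x <- vapply(seq_len(n_ch), function(c)
    as.numeric(stats::filter(innov[, c], phi, method = "recursive",
                             init = x0[c] )),
    numeric(t_len))
  x
}

# Shared stimulus-locked component: boxcar convolved with the canonical HRF,
# normalised to peak 1 (0 if no events).
.shared_response <- function(cfg) {
  stim <- numeric(cfg$n_frames)
  for (on in cfg$event_onsets) {
    i0 <- floor(on * cfg$fs) + 1L
    i1 <- min(cfg$n_frames, floor((on + cfg$event_duration) * cfg$fs))
    stim[seq.int(i0, max(i0, i1))] <- 1
  }
  if (!any(stim > 0)) return(numeric(cfg$n_frames))
  kern <- canonical_hrf(cfg$fs)
  conv <- stats::convolve(stim, rev(kern), type = "open")[seq_len(cfg$n_frames)]
  if (max(conv) > 0) conv / max(conv) else conv
}

#' Simulate a multi-participant hemodynamic dataset with known ground truth
#'
#' Per participant, channel noise is AR(1) with cross-channel equicorrelation
#' and unit stationary variance; if events are configured, a shared
#' HRF-convolved boxcar (peak 1) scaled by
#' `effect_size * (1 + gain_jitter * z_p)` enters the responsive channels,
#' and the idiosyncratic noise there is simultaneously damped by
#' `1 / sqrt(1 + (effect_size * s(t))^2)` (stimulus-evoked variability
#' quenching). The damping is what creates *momentary intersubject
#' similarity*: Euclidean distances between participants are invariant to
#' any purely additive common signal, so response frames can only become
#' more similar across participants if the between-participant spread
#' itself shrinks there. An optional per-participant superficial confound
#' (AR(1), coefficient 0.98) is added to every long channel and emitted as
#' the short channels. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `group` (a [group_dataset()] of the long channels),
#'   `truth` (list: `response_frames` 0-based frames where the noiseless
#'   shared component is at least half its peak, `responsive_channels`,
#'   `clean_signals` `T x C` matrix), and `shorts` (per participant `T x S`
#'   matrices of superficial series; NULL when `n_short_channels` is 0).
#' @export
simulate_group <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  shared <- .shared_response(cfg)
  has_effect <- cfg$effect_size > 0 && any(shared > 0)

  .with_seed(cfg$seed, {
    data <- vector("list", cfg$n_participants)
    shorts <- if (cfg$n_short_channels > 0) vector("list", cfg$n_participants)
    confounds <- if (cfg$superficial_amplitude > 0)
      vector("list", cfg$n_participants)
    for (p in seq_len(cfg$n_participants)) {
      x <- .correlated_ar_noise(cfg$n_frames, cfg$n_long_channels,
                                cfg$ar_coefficient, cfg$spatial_rho)
      if (has_effect) {
        gain <- cfg$effect_size * (1 + cfg$gain_jitter * stats::rnorm(1))
        # Stimulus-evoked variability quenching: where the shared response is
        # strong, it partially *replaces* idiosyncratic fluctuations instead
        # of riding on top of them. Purely additive common signal would leave
        # every between-participant distance unchanged (Euclidean distances
        # are translation invariant), so moments of intersubject similarity
        # must come from a momentary reduction of the idiosyncratic spread.
        quench <- 1 / sqrt(1 + (cfg$effect_size * shared)^2)
        x[, cfg$responsive_channels] <-
          x[, cfg$responsive_channels] * quench + shared * gain
      }
      if (cfg$superficial_amplitude > 0) {
        conf <- .correlated_ar_noise(cfg$n_frames, 1L, 0.98, 0) *
          cfg$superficial_amplitude
        confounds[[p]] <- as.numeric(conf)
        x <- x + as.numeric(conf)
        if (cfg$n_short_channels > 0)
          shorts[[p]] <- vapply(seq_len(cfg$n_short_channels), function(s)
            as.numeric(conf) + 0.2 * stats::rnorm(cfg$n_frames),
            numeric(cfg$n_frames))
      } else if (cfg$n_short_channels > 0) {
        shorts[[p]] <- matrix(stats::rnorm(cfg$n_frames *
                                             cfg$n_short_channels) * 0.2,
                              cfg$n_frames, cfg$n_short_channels)
      }
      colnames(x) <- paste0("ch", seq_len(cfg$n_long_channels))
      data[[p]] <- x
    }
    names(data) <- sprintf("sub%02d", seq_len(cfg$n_participants))

    clean <- matrix(0, cfg$n_frames, cfg$n_long_channels,
                    dimnames = list(NULL,
                                    paste0("ch",
                                           seq_len(cfg$n_long_channels))))
    if (has_effect)
      clean[, cfg$responsive_channels] <- shared * cfg$effect_size
    response_frames <- if (has_effect)
      which(shared >= 0.5 * max(shared)) - 1L else integer(0)

    list(group = group_dataset(data, fs = cfg$fs),
         truth = list(response_frames = response_frames,
                      responsive_channels = if (length(cfg$responsive_channels))
                        paste0("ch", cfg$responsive_channels) else character(0),
                      clean_signals = clean),
         shorts = shorts, confounds = confounds)
  })
}

#' Simulate raw dual-wavelength intensities (forward optical model)
#'
#' Converts the dynamics of [simulate_group()] to detected light intensities
#' by the forward modified Beer-Lambert model around a unit baseline:
#' `I = 10^(-dOD)` with
#' `dOD_l = sep * dpf_l * (e_l,HbO dHbO + e_l,HbR dHbR)`. Long-channel
#' `dHbO` is the simulated series scaled to 1 uM per noise-SD, with
#' `dHbR = -0.25 dHbO` (typical anticorrelation); short channels carry only
#' the superficial series. Long separation 3 cm, short 0.8 cm.
#'
#' @param config a [simulation_config()].
#' @param hbo_scale_mM concentration per simulated noise-SD unit (default
#'   1e-3 mM = 1 uM).
#' @return list with `recordings` (list of [raw_recording()]), plus the
#'   `group`, `truth` and `confounds` of the underlying simulation (the
#'   injected concentration dynamics, for recovery checks).
#' @export
simulate_raw <- function(config, hbo_scale_mM = 1e-3) {
  sim <- simulate_group(config)
  cfg <- config
  ext <- preprocess_config()$extinction
  dpf <- c(6, 6)
  n_short <- cfg$n_short_channels
  geo <- data.frame(
    channel = c(paste0("ch", seq_len(cfg$n_long_channels)),
                if (n_short) paste0("sh", seq_len(n_short))),
    separation_cm = c(rep(3.0, cfg$n_long_channels), rep(0.8, n_short)),
    role = c(rep("long", cfg$n_long_channels), rep("short", n_short)),
    stringsAsFactors = FALSE)

  forward <- function(hbo, sep) {
    hbr <- -0.25 * hbo
    od1 <- sep * dpf[1] * (ext[1, 1] * hbo + ext[1, 2] * hbr)
    od2 <- sep * dpf[2] * (ext[2, 1] * hbo + ext[2, 2] * hbr)
    cbind(10^(-od1), 10^(-od2))
  }

  recs <- lapply(seq_along(sim$group$data), function(p) {
    long_hbo <- sim$group$data[[p]] * hbo_scale_mM
    cols <- lapply(seq_len(cfg$n_long_channels), function(k)
      forward(long_hbo[, k], 3.0))
    if (n_short) {
      short_hbo <- sim$shorts[[p]] * hbo_scale_mM
      cols <- c(cols, lapply(seq_len(n_short), function(s)
        forward(short_hbo[, s], 0.8)))
    }
    intens <- do.call(cbind, cols)
    if (any(intens <= 0))
      stop("forward model produced nonpositive intensity; reduce ",
           "`hbo_scale_mM` or the simulated amplitudes.", call. = FALSE)
    raw_recording(intens, geo, fs = cfg$fs,
                  participant = sim$group$participants[p])
  })
  list(recordings = recs, group = sim$group, truth = sim$truth,
       confounds = sim$confounds)
}
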