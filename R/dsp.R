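# Signal-processing primitives: Butterworth band-pass realised as second-order
# sections run forward-backward (zero phase), and a periodized orthogonal
# Daubechies-4 discrete wavelet transform. Implemented here because the
# analysis needs exactly these two primitives and no more; both are verified
# against analytic gains and perfect-reconstruction identities in the tests.

# --- Butterworth band-pass, second-order sections ---------------------------

# Design an order-`order` Butterworth band-pass as a list of biquads.
# Bilinear transform with prewarping; analog prototype poles on the unit
# circle, band-pass transform s -> (s^2 + W0^2)/(Bw s), zeros at z = +/-1.
# SOS form keeps the narrow-band design (0.01-0.08 Hz at ~8 Hz sampling)
# numerically stable where a single 6th-order polynomial would not be.
.butter_bandpass_sos <- function(low, high, fs, order = 3L) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2 (got ", low, "-", high,
         " Hz at fs = ", fs, " Hz).", call. = FALSE)
  w1 <- tan(pi * low / fs)
  w2 <- tan(pi * high / fs)
  w0sq <- w1 * w2
  bw <- w2 - w1

  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles
  # band-pass transform: each prototype pole spawns two analog poles
  disc <- sqrt((bw * p_proto)^2 - 4 * w0sq + 0i)
  s_poles <- c((bw * p_proto + disc) / 2, (bw * p_proto - disc) / 2)
  z_poles <- (1 + s_poles) / (1 - s_poles)   # bilinear

  # pair poles into real-coefficient biquads: conjugate pairs first,
  # leftover (numerically real) poles paired among themselves
  tol <- 1e-8
  is_real <- abs(Im(z_poles)) < tol * pmax(1, abs(Re(z_poles)))
  cplx <- z_poles[!is_real & Im(z_poles) > 0]
  reals <- sort(Re(z_poles[is_real]))
  sos <- list()
  for (p in cplx)
    sos[[length(sos) + 1L]] <- list(b = c(1, 0, -1),
                                    a = c(1, -2 * Re(p), Mod(p)^2))
  if (length(reals) %% 2L != 0L)
    stop("internal error: unpaired real pole in band-pass design.")
  for (i in seq_len(length(reals) / 2)) {
    r1 <- reals[2 * i - 1]; r2 <- reals[2 * i]
    sos[[length(sos) + 1L]] <- list(b = c(1, 0, -1),
                                    a = c(1, -(r1 + r2), r1 * r2))
  }

  # unit gain at the (warped) centre frequency, spread across sections
  z0 <- exp(1i * 2 * atan(sqrt(w0sq)))
  resp <- vapply(sos, function(s)
    Mod(sum(s$b * z0^(0:-2)) / sum(s$a * z0^(0:-2))), numeric(1))
  gain_per_sec <- (1 / prod(resp))^(1 / length(sos))
  for (i in seq_along(sos)) sos[[i]]$b <- sos[[i]]$b * gain_per_sec
  sos
}

# One biquad pass assuming x[t] = x_init, y[t] = y_init for t <= 0.
# MA part by convolution, AR part through the C code in stats::filter.
.iir2 <- function(b, a, x, x_init = 0) {
  y_init <- x_init * sum(b) / sum(a)
  u <- stats::filter(c(x_init, x_init, x), b, method = "convolution",
                     sides = 1)[-(1:2)]
  as.numeric(stats::filter(u, -a[2:3], method = "recursive",
                           init = rep(y_init, 2)))
}

# Zero-phase filtering: odd-reflection padding, forward pass through all
# sections, then backward. Steady-state initial conditions make a constant
# input map exactly to its steady-state output (0 for a band-pass).
.filtfilt_sos <- function(sos, x) {
  n <- length(x)
  if (n < 4L) stop("series too short to filter.", call. = FALSE)
  pad <- min(n - 1L, 3L * 3L * length(sos) + 1L)
  ext <- c(2 * x[1] - x[seq(pad + 1L, 2L)], x,
           2 * x[n] - x[seq(n - 1L, n - pad)])
  for (s in sos) ext <- .iir2(s$b, s$a, ext, x_init = ext[1])
  ext <- rev(ext)
  for (s in sos) ext <- .iir2(s$b, s$a, ext, x_init = ext[1])
  rev(ext)[seq.int(pad + 1L, pad + n)]
}

# --- Periodized Daubechies-4 DWT --------------------------------------------
# 8-tap Daubechies filter with 4 vanishing moments: its highpass response
# decays like omega^4 at low frequency, so clipping fine-scale coefficients
# leaks almost nothing into the slow hemodynamic band.

.db4_h <- c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728)
.db4_g <- rev(.db4_h) * (-1)^(seq_along(.db4_h) - 1)  # QMF partner

# Pyramid decomposition to depth J; length(x) must be divisible by 2^J.
.dwt_periodic <- function(x, J) {
  stopifnot(length(x) %% 2^J == 0)
  taps <- length(.db4_h)
  details <- vector("list", J)
  a <- x
  for (j in seq_len(J)) {
    L <- length(a)
    idx <- (outer(2L * (seq_len(L / 2) - 1L), seq_len(taps) - 1L, "+") %%
              L) + 1L
    A <- matrix(a[idx], ncol = taps)
    details[[j]] <- drop(A %*% .db4_g)
    a <- drop(A %*% .db4_h)
  }
  list(approx = a, details = details)
}

# Exact inverse (adjoint of the orthogonal analysis operator).
.idwt_periodic <- function(dec) {
  taps <- length(.db4_h)
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    d <- dec$details[[j]]
    L <- 2L * length(a)
    x <- numeric(L)
    base <- 2L * (seq_along(a) - 1L)
    for (m in seq_len(taps) - 1L) {
      n_idx <- (base + m) %% L + 1L
      x[n_idx] <- x[n_idx] + a * .db4_h[m + 1] + d * .db4_g[m + 1]
    }
    a <- x
  }
  a
}
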