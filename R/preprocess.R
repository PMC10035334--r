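#' Band-pass filter specification
#'
#' Describes the linear-phase FIR band-pass used before each detector. The
#' base order follows the transition-width heuristic `ceiling(3 * fs / lo_hz)`
#' rounded up to even, then doubled, so the realised filter is a sharp
#' linear-phase design whose group delay is compensated exactly.
#'
#' @param lo_hz,hi_hz Passband edges in Hz (`0 < lo < hi < fs/2`).
#' @param base_order FIR order before doubling; `NULL` selects the heuristic
#'   above.
#' @param zero_phase Compensate the group delay so the net delay is zero.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(lo_hz, hi_hz, base_order = NULL, zero_phase = TRUE) {
  if (!(lo_hz > 0 && lo_hz < hi_hz)) {
    stop("filter band edges must satisfy 0 < lo_hz < hi_hz", call. = FALSE)
  }
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz, base_order = base_order,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Downsample a recording
#'
#' Anti-alias filtered rational-rate resampling. Only downsampling (or the
#' identity) is supported; the ratio `fs / target_fs` must be rational.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz (`<= rec$fs`).
#' @return The resampled [eeg_recording()].
#' @export
#' @examples
#' rec <- eeg_recording(rnorm(8192), fs = 1024)
#' resample_recording(rec, 512)
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) {
    stop("upsampling not supported (target_fs ", target_fs, " > fs ",
         rec$fs, ")", call. = FALSE)
  }
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  frac <- rational_ratio(target_fs, rec$fs)
  p <- frac[1]; q <- frac[2]
  # zero-stuff by p, zero-phase anti-alias FIR at the upsampled rate, then
  # take every q-th sample; the zero-phase kernel keeps timing exact
  x <- rec$samples
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, n * p, by = p)] <- x * p
  order <- 2L * ceiling(15 * max(p, q))
  h <- signal::fir1(order, 0.9 / q)
  y_up <- fir_zero_phase(up, h)
  y <- y_up[seq(1, n * p, by = q)]
  eeg_recording(y, fs = target_fs, subject_id = rec$subject_id,
                channel = rec$channel, t0 = rec$t0)
}

# Small continued-fraction rationalisation of a/b.
rational_ratio <- function(a, b, tol = 1e-9) {
  x <- a / b
  for (q in 1:10000) {
    p <- x * q
    if (abs(p - round(p)) < tol * q) return(c(round(p), q))
  }
  stop("fs ratio ", b, "/", a, " is not rational within tolerance",
       call. = FALSE)
}

#' Re-reference a channel to the bilateral-mastoid mean
#'
#' Subtracts the mean of the two mastoid channels from the analysis channel:
#' `out = rec - (m1 + m2) / 2`.
#'
#' @param rec Analysis channel ([eeg_recording()]).
#' @param m1,m2 Mastoid channels with the same `fs` and length as `rec`.
#' @return The re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, m1, m2) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(m1, "eeg_recording"), inherits(m2, "eeg_recording"))
  same <- function(x) length(x$samples) == length(rec$samples) &&
    isTRUE(all.equal(x$fs, rec$fs))
  if (!same(m1) || !same(m2)) {
    stop("mastoid channels must match the analysis channel in fs and length",
         call. = FALSE)
  }
  out <- rec$samples - (m1$samples + m2$samples) / 2
  eeg_recording(out, fs = rec$fs, subject_id = rec$subject_id,
                channel = rec$channel, t0 = rec$t0)
}

# Design the (doubled-order) linear-phase FIR band-pass taps for a spec.
design_fir <- function(spec, fs) {
  if (spec$hi_hz >= fs / 2) {
    stop("filter band edge ", spec$hi_hz, " Hz is at or above Nyquist (",
         fs / 2, " Hz)", call. = FALSE)
  }
  base <- spec$base_order %||% {
    o <- ceiling(3 * fs / spec$lo_hz)
    o + (o %% 2)  # even
  }
  order <- 2L * as.integer(base)
  # fir1 corners sit at the -6 dB points, so push them half a transition
  # width outwards: the realised passband then covers [lo, hi] at ~unit
  # gain rather than attenuating tones at the stated band edges
  tw_half <- 1.65 * fs / (order + 1)
  lo <- max(spec$lo_hz - tw_half, 0.05 * spec$lo_hz)
  hi <- min(spec$hi_hz + tw_half, 0.999 * fs / 2)
  signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a linear-phase FIR band-pass whose group delay is compensated, so
#' an in-band burst is not shifted in time. Edges are handled by reflecting
#' half a kernel length of signal at each end before filtering, which keeps
#' the output the same length as the input and avoids spurious onset/offset
#' transients.
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()], or a numeric pair of band edges in Hz.
#' @return The filtered [eeg_recording()].
#' @export
#' @examples
#' rec <- eeg_recording(rnorm(2048), fs = 512)
#' bandpass(rec, c(11, 16))
bandpass <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.numeric(spec) && length(spec) == 2L) {
    spec <- filter_spec(spec[1], spec[2])
  }
  h <- design_fir(spec, rec$fs)
  y <- fir_zero_phase(rec$samples, h)
  eeg_recording(y, fs = rec$fs, subject_id = rec$subject_id,
                channel = rec$channel, t0 = rec$t0)
}

# Convolve with a linear-phase kernel, compensating the (L-1)/2 group delay
# and reflect-padding the edges. Kernel length must be odd (even FIR order).
fir_zero_phase <- function(x, h) {
  half <- (length(h) - 1L) %/% 2L
  xp <- reflect_pad(x, half)
  y <- conv_full(xp, h)
  # full conv of length n + 2*half with kernel L = 2*half + 1 gives
  # n + 4*half samples; the delay-compensated same-length slice starts at
  # 2*half + 1 relative to the padded signal's full convolution.
  y[(2L * half + 1L):(2L * half + length(x))]
}

reflect_pad <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k >= n) {
    # short signal relative to kernel: reflect repeatedly
    left <- rev(rep_len(rev(x[-1]), k))
    right <- rep_len(rev(x)[-1], k)
    return(c(left, x, right))
  }
  c(rev(x[2:(k + 1L)]), x, rev(x[(n - k):(n - 1L)]))
}

# FFT-based full (linear) convolution of a real signal with a real or
# complex kernel.
conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, rep(0 + 0i, nfft - length(h))))
  y <- stats::fft(X * H, inverse = TRUE) / nfft
  if (is.complex(h)) y[seq_len(n)] else Re(y[seq_len(n)])
}
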