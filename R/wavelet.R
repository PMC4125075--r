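# db4 wavelet primitives: filters, cascade-discretized psi, multilevel DWT
# with symmetric extension, and universal-threshold soft shrinkage.

# Orthonormal Daubechies-4 (8-tap) reconstruction lowpass filter; sums to sqrt(2).
.db4_lo <- c( 0.2303778133088965,  0.7148465705529157,  0.6308807679298589,
             -0.0279837694168599, -0.1870348117190931,  0.0308413818355607,
              0.0328830116668852, -0.0105974017850690)

# Quadrature-mirror highpass: g_k = (-1)^k h_{L-1-k}.
.qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

.db4_hi <- .qmf(.db4_lo)

# Center frequency of db4 (cycles per unit of the wavelet's argument): the
# dominant Fourier frequency of the discretized psi, used to map a dilation
# scale to a period. Computed once from the cascade approximation (~0.699;
# the coarse nominal value is 5/7).
.fc_env <- new.env(parent = emptyenv())

.db4_fc <- function() {
  if (is.null(.fc_env$fc)) {
    level <- 10
    wf <- db4_wavefun(level)
    pad <- 2^17
    sp <- Mod(stats::fft(c(wf$psi, numeric(pad - length(wf$psi)))))^2
    half <- seq_len(pad %/% 2)
    freqs <- (half - 1) / pad * 2^level
    .fc_env$fc <- freqs[which.max(sp[half])]
  }
  .fc_env$fc
}

.upsample2 <- function(x) {
  out <- numeric(2 * length(x))
  out[seq(1, length(out), by = 2)] <- x
  out
}

.conv_full <- function(x, y) stats::convolve(x, rev(y), type = "open")

#' Discretized db4 wavelet function
#'
#' Approximates the continuous db4 mother wavelet \eqn{\psi(x)} on a dyadic
#' grid by the cascade algorithm: the highpass filter is refined
#' `level - 1` times through upsampling and convolution with the lowpass
#' filter. The support of db4's \eqn{\psi} is \eqn{[0, 7]}.
#'
#' @param level refinement depth; the grid spacing is `2^-level`. At the
#'   default 8 the approximation error is far below any use here.
#' @return list with `x` (grid over the support) and `psi` (values).
#' @keywords internal
db4_wavefun <- function(level = 8) {
  stopifnot(level >= 2)
  p <- .db4_hi
  for (i in seq_len(level - 1)) {
    u <- p
    up <- numeric(2 * length(u) - 1)
    up[seq(1, length(up), by = 2)] <- u
    p <- .conv_full(up, .db4_lo)
  }
  psi <- p * 2^(level / 2)
  list(x = seq_along(psi) / 2^level, psi = psi)
}

# Half-point symmetric extension index for position k into 1..n.
.sym_idx <- function(k, n) {
  k <- (k - 1) %% (2 * n)
  ifelse(k < n, k + 1, 2 * n - k)
}

# One analysis step: symmetric extension, filter, dyadic downsample.
.dwt_step <- function(x, filt) {
  L <- length(filt)
  n <- length(x)
  idx <- .sym_idx((1 - (L - 1)):(n + L - 1), n)
  full <- .conv_full(x[idx], filt)
  valid <- full[L:(n + 2 * (L - 1))]
  valid[seq(2, length(valid), by = 2)]
}

# One synthesis step; out_len is the length of the signal this level came from.
.idwt_step <- function(cA, cD, out_len) {
  L <- length(.db4_lo)
  ra <- .conv_full(.upsample2(cA), .db4_lo)
  rd <- .conv_full(.upsample2(cD), .db4_hi)
  s <- ra + rd
  s[(L - 1):(L - 2 + out_len)]
}

#' Multilevel db4 wavelet decomposition
#'
#' Discrete wavelet transform with half-point symmetric boundary extension,
#' the dialect used by common `wden`-style denoisers.
#'
#' @param x numeric signal, length >= 8, finite.
#' @param n_levels decomposition depth; default `floor(log2(n)) - 2`,
#'   clamped to at least 1.
#' @return list with `approx` (coarsest approximation coefficients),
#'   `details` (list of detail coefficient vectors, coarsest first) and
#'   `lengths` (per-level input lengths, needed for reconstruction).
#' @keywords internal
dwt_db4 <- function(x, n_levels = NULL) {
  n <- length(x)
  stopifnot(n >= 8, all(is.finite(x)))
  if (is.null(n_levels)) n_levels <- max(1L, floor(log2(n)) - 2L)
  a <- x
  details <- vector("list", n_levels)
  lengths <- integer(n_levels)
  for (j in seq_len(n_levels)) {
    lengths[j] <- length(a)
    d <- .dwt_step(a, rev(.db4_hi))
    a <- .dwt_step(a, rev(.db4_lo))
    details[[j]] <- d
  }
  list(approx = a, details = rev(details), lengths = rev(lengths))
}

#' Multilevel db4 reconstruction
#' @param dec a decomposition from [dwt_db4()].
#' @return numeric signal of the original length.
#' @keywords internal
idwt_db4 <- function(dec) {
  a <- dec$approx
  for (j in seq_along(dec$details)) {
    a <- .idwt_step(a, dec$details[[j]], dec$lengths[j])
  }
  a
}

#' Wavelet denoising with the universal soft threshold
#'
#' Denoises a 1-D signal by multilevel db4 decomposition and soft
#' thresholding of all detail coefficients at the universal threshold
#' \eqn{\sigma \sqrt{2 \log N}}. The noise scale \eqn{\sigma} is estimated
#' once from the finest-level detail coefficients as
#' \eqn{\mathrm{MAD}/0.6745} and applied unchanged at every level
#' ("no rescaling").
#'
#' @param x numeric signal, length >= 8, all finite.
#' @param n_levels decomposition depth; default `floor(log2(n)) - 2`.
#' @return denoised signal, same length as `x`.
#' @examples
#' t <- seq(0, 10, length.out = 128)
#' y <- sin(t) + rnorm(128, sd = 0.1)
#' d <- denoise_curve(y)
#' @export
denoise_curve <- function(x, n_levels = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("denoise_curve: input must be finite numeric")
  if (length(x) < 8) stop("denoise_curve: need at least 8 samples")
  dec <- dwt_db4(x, n_levels)
  finest <- dec$details[[length(dec$details)]]
  sigma <- stats::median(abs(finest)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  dec$details <- lapply(dec$details, soft)
  idwt_db4(dec)
}
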