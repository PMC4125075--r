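# Time-period coefficient maps (scaleograms) and signature features.

# Cache the discretized mother wavelet once per session.
.wave_env <- new.env(parent = emptyenv())

.get_psi <- function(level = 10) {
  key <- paste0("psi", level)
  if (is.null(.wave_env[[key]])) .wave_env[[key]] <- db4_wavefun(level)
  .wave_env[[key]]
}

#' Continuous-style db4 wavelet transform
#'
#' Convolves a uniformly sampled signal with a discretized db4 mother
#' wavelet at a grid of dilations, returning the matrix of absolute
#' coefficients over (period, time) — the scaleogram used as a phenotypic
#' signature. The mother wavelet is discretized by the cascade algorithm
#' and each kernel is centred on the wavelet's magnitude peak, so an
#' isolated feature at time `t0` responds maximally in the column nearest
#' `t0` at every period. Boundaries are zero-padded; cells whose kernel
#' overhangs the record are retained but flagged in the `boundary` matrix.
#'
#' @param signal a [growth_rate_series()], or a numeric vector with `dt`.
#' @param periods increasing grid of periods in hours; default 64
#'   log-spaced periods from `4 * dt` to the record duration.
#' @param dt sampling interval in hours (ignored when `signal` is a
#'   `growth_rate_series`).
#' @param n_periods size of the default period grid.
#' @return object of class `wavelet_signature`: list with `periods`,
#'   `times`, `coef` (periods x times, absolute values), `boundary`
#'   (logical, same shape) and the source labels.
#' @export
wavelet_transform <- function(signal, periods = NULL, dt = NULL,
                              n_periods = 64) {
  if (inherits(signal, "growth_rate_series")) {
    x <- signal$mu
    dt <- .dt_of(signal$times)
    times <- signal$times
    strain <- signal$strain; condition <- signal$condition
  } else {
    x <- as.numeric(signal)
    if (is.null(dt)) stop("wavelet_transform: dt required for bare vectors")
    times <- dt * (seq_along(x) - 1)
    strain <- "unknown"; condition <- "unknown"
  }
  n <- length(x)
  if (n < 16) stop("wavelet_transform: need at least 16 samples")
  if (any(!is.finite(x))) stop("wavelet_transform: non-finite signal")
  duration <- dt * (n - 1)
  if (is.null(periods))
    periods <- exp(seq(log(4 * dt), log(duration), length.out = n_periods))
  if (any(periods < 2 * dt - 1e-12) || any(periods > duration + 1e-12))
    stop("wavelet_transform: periods must lie in [2*dt, duration]")
  periods <- sort(periods)

  wf <- .get_psi()
  xm <- wf$x[which.max(abs(wf$psi))]     # magnitude peak of psi, for centring
  support <- max(wf$x)                   # 7 for db4
  coef <- matrix(0, nrow = length(periods), ncol = n)
  boundary <- matrix(FALSE, nrow = length(periods), ncol = n)
  for (i in seq_along(periods)) {
    a <- .db4_fc() * periods[i] / dt            # dilation in samples
    m <- max(2L, ceiling(support * a) + 1L)
    pos <- (seq_len(m) - 1) / a
    # L1 normalization: equal-amplitude sinusoids give equal-magnitude
    # ridges across scales, so the ridge sits at the labeled period.
    kern <- stats::approx(wf$x, wf$psi, xout = pos, yleft = 0,
                          yright = 0)$y / a
    j0 <- max(1L, min(m, round(xm * a) + 1L))
    full <- .conv_full(x, rev(kern))
    row <- full[(m - j0) + seq_len(n)]
    coef[i, ] <- abs(row)
    b <- seq_len(n)
    boundary[i, ] <- (b - (j0 - 1) < 1) | (b + (m - j0) > n)
  }
  structure(list(periods = periods, times = times, coef = coef,
                 boundary = boundary, strain = strain, condition = condition),
            class = "wavelet_signature")
}

#' @export
print.wavelet_signature <- function(x, ...) {
  cat(sprintf("<wavelet_signature> %s / %s: %d periods (%.2f-%.2f h) x %d times\n",
              x$strain, x$condition, length(x$periods), min(x$periods),
              max(x$periods), length(x$times)))
  invisible(x)
}

#' Signature feature vector at one period
#'
#' Extracts the row of absolute wavelet coefficients at the given period —
#' the per-strain fingerprint clustered downstream. A period between grid
#' points is snapped to the nearest row with a warning.
#'
#' @param sig a [wavelet_transform()] result.
#' @param period period in hours.
#' @return numeric vector of length `length(sig$times)`.
#' @export
signature_vector <- function(sig, period) {
  stopifnot(inherits(sig, "wavelet_signature"))
  i <- which.min(abs(sig$periods - period))
  if (abs(sig$periods[i] - period) > 1e-9 * max(period, 1))
    warning(sprintf("signature_vector: period %.4g snapped to grid point %.4g",
                    period, sig$periods[i]))
  sig$coef[i, ]
}

#' Two-feature wavelet summary of an expression profile
#'
#' Reduces a temporal profile to the (time, period) pair at which the
#' summed wavelet coefficients peak: `C_total_f[p] = sum_t coef[p, t]`
#' and `C_total_t[t] = sum_p coef[p, t]`; the features are the argmax of
#' each, ties broken toward the smaller period and earlier time.
#'
#' @param profile numeric vector (uniformly sampled) or
#'   `growth_rate_series`.
#' @param dt sampling interval in hours for bare vectors.
#' @param periods optional period grid, as in [wavelet_transform()].
#' @return list of class `feature_pair`: `t_star`, `p_star` (hours),
#'   `c_total_f`, `c_total_t` (the profiles) and `degenerate` (all-zero
#'   input flag).
#' @export
expression_features <- function(profile, dt = NULL, periods = NULL) {
  sig <- if (inherits(profile, "wavelet_signature")) profile
         else wavelet_transform(profile, periods = periods, dt = dt)
  ctf <- rowSums(sig$coef)
  ctt <- colSums(sig$coef)
  degenerate <- all(sig$coef == 0)
  structure(list(p_star = sig$periods[which.max(ctf)],
                 t_star = sig$times[which.max(ctt)],
                 c_total_f = ctf, c_total_t = ctt,
                 degenerate = degenerate),
            class = "feature_pair")
}

#' Concatenate growth-rate series across conditions (multiplexing)
#'
#' Joins one strain's series measured under several perturbation
#' conditions, in a fixed condition order, into a single longer series so
#' that condition-specific responses all contribute to one signature.
#'
#' @param series_list ordered list of [growth_rate_series()] (or numeric
#'   vectors) sharing one sampling interval.
#' @return a single `growth_rate_series` on a fresh uniform grid (numeric
#'   input gives a numeric vector).
#' @export
multiplex <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  if (is.numeric(series_list[[1]])) {
    return(unlist(series_list, use.names = FALSE))
  }
  dts <- vapply(series_list, function(s) .dt_of(s$times), numeric(1))
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("multiplex: all series must share one sampling interval")
  mu <- unlist(lapply(series_list, `[[`, "mu"), use.names = FALSE)
  s1 <- series_list[[1]]
  growth_rate_series(dts[1] * (seq_along(mu) - 1), mu, strain = s1$strain,
                     condition = "multiplex", well = s1$well)
}

#' Two-feature matrix for a multi-condition expression dataset
#'
#' Applies [expression_features()] to every promoter profile under every
#' condition and concatenates the per-condition (time, period) pairs, one
#' row per promoter: with 6 conditions the result is a 12-dimensional
#' feature vector per promoter.
#'
#' @param profiles list over conditions of promoters x time matrices
#'   (as from [make_expression_dataset()]).
#' @param dt sampling interval in hours.
#' @return numeric matrix, promoters x (2 * conditions), columns
#'   `t1, p1, t2, p2, ...`.
#' @export
expression_feature_matrix <- function(profiles, dt) {
  stopifnot(length(profiles) >= 1)
  n_prom <- nrow(profiles[[1]])
  out <- NULL
  for (cd in seq_along(profiles)) {
    fp <- t(vapply(seq_len(n_prom), function(i) {
      f <- expression_features(profiles[[cd]][i, ], dt = dt)
      c(f$t_star, f$p_star)
    }, numeric(2)))
    colnames(fp) <- paste0(c("t", "p"), cd)
    out <- if (is.null(out)) fp else cbind(out, fp)
  }
  rownames(out) <- rownames(profiles[[1]])
  out
}
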