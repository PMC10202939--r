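#' Spectra matrix container
#'
#' Holds a set of 1D spectra on a shared chemical-shift axis together with
#' their preprocessing state and, once normalised, the per-sample dilution
#' factors recovered by probabilistic quotient normalisation.
#'
#' @param ppm_axis Numeric chemical-shift grid (length p).
#' @param X Numeric matrix, samples x points.
#' @param state One of `"raw"`, `"aligned"`, `"normalized"`, `"scaled"`.
#' @param dilution_factors Optional per-sample quotient medians.
#'
#' @return A `spectra_matrix` object.
#' @export
spectra_matrix <- function(ppm_axis, X,
                           state = c("raw", "aligned", "normalized", "scaled"),
                           dilution_factors = NULL) {
  state <- match.arg(state)
  X <- as.matrix(X)
  if (length(ppm_axis) != ncol(X)) {
    abort("`ppm_axis` length must equal ncol(X).")
  }
  structure(list(ppm_axis = as.numeric(ppm_axis), X = X, state = state,
                 dilution_factors = dilution_factors),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d points, state = %s\n",
              nrow(x$X), ncol(x$X), x$state))
  invisible(x)
}

as_spectra_matrix <- function(x) {
  if (inherits(x, "spectra_matrix")) return(x)
  if (inherits(x, "spectrum_set")) return(x$spectra)
  if (is.matrix(x)) return(spectra_matrix(seq_len(ncol(x)), x))
  abort("expected a spectra_matrix, spectrum_set or matrix.")
}

# Integer lag in [-max_shift, max_shift] maximising the cross-correlation of
# `seg` against `ref`, computed in the frequency domain. A positive returned
# lag means `seg` is `ref` delayed by that many points.
fft_best_lag <- function(ref, seg, max_shift) {
  n <- length(ref)
  L <- stats::nextn(n + max_shift, 2)
  fr <- fft(c(ref - mean(ref), rep(0, L - n)))
  fs <- fft(c(seg - mean(seg), rep(0, L - n)))
  cc <- Re(fft(fs * Conj(fr), inverse = TRUE)) / L
  # circular index k+1 holds lag k (mod L)
  lags <- c(0:max_shift, -(max_shift:1))
  vals <- cc[c(1:(max_shift + 1), L - (max_shift:1) + 1)]
  lags[which.max(vals)]
}

#' Segment-wise FFT-based peak alignment
#'
#' Aligns each spectrum to a reference by splitting it into fixed-length
#' segments and, per segment, applying the integer point shift (within
#' `max_shift`) that maximises the frequency-domain cross-correlation with
#' the reference segment. Shifted-in points are padded with the segment's
#' boundary value, so segment count and matrix shape never change.
#'
#' @param x A [spectra_matrix()], `spectrum_set` or samples-by-points matrix.
#' @param reference `"mean"` (mean spectrum, the default) or `"index"` to
#'   align against row `ref_index`.
#' @param segment_points Points per segment (>= 8; default 64).
#' @param max_shift Maximum allowed shift, points (< `segment_points / 2`;
#'   default 20).
#' @param ref_index Row used when `reference = "index"`.
#'
#' @return A `spectra_matrix` in state `"aligned"`, with the applied
#'   per-sample, per-segment shifts in attribute `"applied_shifts"`.
#' @export
pafft_align <- function(x, reference = c("mean", "index"),
                        segment_points = 64L, max_shift = 20L,
                        ref_index = 1L) {
  reference <- match.arg(reference)
  sm <- as_spectra_matrix(x)
  X <- sm$X
  p <- ncol(X)
  segment_points <- as.integer(segment_points)
  if (segment_points < 8L) abort("`segment_points` must be >= 8.")
  if (p < segment_points) {
    abort("spectrum shorter than one segment.")
  }
  if (max_shift >= segment_points / 2) {
    abort("`max_shift` must be < segment_points / 2.")
  }
  ref <- if (reference == "mean") colMeans(X) else X[ref_index, ]
  n_segments <- ceiling(p / segment_points)
  out <- X
  applied <- matrix(0L, nrow(X), n_segments)
  for (s in seq_len(nrow(X))) {
    if (reference == "index" && s == ref_index) next
    for (g in seq_len(n_segments)) {
      i0 <- (g - 1L) * segment_points + 1L
      i1 <- min(g * segment_points, p)
      seg <- X[s, i0:i1]
      m <- min(max_shift, floor((i1 - i0 + 1) / 2) - 1L)
      if (m < 1L) next
      # a flat segment (no signal in it, or in the reference) carries no
      # alignment information
      if (sd(seg) < 1e-12 || sd(ref[i0:i1]) < 1e-12) next
      lag <- fft_best_lag(ref[i0:i1], seg, m)
      applied[s, g] <- -lag
      out[s, i0:i1] <- shift_pad(seg, -lag)
    }
  }
  res <- spectra_matrix(sm$ppm_axis, out, state = "aligned",
                        dilution_factors = sm$dilution_factors)
  attr(res, "applied_shifts") <- applied
  res
}

#' Probabilistic quotient normalisation
#'
#' Corrects per-sample dilution: quotients of each spectrum against a
#' reference (the point-wise median spectrum by default) are formed over a
#' support set of clearly non-baseline points, the per-sample dilution
#' factor is the median quotient, and each spectrum is divided by its
#' factor.
#'
#' @param x A [spectra_matrix()], `spectrum_set` or samples-by-points matrix.
#' @param reference `"median"` (median spectrum) or a numeric reference
#'   spectrum of matching length.
#' @param support_factor Support points are those where the reference
#'   exceeds `support_factor` times its median level (default 5), which
#'   excludes baseline noise from the quotient pool.
#'
#' @return A `spectra_matrix` in state `"normalized"` with recovered
#'   `dilution_factors`.
#' @export
pqn_normalize <- function(x, reference = "median", support_factor = 5) {
  sm <- as_spectra_matrix(x)
  X <- sm$X
  if (any(rowSums(abs(X)) == 0)) abort("all-zero sample spectrum.")
  ref <- if (is.numeric(reference)) {
    if (length(reference) != ncol(X)) abort("reference length mismatch.")
    reference
  } else {
    apply(X, 2, median)
  }
  floor_level <- median(ref[ref > 0])
  support <- which(ref > support_factor * floor_level)
  if (length(support) < 5L) {
    support <- which(ref >= quantile(ref, 0.9))
  }
  factors <- vapply(seq_len(nrow(X)), function(s) {
    median(X[s, support] / ref[support])
  }, numeric(1))
  if (any(!is.finite(factors) | factors <= 0)) {
    abort("degenerate dilution factor; check the reference support.")
  }
  spectra_matrix(sm$ppm_axis, X / factors, state = "normalized",
                 dilution_factors = factors)
}

#' Pareto scaling
#'
#' Mean-centres each spectral variable (column) and divides by the square
#' root of its standard deviation (n - 1 denominator), damping the dominance
#' of high-intensity peaks while amplifying low-intensity signal relative to
#' unit-variance scaling. Columns with zero variance are set to zero. The
#' scaled column variance equals the original column standard deviation.
#'
#' @param x A [spectra_matrix()], `spectrum_set` or samples-by-points matrix
#'   with at least 2 samples.
#'
#' @return A `spectra_matrix` in state `"scaled"`.
#' @export
pareto_scale <- function(x) {
  sm <- as_spectra_matrix(x)
  X <- sm$X
  if (nrow(X) < 2L) abort("pareto scaling needs >= 2 samples.")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  Xc <- sweep(X, 2, mu)
  nz <- s > 0
  Xc[, nz] <- sweep(Xc[, nz, drop = FALSE], 2, sqrt(s[nz]), "/")
  Xc[, !nz] <- 0
  spectra_matrix(sm$ppm_axis, Xc, state = "scaled",
                 dilution_factors = sm$dilution_factors)
}

#' Peak area by trapezoidal integration
#'
#' Integrates each spectrum over a chemical-shift window; peak area is
#' proportional to the number of contributing nuclei and serves as relative
#' quantification.
#'
#' @param x A [spectra_matrix()], `spectrum_set` or samples-by-points matrix.
#' @param ppm_window Length-2 window (ppm), any order; must intersect the
#'   axis in >= 2 points.
#'
#' @return Tibble with `sample` and `area`.
#' @export
peak_area <- function(x, ppm_window) {
  sm <- as_spectra_matrix(x)
  w <- sort(as.numeric(ppm_window))
  idx <- which(sm$ppm_axis >= w[1] & sm$ppm_axis <= w[2])
  if (length(idx) < 2L) abort("`ppm_window` spans fewer than 2 axis points.")
  pp <- sm$ppm_axis[idx]
  areas <- vapply(seq_len(nrow(sm$X)), function(s) {
    y <- sm$X[s, idx]
    abs(sum(diff(pp) * (head(y, -1) + tail(y, -1)) / 2))
  }, numeric(1))
  tibble(sample = seq_len(nrow(sm$X)), area = areas)
}
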