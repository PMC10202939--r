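#' Synthetic 1D NMR spectrum set with known shifts and dilutions
#'
#' Each sample is a sum of Lorentzian peaks on a common chemical-shift grid,
#' segment-wise shifted by a known number of grid points, scaled by a known
#' dilution factor, with optional additive noise clipped at zero. The
#' injected shifts and dilutions are stored so alignment and normalisation
#' can be validated against ground truth.
#'
#' @param n_samples Number of spectra.
#' @param peaks Tibble/data frame with columns `ppm` (centre), `height` and
#'   `width` (half-width at half-maximum, ppm). Default: a five-peak mixture
#'   spread over the grid.
#' @param truth_shifts Integer point shifts per sample and segment: a matrix
#'   `[n_samples x n_segments]`, or a vector (one shift per sample applied to
#'   all segments), or a scalar. Positive shift moves the segment content to
#'   higher index.
#' @param truth_dilutions Positive per-sample scale factors (scalar or
#'   vector).
#' @param noise_sd Additive Gaussian noise sd relative to max peak height 1.
#' @param seed Integer seed.
#' @param n_points Points on the ppm grid.
#' @param ppm_range Chemical-shift range (ppm), increasing.
#' @param segment_points Points per alignment segment (defines the segment
#'   grid used for `truth_shifts`).
#'
#' @return A `spectrum_set`: a [spectra_matrix()] plus `truth_shifts`
#'   (matrix) and `truth_dilutions`.
#' @export
generate_spectra <- function(n_samples = 4,
                             peaks = NULL,
                             truth_shifts = 0L,
                             truth_dilutions = 1,
                             noise_sd = 0,
                             seed = 1L,
                             n_points = 1024L,
                             ppm_range = c(0, 10),
                             segment_points = 64L) {
  if (any(truth_dilutions <= 0)) abort("`truth_dilutions` must be > 0.")
  if (is.null(peaks)) {
    peaks <- tibble(ppm = c(1.3, 2.5, 3.7, 5.5, 8.1),
                    height = c(1, 0.6, 0.9, 0.4, 0.7),
                    width = c(0.04, 0.05, 0.03, 0.06, 0.04))
  }
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  base <- rowSums(vapply(seq_len(nrow(peaks)), function(i) {
    peaks$height[i] / (1 + ((ppm - peaks$ppm[i]) / peaks$width[i])^2)
  }, numeric(n_points)))
  n_segments <- ceiling(n_points / segment_points)
  shifts <- truth_shifts
  if (is.matrix(shifts)) {
    if (!all(dim(shifts) == c(n_samples, n_segments))) {
      abort("`truth_shifts` matrix must be n_samples x n_segments.")
    }
  } else {
    shifts <- matrix(rep_len(as.integer(shifts), n_samples),
                     n_samples, n_segments)
  }
  dil <- rep_len(truth_dilutions, n_samples)
  X <- matrix(0, n_samples, n_points)
  withr::with_seed(as.integer(seed), {
    for (s in seq_len(n_samples)) {
      spec <- base
      for (g in seq_len(n_segments)) {
        i0 <- (g - 1L) * segment_points + 1L
        i1 <- min(g * segment_points, n_points)
        spec[i0:i1] <- shift_pad(base[i0:i1], shifts[s, g])
      }
      spec <- dil[s] * spec
      if (noise_sd > 0) spec <- spec + rnorm(n_points, sd = noise_sd)
      spec[spec < 0] <- 0
      X[s, ] <- spec
    }
  })
  sm <- spectra_matrix(ppm, X, state = "raw")
  structure(list(spectra = sm, truth_shifts = shifts, truth_dilutions = dil),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples, %d points, dilutions [%s]\n",
              nrow(x$spectra$X), ncol(x$spectra$X),
              paste(signif(x$truth_dilutions, 3), collapse = ", ")))
  invisible(x)
}

# Shift a vector by `by` points, padding with the boundary value.
shift_pad <- function(v, by) {
  n <- length(v)
  by <- as.integer(by)
  if (by == 0L || abs(by) >= n) return(if (abs(by) >= n) v else v)
  if (by > 0) c(rep(v[1], by), v[seq_len(n - by)])
  else c(v[(1 - by):n], rep(v[n], -by))
}
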