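#' Histologic score from staining-intensity percentages
#'
#' Weighted sum of the light / moderate / strong staining percentages of a
#' detection or tissue core: `Hs = 1*(% light) + 2*(% moderate) +
#' 3*(% strong)`, ranging from 0 (no immunoreaction) to 300 (100% strong
#' staining). Vectorised over its arguments.
#'
#' @param pct_light,pct_moderate,pct_strong Percentages in `[0, 100]`;
#'   their sum must not exceed 100 (the remainder is unstained).
#'
#' @return Numeric Hs in `[0, 300]`.
#' @export
#'
#' @examples
#' histologic_score(0, 0, 100)   # 300
#' histologic_score(20, 30, 10)  # 110
histologic_score <- function(pct_light, pct_moderate, pct_strong) {
  p <- cbind(pct_light, pct_moderate, pct_strong)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    abort("staining percentages must lie in [0, 100].")
  }
  if (any(rowSums(p) > 100 + 1e-9)) {
    abort("staining percentages must sum to <= 100.")
  }
  as.numeric(p %*% c(1, 2, 3))
}

#' Amoeboid score
#'
#' Per-detection product of cell roundness (0-1) and the pMLC2 histologic
#' score (0-300): `As = roundness * Hs`, ranging from 0 (a fully elongated
#' cell with no Myosin II activity) to 300 (a fully rounded cell with
#' maximal cortical pMLC2). Vectorised.
#'
#' @param roundness Roundness in `[0, 1]`.
#' @param hs_pmlc2 pMLC2 histologic score in `[0, 300]`.
#'
#' @return Numeric As in `[0, 300]`.
#' @export
#'
#' @examples
#' amoeboid_score(1, 300)  # 300
#' amoeboid_score(0, 0)    # 0
amoeboid_score <- function(roundness, hs_pmlc2) {
  if (any(!is.finite(roundness)) || any(roundness < 0) || any(roundness > 1)) {
    abort("`roundness` must lie in [0, 1].")
  }
  if (any(!is.finite(hs_pmlc2)) || any(hs_pmlc2 < 0) || any(hs_pmlc2 > 300)) {
    abort("`hs_pmlc2` must lie in [0, 300].")
  }
  roundness * hs_pmlc2
}

#' Score a detection table
#'
#' Data-frame-first wrapper for tissue quantification: adds the histologic
#' score `Hs` from staining-class percentage columns and, when a `roundness`
#' column is present, the amoeboid score `As = roundness * Hs`.
#'
#' @param detections Data frame with columns `pct_light`, `pct_moderate`,
#'   `pct_strong`, and optionally `roundness` and a grouping column `roi`.
#'
#' @return The input as a tibble with `Hs` (and `As`) columns appended.
#' @export
score_detections <- function(detections) {
  d <- as_tibble(detections)
  need <- c("pct_light", "pct_moderate", "pct_strong")
  if (!all(need %in% names(d))) {
    abort("`detections` needs pct_light, pct_moderate and pct_strong columns.")
  }
  d <- mutate(d, Hs = histologic_score(.data$pct_light, .data$pct_moderate,
                                       .data$pct_strong))
  if ("roundness" %in% names(d)) {
    d <- mutate(d, As = amoeboid_score(.data$roundness, .data$Hs))
  }
  d
}

#' Per-ROI summary of amoeboid scores
#'
#' Each case is reported as the mean score over all detections in the region
#' of interest.
#'
#' @param detections Scored tibble (see [score_detections()]) with columns
#'   `roi` and `As`.
#'
#' @return Tibble with `roi`, `n_detections`, `mean_As`.
#' @export
summarise_roi <- function(detections) {
  d <- as_tibble(detections)
  if (!all(c("roi", "As") %in% names(d))) {
    abort("`detections` needs roi and As columns.")
  }
  d |>
    group_by(.data$roi) |>
    summarise(n_detections = n(), mean_As = mean(.data$As), .groups = "drop")
}

#' Roundness of a segmented region
#'
#' Shape-descriptor roundness `4 * area / (pi * major_axis^2)` with the
#' major axis from image second moments, clipped to `[0, 1]`. Values near 1
#' indicate rounded (amoeboid-like) morphology; values near 0 indicate
#' spindle-shaped cells.
#'
#' @param mask Logical or 0/1 matrix marking one region; area must be >= 5
#'   pixels.
#'
#' @return Roundness in `[0, 1]`.
#' @export
roundness <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1
  a <- sum(m)
  if (a < 5) abort("region too small (area < 5 px).")
  feat <- EBImage::computeFeatures.moment(m)
  major <- feat[1, "m.majoraxis"]
  if (!is.finite(major) || major <= 0) abort("degenerate region.")
  min(1, max(0, 4 * a / (pi * major^2)))
}

#' Stained area fraction within a cell
#'
#' Fraction of the cell mask covered by above-threshold stain (e.g. the area
#' occupied by pMLC2 staining relative to the cell area).
#'
#' @param cell_mask Logical/0-1 matrix marking the cell; must be nonempty.
#' @param stain_image Numeric matrix of stain intensity, same shape.
#' @param threshold `"otsu"` (computed within the mask) or a numeric cutoff.
#'
#' @return Fraction in `[0, 1]`.
#' @export
stain_fraction <- function(cell_mask, stain_image, threshold = "otsu") {
  m <- as.matrix(cell_mask) > 0
  if (!any(m)) abort("empty cell mask.")
  img <- as.matrix(stain_image)
  if (!all(dim(img) == dim(m))) abort("mask and stain image shapes differ.")
  thr <- if (is.numeric(threshold)) threshold else otsu_threshold(img[m])
  sum(img > thr & m) / sum(m)
}

# Otsu threshold of an intensity sample (maximises between-class variance
# over a 256-bin histogram).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Adhesion percentage
#'
#' Percentage of cells remaining attached to the collagen matrix after
#' washing: `100 * n_after / n_before`. Vectorised.
#'
#' @param n_before,n_after Cell counts before and after washing
#'   (`n_before > 0`).
#'
#' @return Percentage.
#' @export
adhesion_percent <- function(n_before, n_after) {
  if (any(n_before <= 0)) abort("`n_before` must be > 0.")
  if (any(n_after < 0)) abort("`n_after` must be >= 0.")
  100 * n_after / n_before
}

#' 3D invasion index
#'
#' Number of cells that invaded to 50 micrometres divided by the number of
#' cells at the bottom of the matrix. Vectorised.
#'
#' @param n_invading_50um Invading-cell count (>= 0).
#' @param n_bottom Bottom-of-well cell count (> 0).
#'
#' @return Invasion index (dimensionless).
#' @export
invasion_index <- function(n_invading_50um, n_bottom) {
  if (any(n_bottom <= 0)) abort("`n_bottom` must be > 0.")
  if (any(n_invading_50um < 0)) abort("`n_invading_50um` must be >= 0.")
  n_invading_50um / n_bottom
}

#' Pixel-by-pixel ratio image
#'
#' Ratiometric biosensor readout (e.g. ATP-bound 488 nm / ADP-bound 405 nm
#' excitation of PercevalHR): per-pixel `numerator / max(denominator,
#' floor)`. Pixels whose denominator falls below `floor` are flagged invalid
#' and excluded from summary statistics.
#'
#' @param numerator_image,denominator_image Numeric matrices of equal shape.
#' @param floor Positive denominator floor (default 1 intensity unit).
#'
#' @return A `ratio_image` object: `ratio` matrix, logical `valid` matrix,
#'   and `summary` tibble (mean/median over valid pixels).
#' @export
ratio_image <- function(numerator_image, denominator_image, floor = 1) {
  num <- as.matrix(numerator_image)
  den <- as.matrix(denominator_image)
  if (!all(dim(num) == dim(den))) abort("image shapes differ.")
  if (floor <= 0) abort("`floor` must be > 0.")
  valid <- den >= floor
  ratio <- num / pmax(den, floor)
  structure(
    list(ratio = ratio, valid = valid,
         summary = tibble(n_valid = sum(valid),
                          mean_ratio = mean(ratio[valid]),
                          median_ratio = median(ratio[valid]))),
    class = "ratio_image")
}

#' @export
print.ratio_image <- function(x, ...) {
  cat(sprintf("<ratio_image> %d x %d px, %d valid, mean ratio %.3g\n",
              nrow(x$ratio), ncol(x$ratio), x$summary$n_valid,
              x$summary$mean_ratio))
  invisible(x)
}
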