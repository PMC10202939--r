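#' Synthetic mitochondrial-stain phantom with known ground truth
#'
#' Emulates the two morphologies contrasted in amoeboid vs mesenchymal cells:
#' `"fragmented"` draws `n_objects` well-separated filled disks (punctate,
#' disconnected mitochondria); `"fused"` draws a single connected star of
#' `n_branches` thick arms radiating from one junction (a networked,
#' tubular morphology). Truth tables are populated from the drawing
#' primitives before rasterisation, so every downstream measurement can be
#' compared with a stored answer.
#'
#' @param mode `"fragmented"` or `"fused"`.
#' @param n_objects Number of disks in fragmented mode (>= 1).
#' @param seed Integer seed (generators are pure functions of their seed).
#' @param n_branches Number of arms in fused mode (default 3, a Y shape).
#' @param image_size Image side length in pixels.
#' @param disk_radius Range of disk radii, pixels (fragmented mode).
#' @param arm_length Range of arm lengths, pixels (fused mode).
#' @param thickness Half-thickness of fused arms, pixels.
#' @param intensity Foreground intensity (8-bit-like scale).
#' @param background Background intensity.
#' @param blur_sigma Gaussian blur applied to the rendered scene, pixels.
#' @param noise_sd Additive Gaussian noise sd (clipped at zero).
#'
#' @return A `mito_phantom` object: `image` (2D matrix), `mask` (ground-truth
#'   binary), `truth_objects` (tibble: object, area, perimeter, circularity),
#'   `truth_branches` (branch count for the synthetic cell) and `mode`.
#' @export
#'
#' @examples
#' ph <- generate_mito_phantom("fragmented", n_objects = 12, seed = 1)
#' nrow(ph$truth_objects)
generate_mito_phantom <- function(mode = c("fragmented", "fused"),
                                  n_objects = 12, seed = 1L,
                                  n_branches = 3,
                                  image_size = 256,
                                  disk_radius = c(4, 7),
                                  arm_length = c(40, 70),
                                  thickness = 2,
                                  intensity = 200, background = 10,
                                  blur_sigma = 0.8, noise_sd = 4) {
  mode <- match.arg(mode)
  if (mode == "fragmented" && n_objects < 1) abort("`n_objects` must be >= 1.")
  if (mode == "fused" && n_branches < 1) abort("`n_branches` must be >= 1.")
  n <- as.integer(image_size)
  gx <- matrix(rep(seq_len(n), times = n), n, n)
  gy <- matrix(rep(seq_len(n), each = n), n, n)
  withr::with_seed(as.integer(seed), {
    mask <- matrix(FALSE, n, n)
    if (mode == "fragmented") {
      centres <- matrix(NA_real_, n_objects, 2)
      radii <- numeric(n_objects)
      placed <- 0L
      guard <- 0L
      while (placed < n_objects && guard < 10000L) {
        guard <- guard + 1L
        r <- runif(1, disk_radius[1], disk_radius[2])
        c2 <- runif(2, r + 6, n - r - 6)
        if (placed > 0) {
          dmin <- min(sqrt(rowSums(sweep(centres[seq_len(placed), , drop = FALSE],
                                         2, c2)^2)) - radii[seq_len(placed)])
          if (dmin < r + 6) next
        }
        placed <- placed + 1L
        centres[placed, ] <- c2
        radii[placed] <- r
        mask <- mask | ((gx - c2[1])^2 + (gy - c2[2])^2 <= r^2)
      }
      if (placed < n_objects) {
        abort("could not place all disks without overlap; reduce n_objects.")
      }
      truth_branches <- n_objects  # each punctum skeletonises to one branch
    } else {
      centre <- c(n / 2, n / 2)
      angles <- seq(0, 2 * pi, length.out = n_branches + 1)[-(n_branches + 1)]
      angles <- angles + runif(1, 0, 2 * pi / max(n_branches, 1))
      for (a in angles) {
        len <- runif(1, arm_length[1], arm_length[2])
        tip <- centre + len * c(cos(a), sin(a))
        # thick segment: distance from pixel to segment <= thickness
        vx <- tip - centre
        tt <- pmin(pmax(((gx - centre[1]) * vx[1] + (gy - centre[2]) * vx[2]) /
                          sum(vx^2), 0), 1)
        px <- centre[1] + tt * vx[1]
        py <- centre[2] + tt * vx[2]
        mask <- mask | ((gx - px)^2 + (gy - py)^2 <= thickness^2)
      }
      truth_branches <- n_branches
    }
    img <- matrix(background, n, n)
    img[mask] <- intensity
    if (blur_sigma > 0) img <- gauss_blur2(img, blur_sigma)
    if (noise_sd > 0) img <- img + matrix(rnorm(n * n, sd = noise_sd), n, n)
    img[img < 0] <- 0
  })
  lab <- label8(mask)
  ids <- seq_len(max(lab))
  truth_objects <- tibble(
    object = ids,
    area = map_dbl(ids, ~ sum(lab == .x)),
    perimeter = map_dbl(ids, ~ mask_perimeter(lab == .x)),
  ) |>
    mutate(circularity = 4 * pi * .data$area / .data$perimeter^2)
  structure(
    list(image = img, mask = mask, truth_objects = truth_objects,
         truth_branches = truth_branches, mode = mode),
    class = "mito_phantom")
}

#' @export
print.mito_phantom <- function(x, ...) {
  cat(sprintf("<mito_phantom> mode = %s, %d truth objects, %d truth branches\n",
              x$mode, nrow(x$truth_objects), x$truth_branches))
  invisible(x)
}
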