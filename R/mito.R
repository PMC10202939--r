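#' Difference-of-Gaussian frequency decomposition
#'
#' Decomposes an image into frequency bands `band_k = G(sigma = r_k) -
#' G(sigma = r_{k+1})`, with radii defaulting to powers of two from 1 to 32.
#' This simultaneously smooths and background-subtracts: small radii carry
#' punctate structure, large radii carry tubule-scale ridges. The residual
#' `G(sigma = r_last)` is attached so the telescoping sum of all bands plus
#' the residual reconstructs the `G(sigma = r_1)`-blurred input.
#'
#' @param image Numeric matrix.
#' @param radii Strictly increasing Gaussian radii; at least two.
#'
#' @return List of band matrices (length `length(radii) - 1`) with the
#'   largest-scale blur in attribute `"residual"`.
#' @export
dog_decompose <- function(image, radii = c(1, 2, 4, 8, 16, 32)) {
  if (length(radii) < 2L) abort("need at least two radii.")
  if (any(diff(radii) <= 0)) abort("`radii` must be strictly increasing.")
  img <- as.matrix(image)
  blurs <- map(radii, ~ gauss_blur2(img, .x))
  bands <- map(seq_len(length(radii) - 1L),
               ~ blurs[[.x]] - blurs[[.x + 1L]])
  attr(bands, "residual") <- blurs[[length(radii)]]
  bands
}

#' Combine frequency bands into one frequency-encoded image
#'
#' Clips each band at zero and combines per pixel, by maximum (default,
#' preserving both fine puncta and tubule-scale ridges) or by sum.
#'
#' @param bands List of band matrices from [dog_decompose()].
#' @param method `"max"` or `"sum"`.
#'
#' @return Numeric matrix.
#' @export
frequency_encode <- function(bands, method = c("max", "sum")) {
  method <- match.arg(method)
  if (length(bands) < 1L) abort("need at least one band.")
  clipped <- map(bands, ~ pmax(.x, 0))
  out <- clipped[[1]]
  for (b in clipped[-1]) {
    out <- if (method == "max") pmax(out, b) else out + b
  }
  out
}

#' White top-hat enhancement
#'
#' Subtracts the morphological opening with a disk structuring element of
#' the given radius, keeping bright structures narrower than about twice the
#' radius and flattening broad uneven background.
#'
#' @param image Numeric matrix.
#' @param radius Disk radius in pixels (>= 1; default 4).
#'
#' @return Non-negative matrix of the same shape.
#' @export
tophat_enhance <- function(image, radius = 4) {
  if (radius < 1) abort("`radius` must be >= 1.")
  img <- as.matrix(image)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  opened <- gray_dilate(gray_erode(img, brush), brush)
  pmax(img - opened, 0)
}

# Grayscale erosion / dilation with a 0-1 structuring element and
# edge-replicated borders (a constant image is a fixed point, unlike
# zero-padded morphology).
gray_morph <- function(m, brush, op = c("erode", "dilate")) {
  op <- match.arg(op)
  r <- (dim(brush) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ridx <- pmin(pmax(seq_len(nr + 2L * r[1]) - r[1], 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + 2L * r[2]) - r[2], 1L), nc)
  pad <- m[ridx, cidx, drop = FALSE]
  out <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  off <- which(brush > 0, arr.ind = TRUE)
  for (o in seq_len(nrow(off))) {
    di <- off[o, 1] - 1L; dj <- off[o, 2] - 1L
    blk <- pad[seq_len(nr) + di, seq_len(nc) + dj, drop = FALSE]
    out <- if (op == "erode") pmin(out, blk) else pmax(out, blk)
  }
  out
}

gray_erode <- function(m, brush) gray_morph(m, brush, "erode")

gray_dilate <- function(m, brush) {
  # dilation uses the reflected structuring element; brushes here are
  # symmetric so reflection is a no-op, kept explicit for clarity
  gray_morph(m, brush[rev(seq_len(nrow(brush))), rev(seq_len(ncol(brush))),
                      drop = FALSE], "dilate")
}

# Separable Gaussian blur of a matrix with edge replication; kernel radius
# truncated to fit the image.
gauss_blur2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- min(ceiling(3 * sigma), nrow(m) - 1L, ncol(m) - 1L)
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  apply_sep(m, k, r)
}

# Perimeter of a binary mask: contour length of the Gaussian-smoothed mask
# at level 0.5 (sub-pixel, unbiased for convex blobs); falls back to the
# staircase contour of the raw mask for thin shapes that the smoothing
# erases.
mask_perimeter <- function(mask, sigma = 1) {
  m <- (as.matrix(mask) > 0) * 1
  # pad so boundary objects close their contour
  mp <- matrix(0, nrow(m) + 4, ncol(m) + 4)
  mp[3:(nrow(m) + 2), 3:(ncol(m) + 2)] <- m
  contour_len <- function(z) {
    cl <- grDevices::contourLines(x = seq_len(nrow(mp)),
                                  y = seq_len(ncol(mp)), z = z, levels = 0.5)
    sum(vapply(cl, function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2)),
               numeric(1)))
  }
  p <- if (sigma > 0) contour_len(gauss_blur2(mp, sigma)) else 0
  if (p < 2) p <- contour_len(mp)
  p
}

#' Segment objects and measure circularity
#'
#' Global threshold (Otsu by default) of an enhanced image, connected-
#' component labelling, removal of objects below `min_size` pixels, and
#' per-object circularity `4 * pi * area / perimeter^2` with a sub-pixel
#' contour perimeter. A rasterised disk scores close to 1; elongated
#' tubules score low.
#'
#' @param image Enhanced intensity matrix (see [tophat_enhance()]).
#' @param min_size Minimum object size in pixels (default 10; smaller
#'   objects are deleted).
#' @param threshold_method `"otsu"` or a numeric cutoff.
#'
#' @return A `mito_segmentation`: integer `labels` matrix and an `objects`
#'   tibble (`object`, `area`, `perimeter`, `circularity`). Zero objects
#'   (with a warning) if the foreground is empty.
#' @export
segment_circularity <- function(image, min_size = 10,
                                threshold_method = "otsu") {
  img <- as.matrix(image)
  thr <- if (is.numeric(threshold_method)) threshold_method
         else otsu_threshold(c(img))
  fg <- img > thr
  if (!any(fg)) {
    warn("empty foreground after thresholding; returning zero objects.")
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          objects = tibble(object = integer(),
                                           area = numeric(),
                                           perimeter = numeric(),
                                           circularity = numeric())),
                     class = "mito_segmentation"))
  }
  lab <- label8(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  relab <- matrix(0L, nrow(img), ncol(img))
  objects <- tibble(object = integer(), area = numeric(),
                    perimeter = numeric(), circularity = numeric())
  for (i in seq_along(keep)) {
    obj <- lab == keep[i]
    relab[obj] <- i
    a <- sum(obj)
    p <- mask_perimeter(obj)
    objects <- bind_rows(objects,
                         tibble(object = i, area = a, perimeter = p,
                                circularity = 4 * pi * a / p^2))
  }
  structure(list(labels = relab, objects = objects),
            class = "mito_segmentation")
}

#' @export
print.mito_segmentation <- function(x, ...) {
  cat(sprintf("<mito_segmentation> %d objects, median circularity %.3g\n",
              nrow(x$objects),
              if (nrow(x$objects)) median(x$objects$circularity) else NA))
  invisible(x)
}

#' Adaptive mean thresholding with physical block size
#'
#' Local-mean thresholding as used for mitochondrial network segmentation:
#' the image is rescaled to the 8-bit range, the block size is converted
#' from micrometres to the nearest odd pixel count (>= 3), and a pixel is
#' foreground iff its intensity exceeds the local block mean plus the
#' C-value offset on the 8-bit scale (`"above"`, the default: a flat image
#' yields empty foreground and only pixels standing clearly above their
#' neighbourhood survive). The alternative `"subtract"` convention
#' (foreground iff intensity exceeds the local mean minus C) is provided
#' for compatibility with tools that treat C as a subtractive offset, but
#' it admits every pixel of a flat region and is not useful on
#' background-dominated images.
#'
#' @param image Numeric matrix.
#' @param block_size Block edge in micrometres (default 2.25).
#' @param c_value Offset on the 8-bit scale (default 28).
#' @param pixel_size Micrometres per pixel.
#' @param convention `"above"` (default) or `"subtract"`.
#'
#' @return Logical matrix (foreground mask).
#' @export
adaptive_threshold <- function(image, block_size = 2.25, c_value = 28,
                               pixel_size = 0.1,
                               convention = c("above", "subtract")) {
  convention <- match.arg(convention)
  img <- as.matrix(image)
  block_px <- round(block_size / pixel_size)
  if (block_px %% 2 == 0) block_px <- block_px + 1
  if (block_px < 3) abort("block smaller than 3 px at this pixel size.")
  rng <- range(img)
  img8 <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) * 255 else img * 0
  local_mean <- box_mean(img8, block_px)
  if (convention == "above") img8 > local_mean + c_value
  else img8 > local_mean - c_value
}

# Local mean over a block_px x block_px window with edge replication,
# via separable running sums.
box_mean <- function(m, block_px) {
  r <- (block_px - 1L) / 2L
  k <- rep(1 / block_px, block_px)
  m1 <- apply_sep(m, k, r)
  m1
}

apply_sep <- function(m, k, r) {
  pad_rows <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), ,
                drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad_rows[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
  }
  pad_cols <- out[, c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r)),
                  drop = FALSE]
  out2 <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    out2 <- out2 + k[j] * pad_cols[, seq_len(ncol(m)) + (j - 1L),
                                   drop = FALSE]
  }
  out2
}

# Zhang-Suen thinning of a binary matrix to a 1-px skeleton.
skeletonize_2d <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1L
  # pad border with zeros
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  nr <- nrow(p); nc <- ncol(p)
  shift2 <- function(a, di, dj) {
    out <- matrix(0L, nr, nc)
    si <- seq_len(nr) + di; sj <- seq_len(nc) + dj
    ok_i <- si >= 1 & si <= nr; ok_j <- sj >= 1 & sj <= nc
    out[ok_i, ok_j] <- a[si[ok_i], sj[ok_j]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north
      P2 <- shift2(p, -1, 0); P3 <- shift2(p, -1, 1); P4 <- shift2(p, 0, 1)
      P5 <- shift2(p, 1, 1);  P6 <- shift2(p, 1, 0);  P7 <- shift2(p, 1, -1)
      P8 <- shift2(p, 0, -1); P9 <- shift2(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (pass == 1) {
        cond <- p == 1L & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- p == 1L & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] > 0
}

#' Count mitochondrial skeleton branches per cell
#'
#' Skeletonises the binary mitochondrial mask restricted to a cell, builds
#' the skeleton graph (junction pixels have >= 3 neighbours) and counts
#' branches as the connected segments between junctions/endpoints. Spur
#' segments shorter than `prune` pixels hanging off a junction are pruned as
#' rasterisation artefacts; isolated single-pixel components count as one
#' branch each. Punctate, fragmented mitochondria therefore yield one
#' branch per punctum, while a fused network yields arms per junction.
#'
#' @param binary Logical/0-1 matrix of mitochondrial foreground (e.g. from
#'   [adaptive_threshold()]).
#' @param cell_mask Optional logical matrix restricting the analysis to one
#'   cell; must be nonempty if supplied.
#' @param cell_id Identifier recorded in the output (default 1).
#' @param prune Minimum branch length in pixels (default 2).
#'
#' @return A one-row tibble of class `mito_branch_stats`: `cell_id`,
#'   `n_branches`, `n_junctions`, `total_skeleton_length` (px).
#' @export
count_branches <- function(binary, cell_mask = NULL, cell_id = 1L,
                           prune = 2L) {
  b <- as.matrix(binary) > 0
  if (!is.null(cell_mask)) {
    cm <- as.matrix(cell_mask) > 0
    if (!any(cm)) abort("empty cell mask.")
    b <- b & cm
  }
  if (!any(b)) {
    return(structure(tibble(cell_id = cell_id, n_branches = 0L,
                            n_junctions = 0L, total_skeleton_length = 0),
                     class = c("mito_branch_stats", class(tibble()))))
  }
  sk <- skeletonize_2d(b)
  # junctions by crossing number: >= 3 separate foreground runs around the
  # pixel (robust to diagonal staircases, which a plain neighbour count
  # misclassifies)
  junction <- sk & crossing_number(sk) >= 3
  # remove the full 3x3 junction cluster so arms meeting diagonally around a
  # junction pixel do not stay connected to each other
  junction_zone <- if (any(junction)) {
    EBImage::dilate(junction * 1, EBImage::makeBrush(3, "box")) > 0
  } else {
    junction
  }
  segments <- sk & !junction_zone
  seg_lab <- label8(segments)
  n_seg <- max(seg_lab)
  n_branches <- 0L
  skel_len <- sum(sk)
  if (n_seg > 0) {
    junction_dil <- if (any(junction)) {
      EBImage::dilate(junction * 1, EBImage::makeBrush(3, "box")) > 0
    } else {
      matrix(FALSE, nrow(junction), ncol(junction))
    }
    for (i in seq_len(n_seg)) {
      obj <- seg_lab == i
      size <- sum(obj)
      if (size >= prune) {
        n_branches <- n_branches + 1L
      } else if (!any(obj & junction_dil)) {
        n_branches <- n_branches + 1L  # isolated punctum
      }  # else: short spur off a junction -> pruned
    }
  }
  if (n_seg == 0 && any(junction)) n_branches <- 1L
  # components of the binary whose skeleton eroded away entirely are still
  # one punctum each
  comp <- label8(b)
  for (ci in seq_len(max(comp))) {
    if (!any(sk & comp == ci)) n_branches <- n_branches + 1L
  }
  structure(tibble(cell_id = cell_id, n_branches = n_branches,
                   n_junctions = sum(junction),
                   total_skeleton_length = skel_len),
            class = c("mito_branch_stats", class(tibble())))
}

# Crossing number: count of 0->1 transitions in the cyclic 8-neighbourhood,
# with 4-adjacent diagonal pairs merged into single runs.
crossing_number <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1L
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  ri <- 2:(nrow(m) + 1); cj <- 2:(ncol(m) + 1)
  P2 <- p[ri - 1, cj]; P3 <- p[ri - 1, cj + 1]; P4 <- p[ri, cj + 1]
  P5 <- p[ri + 1, cj + 1]; P6 <- p[ri + 1, cj]; P7 <- p[ri + 1, cj - 1]
  P8 <- p[ri, cj - 1]; P9 <- p[ri - 1, cj - 1]
  (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
    (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
    (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
}

# 8-connected labelling: 4-connected labels merged across diagonal contacts
# with union-find.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(as.matrix(mask) > 0)
  nmax <- max(lab)
  if (nmax <= 1) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(c(lab[-nr, -nc]), c(lab[-1, -1])),   # down-right diagonal
    cbind(c(lab[-nr, -1]), c(lab[-1, -nc]))    # down-left diagonal
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# 8-neighbour count of TRUE pixels.
neighbour_count <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1L
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  s <- matrix(0L, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    s <- s + p[2:(nrow(m) + 1) + di, 2:(ncol(m) + 1) + dj]
  }
  s
}
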