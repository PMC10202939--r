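#' Displacement grid constructor
#'
#' Tibble-first container for a tracked displacement field: one row per mesh
#' node with the node position (0-based voxel coordinates), the displacement
#' in micrometres, the correlation peak value and the untracked flag. Mesh
#' geometry travels in attributes so tensor operations can rebuild the
#' regular grid.
#'
#' @param nodes Tibble with columns `i, j, k` (1-based mesh indices),
#'   `x, y, z` (0-based voxel coordinates), `ux, uy, uz` (micrometres),
#'   `quality` (correlation peak in `[-1, 1]`) and `untracked` (logical).
#' @param mesh_dims Integer length-3, nodes per axis.
#' @param node_spacing Voxels between nodes per axis.
#' @param voxel_size Micrometres per voxel per axis.
#'
#' @return A `displacement_grid` tibble.
#' @export
displacement_grid <- function(nodes, mesh_dims, node_spacing, voxel_size) {
  nodes <- as_tibble(nodes)
  need <- c("i", "j", "k", "x", "y", "z", "ux", "uy", "uz", "quality",
            "untracked")
  if (!all(need %in% names(nodes))) {
    abort(paste("displacement grid needs columns:", paste(need, collapse = ", ")))
  }
  if (any(nodes$quality < -1 - 1e-9 | nodes$quality > 1 + 1e-9, na.rm = TRUE)) {
    abort("`quality` must lie in [-1, 1].")
  }
  structure(nodes,
            mesh_dims = as.integer(mesh_dims),
            node_spacing = as.numeric(rep_len(node_spacing, 3L)),
            voxel_size = as.numeric(rep_len(voxel_size, 3L)),
            class = c("displacement_grid", class(tibble())))
}

#' @export
print.displacement_grid <- function(x, ...) {
  md <- attr(x, "mesh_dims")
  cat(sprintf("<displacement_grid> %d x %d x %d nodes, %d untracked\n",
              md[1], md[2], md[3], sum(x$untracked)))
  NextMethod()
}

# Normalised cross-correlation of `win` against all placements inside
# `region` (both 3D arrays), via zero-padded FFTs. Returns the NCC array
# over valid shifts (dims = dim(region) - dim(win) + 1).
ncc3d <- function(win, region) {
  dw <- dim(win); dr <- dim(region)
  nw <- prod(dw)
  wz <- win - mean(win)
  wn <- sqrt(sum(wz^2))
  pad <- function(a) {
    out <- array(0, dr)
    out[seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3])] <- a
    out
  }
  fw <- Conj(fft(pad(wz)))
  fr <- fft(region)
  fr2 <- fft(region^2)
  f1 <- Conj(fft(pad(array(1, dw))))
  num <- Re(fft(fr * fw, inverse = TRUE)) / prod(dr)
  s1 <- Re(fft(fr * f1, inverse = TRUE)) / prod(dr)
  s2 <- Re(fft(fr2 * f1, inverse = TRUE)) / prod(dr)
  valid <- dr - dw + 1L
  idx <- function(a) a[seq_len(valid[1]), seq_len(valid[2]), seq_len(valid[3]),
                       drop = FALSE]
  num <- idx(num); s1 <- idx(s1); s2 <- idx(s2)
  denom <- wn * sqrt(pmax(s2 - s1^2 / nw, 0))
  out <- num / denom
  out[!is.finite(out) | denom < 1e-9 * wn] <- 0
  array(out, valid)
}

# Three-point Gaussian sub-voxel peak refinement along one axis.
subvoxel_offset <- function(cm, c0, cp) {
  eps <- 1e-12
  lcm <- log(max(cm, eps)); lc0 <- log(max(c0, eps)); lcp <- log(max(cp, eps))
  den <- 2 * (lcm + lcp - 2 * lc0)
  if (!is.finite(den) || den >= 0) return(0)
  off <- (lcm - lcp) / den
  max(-0.5, min(0.5, off))
}

#' Track 3D displacements between two frames by block-matching PIV
#'
#' Superimposes a regular mesh on the first frame and, for each node, finds
#' the shift of its interrogation window that maximises the normalised
#' cross-correlation with the second frame (frequency-domain matching),
#' refined to sub-voxel precision by a three-point Gaussian peak fit per
#' axis. Nodes whose correlation peak falls below `min_quality`, or whose
#' window has no intensity structure, are flagged untracked with zero
#' displacement. Displacements are reported in micrometres via the voxel
#' size.
#'
#' @param frame_a,frame_b [image_stack()] objects of identical shape and
#'   voxel size.
#' @param window Interrogation window, voxels per axis (default
#'   `c(32, 32, 8)`); must fit inside the frame.
#' @param search Maximum shift searched, voxels per axis (default
#'   `c(10, 10, 3)`).
#' @param node_spacing Mesh node spacing, voxels per axis (default
#'   `c(16, 16, 4)`).
#' @param min_quality Correlation-peak threshold below which a node is
#'   declared untracked (default 0.3).
#' @param plane Restrict the search to one image plane (`"xy"`, `"xz"` or
#'   `"yz"`): the out-of-plane search radius is set to zero, so only the two
#'   in-plane displacement components are measured. Default `"none"` (full
#'   3D search).
#'
#' @return A [displacement_grid()].
#' @export
track_displacements <- function(frame_a, frame_b,
                                window = c(32, 32, 8),
                                search = c(10, 10, 3),
                                node_spacing = c(16, 16, 4),
                                min_quality = 0.3,
                                plane = c("none", "xy", "xz", "yz")) {
  plane <- match.arg(plane)
  if (!inherits(frame_a, "image_stack") || !inherits(frame_b, "image_stack")) {
    abort("frames must be image_stack objects.")
  }
  d <- dim(frame_a$voxels)
  if (!all(d == dim(frame_b$voxels))) abort("frame shapes do not match.")
  if (!all(frame_a$voxel_size == frame_b$voxel_size)) {
    abort("frame voxel sizes do not match.")
  }
  window <- as.integer(rep_len(window, 3L))
  search <- as.integer(rep_len(search, 3L))
  node_spacing <- as.integer(rep_len(node_spacing, 3L))
  if (any(window > d)) abort("window larger than frame.")
  search_full <- search  # mesh placement uses the full search budget so all
  if (plane != "none") { # plane passes share one mesh
    out_axis <- switch(plane, xy = 3L, xz = 2L, yz = 1L)
    search[out_axis] <- 0L
  }
  half <- window %/% 2L
  # node centres (1-based), symmetric about the frame centre so that the
  # middle of the field of view always carries a node
  centres_axis <- function(ax) {
    lo <- half[ax] + search_full[ax] + 1L
    hi <- d[ax] - (window[ax] - half[ax]) - search_full[ax] + 1L
    if (hi < lo) abort("window + search exceed the frame extent.")
    mid <- floor(d[ax] / 2) + 1L
    below <- rev(seq(mid, lo, by = -node_spacing[ax]))
    above <- seq(mid, hi, by = node_spacing[ax])
    unique(c(below, above))
  }
  cx <- centres_axis(1); cy <- centres_axis(2); cz <- centres_axis(3)
  vs <- frame_a$voxel_size
  A <- frame_a$voxels; B <- frame_b$voxels
  rows <- vector("list", length(cx) * length(cy) * length(cz))
  r <- 0L
  for (kk in seq_along(cz)) for (jj in seq_along(cy)) for (ii in seq_along(cx)) {
    c0 <- c(cx[ii], cy[jj], cz[kk])
    w0 <- c0 - half
    win <- A[w0[1]:(w0[1] + window[1] - 1L),
             w0[2]:(w0[2] + window[2] - 1L),
             w0[3]:(w0[3] + window[3] - 1L), drop = FALSE]
    win <- array(win, window)
    u <- c(0, 0, 0); q <- 0; untracked <- TRUE
    if (sd(win) > 1e-12) {
      r0 <- w0 - search
      reg <- B[r0[1]:(w0[1] + window[1] + search[1] - 1L),
               r0[2]:(w0[2] + window[2] + search[2] - 1L),
               r0[3]:(w0[3] + window[3] + search[3] - 1L), drop = FALSE]
      reg <- array(reg, window + 2L * search)
      cc <- ncc3d(win, reg)
      pk <- arrayInd(which.max(cc), dim(cc))[1, ]
      q <- cc[pk[1], pk[2], pk[3]]
      if (is.finite(q) && q >= min_quality) {
        shift <- pk - 1L - search  # integer displacement, voxels
        sub <- c(0, 0, 0)
        for (ax in 1:3) {
          if (pk[ax] > 1 && pk[ax] < dim(cc)[ax]) {
            im <- pk; ip <- pk
            im[ax] <- im[ax] - 1L; ip[ax] <- ip[ax] + 1L
            sub[ax] <- subvoxel_offset(cc[im[1], im[2], im[3]], q,
                                       cc[ip[1], ip[2], ip[3]])
          }
        }
        u <- (shift + sub) * vs
        untracked <- FALSE
      }
    }
    r <- r + 1L
    rows[[r]] <- c(ii, jj, kk, c0 - 1L, u, q, untracked)
  }
  m <- do.call(rbind, rows)
  nodes <- tibble(
    i = as.integer(m[, 1]), j = as.integer(m[, 2]), k = as.integer(m[, 3]),
    x = m[, 4], y = m[, 5], z = m[, 6],
    ux = m[, 7], uy = m[, 8], uz = m[, 9],
    quality = pmin(pmax(m[, 10], -1), 1),
    untracked = m[, 11] > 0)
  g <- displacement_grid(nodes,
                         mesh_dims = c(length(cx), length(cy), length(cz)),
                         node_spacing = node_spacing, voxel_size = vs)
  attr(g, "plane") <- plane
  g
}

#' Fill untracked nodes by inverse-distance interpolation
#'
#' Replaces the displacement at each untracked node with the
#' inverse-distance-weighted average of its 9 nearest tracked neighbours
#' (Euclidean distance in voxel coordinates). Tracked nodes are unchanged;
#' the output has no untracked nodes remaining.
#'
#' @param grid A [displacement_grid()].
#' @param n_neighbours Number of tracked neighbours used (default 9).
#'
#' @return A [displacement_grid()] with all nodes tracked; filled nodes are
#'   marked in the logical column `filled`.
#' @export
fill_untracked <- function(grid, n_neighbours = 9L) {
  if (!inherits(grid, "displacement_grid")) {
    abort("`grid` must be a displacement_grid.")
  }
  tracked <- which(!grid$untracked)
  if (length(tracked) < n_neighbours) {
    abort(sprintf("need at least %d tracked nodes to interpolate.",
                  n_neighbours))
  }
  out <- grid
  out$filled <- FALSE
  todo <- which(grid$untracked)
  if (length(todo) == 0L) return(out)
  P <- cbind(grid$x, grid$y, grid$z)
  for (n0 in todo) {
    d2 <- (P[tracked, 1] - P[n0, 1])^2 + (P[tracked, 2] - P[n0, 2])^2 +
      (P[tracked, 3] - P[n0, 3])^2
    nb <- tracked[order(d2)[seq_len(n_neighbours)]]
    w <- 1 / sqrt(d2[order(d2)[seq_len(n_neighbours)]])
    w <- w / sum(w)
    out$ux[n0] <- sum(w * grid$ux[nb])
    out$uy[n0] <- sum(w * grid$uy[nb])
    out$uz[n0] <- sum(w * grid$uz[nb])
    out$untracked[n0] <- FALSE
    out$filled[n0] <- TRUE
  }
  out
}

#' Fuse plane-wise tracking passes into one 3D displacement field
#'
#' Combines the xy, xz and yz plane passes of [track_displacements()] into a
#' single 3-vector per node: each Cartesian component is the average of the
#' two plane passes that measure it (x from xy and xz, y from xy and yz,
#' z from xz and yz). Quality is the mean of the contributing passes; a node
#' is untracked only if untracked in every pass that measures one of its
#' components.
#'
#' @param xy_pass,xz_pass,yz_pass [displacement_grid()] objects from
#'   `track_displacements(..., plane = )` on the same mesh.
#'
#' @return A fused [displacement_grid()].
#' @export
reconstruct_3d <- function(xy_pass, xz_pass, yz_pass) {
  passes <- list(xy = xy_pass, xz = xz_pass, yz = yz_pass)
  md <- attr(xy_pass, "mesh_dims")
  for (p in passes) {
    if (!inherits(p, "displacement_grid")) {
      abort("all passes must be displacement_grid objects.")
    }
    if (!all(attr(p, "mesh_dims") == md) ||
        nrow(p) != nrow(xy_pass) ||
        any(p$x != xy_pass$x) || any(p$y != xy_pass$y) ||
        any(p$z != xy_pass$z)) {
      abort("plane passes do not share a common mesh.")
    }
  }
  avg2 <- function(a, b, ta, tb) {
    # average the passes that tracked the node; 0 if neither did
    wa <- as.numeric(ta); wb <- as.numeric(tb)
    tot <- wa + wb
    ifelse(tot > 0, (wa * a + wb * b) / pmax(tot, 1), 0)
  }
  t_xy <- !xy_pass$untracked; t_xz <- !xz_pass$untracked
  t_yz <- !yz_pass$untracked
  out <- xy_pass
  out$ux <- avg2(xy_pass$ux, xz_pass$ux, t_xy, t_xz)
  out$uy <- avg2(xy_pass$uy, yz_pass$uy, t_xy, t_yz)
  out$uz <- avg2(xz_pass$uz, yz_pass$uz, t_xz, t_yz)
  out$quality <- (xy_pass$quality + xz_pass$quality + yz_pass$quality) / 3
  out$untracked <- !(t_xy | t_xz | t_yz)
  attr(out, "plane") <- "fused"
  out
}
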