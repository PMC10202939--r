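# Shared fixtures, built in code at test time.

# Small fibre phantom pair: frame A and its warp under a known contraction.
make_tfm_pair <- function(grid = c(96, 96, 16), amplitude = 2, radius = 14,
                          noise_sd = 0, seed = 5) {
  params <- fibre_phantom_params(grid_shape = grid, voxel_size = c(1, 1, 1),
                                 n_fibres = 300, noise_sd = noise_sd,
                                 seed = seed)
  a <- generate_fibre_stack(params)
  centre <- (grid - 1) / 2
  fld <- make_contraction_field(centre, amplitude, radius,
                                grid_shape = grid, voxel_size = c(1, 1, 1))
  list(a = a, b = warp_stack(a, fld), field = fld, centre = centre)
}

# Ground-truth displacement (um) at the nodes of a displacement grid.
truth_at_nodes <- function(grid, field) {
  idx <- cbind(grid$x + 1, grid$y + 1, grid$z + 1)
  cbind(field$u[cbind(idx, 1L)], field$u[cbind(idx, 2L)],
        field$u[cbind(idx, 3L)])
}

rmse_voxels <- function(grid, field) {
  tr <- grid[!grid$untracked, ]
  tu <- truth_at_nodes(tr, field)
  sqrt(mean(rowSums((cbind(tr$ux, tr$uy, tr$uz) - tu)^2)))
}

# Hand-built displacement grid from a function u(x, y, z) -> c(ux, uy, uz),
# positions in voxels (0-based), displacements in um.
synthetic_grid <- function(fun, mesh = c(9, 9, 5), spacing = c(4, 4, 4),
                           voxel_size = c(1, 1, 1)) {
  nodes <- expand.grid(i = seq_len(mesh[1]), j = seq_len(mesh[2]),
                       k = seq_len(mesh[3]))
  pos <- cbind((nodes$i - 1) * spacing[1], (nodes$j - 1) * spacing[2],
               (nodes$k - 1) * spacing[3])
  u <- t(apply(pos, 1, function(p) fun(p[1], p[2], p[3])))
  displacement_grid(
    tibble::tibble(i = nodes$i, j = nodes$j, k = nodes$k,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   ux = u[, 1], uy = u[, 2], uz = u[, 3],
                   quality = 1, untracked = FALSE),
    mesh_dims = mesh, node_spacing = spacing, voxel_size = voxel_size)
}

# Rasterised ellipse mask (axes a, b half-lengths in px).
ellipse_mask <- function(a, b, pad = 6) {
  nx <- ceiling(2 * a) + 2 * pad
  ny <- ceiling(2 * b) + 2 * pad
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  gx <- matrix(rep(seq_len(nx), times = ny), nx, ny)
  gy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
}

disk_mask <- function(r, pad = 6) ellipse_mask(r, r, pad)
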