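test_that("identical frames track to zero displacement", {
  p <- fibre_phantom_params(grid_shape = c(48, 48, 16), n_fibres = 80,
                            noise_sd = 0, seed = 4)
  a <- generate_fibre_stack(p)
  g <- track_displacements(a, a, window = c(16, 16, 6), search = c(4, 4, 2),
                           node_spacing = c(8, 8, 3))
  tr <- g[!g$untracked, ]
  expect_gt(nrow(tr), 0)
  # sub-voxel peak interpolation carries a small bias; well under 0.15 voxel
  vs <- rep(c(0.5, 0.5, 1), each = nrow(tr))
  expect_true(all(abs(c(tr$ux, tr$uy, tr$uz)) / vs < 0.15))
  expect_true(all(tr$quality > 0.99))
})

test_that("rigid integer translations are recovered to sub-voxel accuracy", {
  p <- fibre_phantom_params(grid_shape = c(96, 96, 16), voxel_size = c(1, 1, 1),
                            n_fibres = 300, noise_sd = 0, seed = 3)
  a <- generate_fibre_stack(p)
  v <- a$voxels
  b <- array(0, dim(v))
  b[3:96, 4:96, 2:16] <- v[1:94, 1:93, 1:15]
  g <- track_displacements(a, image_stack(b), window = c(24, 24, 8),
                           search = c(5, 5, 2), node_spacing = c(12, 12, 3))
  tr <- g[!g$untracked, ]
  expect_lt(abs(median(tr$ux) - 2), 0.25)
  expect_lt(abs(median(tr$uy) - 3), 0.25)
  expect_lt(abs(median(tr$uz) - 1), 0.25)
})

test_that("a known contraction field is recovered below half a voxel RMSE", {
  pair <- make_tfm_pair(grid = c(96, 96, 16), amplitude = 2, radius = 14,
                        noise_sd = 0, seed = 5)
  g <- track_displacements(pair$a, pair$b, window = c(20, 20, 6),
                           search = c(4, 4, 2), node_spacing = c(8, 8, 2))
  expect_lt(rmse_voxels(g, pair$field), 0.5)
})

test_that("tracking validates its inputs", {
  p <- fibre_phantom_params(grid_shape = c(32, 32, 16), seed = 1)
  a <- generate_fibre_stack(p)
  b <- generate_fibre_stack(fibre_phantom_params(grid_shape = c(48, 48, 16),
                                                 seed = 1))
  expect_error(track_displacements(a, b), "shape")
  expect_error(track_displacements(a, a, window = c(64, 64, 8)), "window")
})

test_that("untracked nodes are filled from their 9 nearest tracked neighbours", {
  lin <- function(x, y, z) c(0.1 * x + 0.02 * y, -0.05 * y, 0.01 * z)
  g <- synthetic_grid(lin, mesh = c(7, 7, 3), spacing = c(4, 4, 4))

  # no untracked nodes: unchanged
  f0 <- fill_untracked(g)
  expect_equal(f0$ux, g$ux)
  expect_false(any(f0$filled))

  # constant field: filled value is the constant
  gc <- synthetic_grid(function(x, y, z) c(1.5, -2, 0.5), mesh = c(5, 5, 3))
  gc$untracked[30] <- TRUE
  gc$ux[30] <- 0; gc$uy[30] <- 0; gc$uz[30] <- 0
  fc <- fill_untracked(gc)
  expect_equal(fc$ux[30], 1.5, tolerance = 1e-12)
  expect_equal(fc$uy[30], -2, tolerance = 1e-12)
  expect_false(any(fc$untracked))

  # linear field: filled value equals an explicit neighbour enumeration
  gl <- g
  n0 <- 60
  gl$untracked[n0] <- TRUE
  gl$ux[n0] <- 0; gl$uy[n0] <- 0; gl$uz[n0] <- 0
  fl <- fill_untracked(gl)
  P <- cbind(gl$x, gl$y, gl$z)
  tracked <- which(!gl$untracked)
  d <- sqrt(rowSums(sweep(P[tracked, ], 2, P[n0, ])^2))
  nb <- tracked[order(d)[1:9]]
  w <- 1 / sort(d)[1:9]; w <- w / sum(w)
  expect_equal(fl$ux[n0], sum(w * gl$ux[nb]), tolerance = 1e-12)
  expect_equal(fl$uy[n0], sum(w * gl$uy[nb]), tolerance = 1e-12)
  expect_equal(fl$uz[n0], sum(w * gl$uz[nb]), tolerance = 1e-12)

  # too few tracked nodes
  tiny <- synthetic_grid(lin, mesh = c(2, 2, 2), spacing = c(4, 4, 4))
  tiny$untracked[1:5] <- TRUE
  expect_error(fill_untracked(tiny), "tracked nodes")
})

test_that("plane-wise passes fuse into the single-pass 3D answer", {
  p <- fibre_phantom_params(grid_shape = c(64, 64, 16), voxel_size = c(1, 1, 1),
                            n_fibres = 200, noise_sd = 0, seed = 6)
  a <- generate_fibre_stack(p)
  v <- a$voxels
  b <- array(0, dim(v))
  b[3:64, 4:64, 2:16] <- v[1:62, 1:61, 1:15]
  bst <- image_stack(b)
  args <- list(window = c(16, 16, 6), search = c(4, 4, 2),
               node_spacing = c(8, 8, 3))
  g_xy <- do.call(track_displacements, c(list(a, bst, plane = "xy"), args))
  g_xz <- do.call(track_displacements, c(list(a, bst, plane = "xz"), args))
  g_yz <- do.call(track_displacements, c(list(a, bst, plane = "yz"), args))
  fused <- reconstruct_3d(g_xy, g_xz, g_yz)
  tr <- fused[!fused$untracked, ]
  expect_lt(abs(median(tr$ux) - 2), 0.25)
  expect_lt(abs(median(tr$uy) - 3), 0.25)
  expect_lt(abs(median(tr$uz) - 1), 0.25)

  # component-wise averaging equals hand recomputation at random nodes
  set.seed(1)
  for (n0 in sample(nrow(fused), 10)) {
    txy <- !g_xy$untracked[n0]; txz <- !g_xz$untracked[n0]
    tyz <- !g_yz$untracked[n0]
    ex <- if (txy || txz) {
      (txy * g_xy$ux[n0] + txz * g_xz$ux[n0]) / max(txy + txz, 1)
    } else 0
    expect_equal(fused$ux[n0], ex, tolerance = 1e-12)
  }

  # identical constant passes fuse to that constant
  cgrid <- synthetic_grid(function(x, y, z) c(1, 2, 3), mesh = c(4, 4, 3))
  fused_c <- reconstruct_3d(cgrid, cgrid, cgrid)
  expect_true(all(fused_c$ux == 1 & fused_c$uy == 2 & fused_c$uz == 3))

  # inconsistent meshes rejected
  small <- synthetic_grid(function(x, y, z) c(0, 0, 0), mesh = c(3, 3, 3))
  expect_error(reconstruct_3d(cgrid, cgrid, small), "mesh")
})

test_that("tracking B against A gives the negative of A against B", {
  pair <- make_tfm_pair(grid = c(64, 64, 16), amplitude = 1.5, radius = 12,
                        noise_sd = 0, seed = 8)
  args <- list(window = c(16, 16, 6), search = c(4, 4, 2),
               node_spacing = c(8, 8, 3))
  fwd <- do.call(track_displacements, c(list(pair$a, pair$b), args))
  rev <- do.call(track_displacements, c(list(pair$b, pair$a), args))
  both <- !fwd$untracked & !rev$untracked
  expect_gt(mean(both), 0.8)
  diff <- cbind(fwd$ux + rev$ux, fwd$uy + rev$uy, fwd$uz + rev$uz)[both, ]
  expect_lt(sqrt(mean(diff^2)), 0.35)
})

test_that("tracking error grows monotonically with imaging noise", {
  # independent per-frame noise (as in consecutive acquisitions), not noise
  # baked into the warped texture
  pair <- make_tfm_pair(grid = c(64, 64, 16), amplitude = 1.5, radius = 12,
                        noise_sd = 0, seed = 9)
  rmses <- vapply(c(0, 5, 8), function(ns) {
    an <- pair$a; bn <- pair$b
    withr::with_seed(100 + ns, {
      an$voxels <- pmax(an$voxels + array(rnorm(length(an$voxels), sd = ns),
                                          dim(an$voxels)), 0)
      bn$voxels <- pmax(bn$voxels + array(rnorm(length(bn$voxels), sd = ns),
                                          dim(bn$voxels)), 0)
    })
    g <- track_displacements(an, bn, window = c(16, 16, 6),
                             search = c(4, 4, 2), node_spacing = c(8, 8, 3))
    rmse_voxels(g, pair$field)
  }, 0)
  expect_true(all(diff(rmses) >= -1e-6))
})

test_that("translation equivariance holds in the interior", {
  p <- fibre_phantom_params(grid_shape = c(64, 64, 16), voxel_size = c(1, 1, 1),
                            n_fibres = 200, noise_sd = 0, seed = 10)
  a <- generate_fibre_stack(p)
  fld <- make_contraction_field(c(32, 32, 8), 1.5, 10,
                                grid_shape = c(64, 64, 16))
  b <- warp_stack(a, fld)
  shift_arr <- function(v, d) {
    out <- array(0, dim(v))
    out[(1 + d[1]):64, (1 + d[2]):64, (1 + d[3]):16] <-
      v[1:(64 - d[1]), 1:(64 - d[2]), 1:(16 - d[3])]
    out
  }
  d <- c(8, 8, 3)  # one node spacing, so shifted nodes land on the mesh
  args <- list(window = c(16, 16, 6), search = c(3, 3, 2),
               node_spacing = c(8, 8, 3))
  g0 <- do.call(track_displacements, c(list(a, b), args))
  g1 <- do.call(track_displacements,
                c(list(image_stack(shift_arr(a$voxels, d)),
                       image_stack(shift_arr(b$voxels, d))), args))
  # node at x in the shifted pair sees the field at x - d
  m0 <- g0[!g0$untracked, c("x", "y", "z", "ux", "uy", "uz")]
  m1 <- g1[!g1$untracked, c("x", "y", "z", "ux", "uy", "uz")]
  m1$x <- m1$x - d[1]; m1$y <- m1$y - d[2]; m1$z <- m1$z - d[3]
  j <- merge(as.data.frame(m0), as.data.frame(m1), by = c("x", "y", "z"))
  # interior only: away from frame borders in the original frame
  j <- j[j$x > 12 & j$x < 52 & j$y > 12 & j$y < 52, ]
  expect_gt(nrow(j), 5)
  err <- sqrt(rowSums((j[, c("ux.x", "uy.x", "uz.x")] -
                         j[, c("ux.y", "uy.y", "uz.y")])^2))
  expect_lt(max(err), 0.35)
})
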