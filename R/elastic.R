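#' Linear isotropic elastic parameters
#'
#' Constitutive constants of the collagen matrix assumed purely elastic,
#' continuous, homogeneous and isotropic: Young's modulus `E` (28 Pa by
#' default, as measured for a pliable collagen I gel), Poisson ratio `v`
#' (0.25 by default) and the derived shear modulus `mu = E / (2 (1 + v))`.
#'
#' @param E Young's modulus, Pa (>= 0).
#' @param v Poisson ratio, dimensionless, in (-1, 0.5).
#'
#' @return An `elastic_params` list with `E`, `v` and `mu`.
#' @export
elastic_params <- function(E = 28, v = 0.25) {
  structure(list(E = E, v = v, mu = shear_modulus(E, v)),
            class = "elastic_params")
}

#' Shear modulus from Young's modulus and Poisson ratio
#'
#' Solves `E = 2 mu (1 + v)` for `mu`.
#'
#' @param E Young's modulus, Pa (>= 0).
#' @param v Poisson ratio in (-1, 0.5).
#'
#' @return Shear modulus, Pa.
#' @export
#'
#' @examples
#' shear_modulus(28, 0.25)  # 11.2 Pa
shear_modulus <- function(E, v) {
  if (any(E < 0)) abort("`E` must be >= 0.")
  if (any(v <= -1 | v >= 0.5)) abort("`v` must lie in (-1, 0.5).")
  E / (2 * (1 + v))
}

# displacement_grid -> list(u = [ni,nj,nk,3] um, h = node pitch um)
grid_to_arrays <- function(grid) {
  md <- attr(grid, "mesh_dims")
  ns <- attr(grid, "node_spacing")
  vs <- attr(grid, "voxel_size")
  u <- array(0, c(md, 3))
  idx <- cbind(grid$i, grid$j, grid$k)
  u[cbind(idx, 1L)] <- grid$ux
  u[cbind(idx, 2L)] <- grid$uy
  u[cbind(idx, 3L)] <- grid$uz
  list(u = u, h = ns * vs, md = md)
}

# d/dx along one axis of a 3D array with node pitch h; Gaussian-derivative
# filtering at `smoothing` nodes, or central differences when smoothing = 0.
deriv_axis <- function(a, axis, h, smoothing) {
  if (smoothing > 0) {
    k <- gauss_deriv_kernel(smoothing)
    g <- gauss_kernel(smoothing)
    for (ax in 1:3) {
      a <- conv_axis3(a, if (ax == axis) k else g, ax)
    }
    return(a / h)
  }
  d <- dim(a)
  n <- d[axis]
  if (n < 2) return(array(0, d))
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  out <- array(0, dp)
  if (n >= 3) out[2:(n - 1), , ] <- (ap[3:n, , ] - ap[1:(n - 2), , ]) / 2
  out[1, , ] <- ap[2, , ] - ap[1, , ]
  out[n, , ] <- ap[n, , ] - ap[n - 1, , ]
  aperm(out, order(perm)) / h
}

#' Strain tensor field from a displacement grid
#'
#' Converts a filled displacement field to a symmetric 3x3 strain tensor per
#' node by the displacement-gradient technique. In `"full"` mode the
#' small-strain tensor `eps = (grad u + grad u^T) / 2` is formed; in
#' `"diagonal"` mode only the normal strains `eps_ii = d u_i / d x_i` are
#' kept (the axis strains treated as principal strains), with zero
#' off-diagonals. The two modes agree for shear-free fields. Derivatives use
#' Gaussian-derivative filtering at scale `smoothing` (nodes), or central
#' differences when `smoothing = 0`.
#'
#' @param grid A [displacement_grid()] with no untracked nodes (see
#'   [fill_untracked()]).
#' @param mode `"full"` (default) or `"diagonal"`.
#' @param smoothing Gaussian scale in nodes (default 1; 0 for plain central
#'   differences).
#'
#' @return A `strain_field`: `eps` array `[ni, nj, nk, 3, 3]`
#'   (dimensionless), `mode`, `h` (node pitch, micrometres) and `mesh_dims`.
#' @export
strain_field <- function(grid, mode = c("full", "diagonal"), smoothing = 1) {
  mode <- match.arg(mode)
  if (!inherits(grid, "displacement_grid")) {
    abort("`grid` must be a displacement_grid.")
  }
  if (any(grid$untracked)) {
    abort("grid has untracked nodes; run fill_untracked() first.")
  }
  ga <- grid_to_arrays(grid)
  md <- ga$md
  eps <- array(0, c(md, 3, 3))
  grads <- array(0, c(md, 3, 3))  # grads[,,,i,j] = d u_i / d x_j
  for (ci in 1:3) for (cj in 1:3) {
    if (mode == "diagonal" && ci != cj) next
    ui <- array(ga$u[, , , ci], md)  # keep singleton mesh dims
    grads[, , , ci, cj] <- deriv_axis(ui, cj, ga$h[cj], smoothing)
  }
  if (mode == "full") {
    for (ci in 1:3) for (cj in 1:3) {
      eps[, , , ci, cj] <- (grads[, , , ci, cj] + grads[, , , cj, ci]) / 2
    }
  } else {
    for (ci in 1:3) eps[, , , ci, ci] <- grads[, , , ci, ci]
  }
  structure(list(eps = eps, mode = mode, h = ga$h, mesh_dims = md),
            class = "strain_field")
}

#' Cauchy stress from strain
#'
#' Voxel-wise linear isotropic constitutive relation `delta = 2 mu eps`,
#' with the shear modulus from [elastic_params()]. Linear in the strain and
#' symmetric wherever the strain is.
#'
#' @param strain A [strain_field()].
#' @param params An [elastic_params()] (default `E` 28 Pa, `v` 0.25).
#'
#' @return A `stress_field` with `delta` array `[ni, nj, nk, 3, 3]` in Pa.
#' @export
stress_field <- function(strain, params = elastic_params()) {
  if (!inherits(strain, "strain_field")) abort("`strain` must be a strain_field.")
  if (!is.finite(params$mu)) abort("shear modulus must be finite.")
  structure(list(delta = 2 * params$mu * strain$eps, params = params,
                 mesh_dims = strain$mesh_dims, h = strain$h),
            class = "stress_field")
}

#' Principal stresses and directions
#'
#' Per-node symmetric eigendecomposition of the Cauchy stress tensor:
#' eigenvalues sorted descending (`lambda1 >= lambda2 >= lambda3`, Pa) with
#' unit eigenvectors, which give the traction-stress solutions and the
#' normal directions they act on.
#'
#' @param stress A [stress_field()]; tensors must be symmetric within
#'   `tol`.
#' @param tol Symmetry tolerance relative to the largest |component|
#'   (default 1e-8).
#'
#' @return A `principal_stress_field`: `values` `[ni, nj, nk, 3]` and
#'   `vectors` `[ni, nj, nk, 3, 3]` (column `m` of `[i, j, k, , m]` is the
#'   eigenvector of `lambda_m`).
#' @export
principal_stresses <- function(stress, tol = 1e-8) {
  if (!inherits(stress, "stress_field")) abort("`stress` must be a stress_field.")
  dl <- stress$delta
  md <- stress$mesh_dims
  scale <- max(abs(dl), 1e-300)
  asym <- max(abs(dl[, , , 1, 2] - dl[, , , 2, 1]),
              abs(dl[, , , 1, 3] - dl[, , , 3, 1]),
              abs(dl[, , , 2, 3] - dl[, , , 3, 2]))
  if (asym > tol * scale) abort("stress tensors are not symmetric.")
  values <- array(0, c(md, 3))
  vectors <- array(0, c(md, 3, 3))
  for (k in seq_len(md[3])) for (j in seq_len(md[2])) for (i in seq_len(md[1])) {
    m <- matrix(dl[i, j, k, , ], 3, 3)
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)  # descending eigenvalues
    values[i, j, k, ] <- e$values
    vectors[i, j, k, , ] <- e$vectors
  }
  structure(list(values = values, vectors = vectors, mesh_dims = md,
                 h = stress$h),
            class = "principal_stress_field")
}

#' Traction stress field
#'
#' Combines the principal stresses into a traction vector and magnitude per
#' node. `"principal"` mode (default) reports the basis-independent
#' magnitude `sqrt(lambda1^2 + lambda2^2 + lambda3^2)`, reading the
#' eigenvalues as the traction components along their own normal directions.
#' `"components"` mode forms `T = sum_i lambda_i V_i` in the laboratory
#' frame and reports `|T| = sqrt(Tx^2 + Ty^2 + Tz^2)`.
#'
#' @param principal A [principal_stresses()] result; eigenvectors must be
#'   unit length.
#' @param mode `"principal"` or `"components"`.
#'
#' @return A `traction_field`: `Tx`, `Ty`, `Tz` arrays (Pa; zero in
#'   principal mode's lab frame is not defined, so the per-axis components
#'   are the eigenvalue triple) and `magnitude` array (Pa).
#' @export
traction_field <- function(principal, mode = c("principal", "components")) {
  mode <- match.arg(mode)
  if (!inherits(principal, "principal_stress_field")) {
    abort("`principal` must be a principal_stress_field.")
  }
  V <- principal$vectors
  norms <- sqrt(apply(V^2, c(1, 2, 3, 5), sum))
  if (max(abs(norms - 1)) > 1e-6) abort("eigenvectors must be unit length.")
  lam <- principal$values
  md <- principal$mesh_dims
  if (mode == "principal") {
    Tx <- array(lam[, , , 1], md)
    Ty <- array(lam[, , , 2], md)
    Tz <- array(lam[, , , 3], md)
  } else {
    Tx <- array(0, md); Ty <- array(0, md); Tz <- array(0, md)
    for (m in 1:3) {
      Tx <- Tx + array(lam[, , , m], md) * array(V[, , , 1, m], md)
      Ty <- Ty + array(lam[, , , m], md) * array(V[, , , 2, m], md)
      Tz <- Tz + array(lam[, , , m], md) * array(V[, , , 3, m], md)
    }
  }
  structure(list(Tx = Tx, Ty = Ty, Tz = Tz,
                 magnitude = sqrt(Tx^2 + Ty^2 + Tz^2),
                 mode = mode, mesh_dims = md, h = principal$h),
            class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf("<traction_field> %s mode, peak |T| = %.3g Pa\n",
              x$mode, max(x$magnitude)))
  invisible(x)
}

#' Full traction pipeline from a displacement grid
#'
#' Convenience chain: strain -> stress -> principal decomposition ->
#' traction, at the given elastic constants.
#'
#' @param grid Filled [displacement_grid()].
#' @param params [elastic_params()].
#' @param mode Strain mode, `"full"` or `"diagonal"`.
#' @param smoothing Strain derivative scale, nodes.
#' @param traction_mode `"principal"` or `"components"`.
#'
#' @return A `traction_field`.
#' @export
compute_traction <- function(grid, params = elastic_params(),
                             mode = "full", smoothing = 1,
                             traction_mode = "principal") {
  grid |>
    strain_field(mode = mode, smoothing = smoothing) |>
    stress_field(params = params) |>
    principal_stresses() |>
    traction_field(mode = traction_mode)
}

#' Render a 2D traction stress map
#'
#' Projects the traction magnitude to 2D (one z slice or the
#' maximum-intensity projection) and maps it to a jet-style colour scale:
#' blue at zero, red at `scale_max`, the convention used for cell "reaction
#' maps" where red marks matrix under traction.
#'
#' @param traction A [traction_field()].
#' @param projection `"max"` for maximum-intensity projection, or an integer
#'   z slice index.
#' @param scale_max Top of the colour scale in Pa (default: field maximum).
#'
#' @return A `traction_map`: `values` matrix (Pa), `colors` matrix of hex
#'   colours, and `scale_max`. Plot with [autoplot()].
#' @export
render_stress_map <- function(traction, projection = "max",
                              scale_max = NULL) {
  if (!inherits(traction, "traction_field")) {
    abort("`traction` must be a traction_field.")
  }
  mag <- traction$magnitude
  if (length(mag) == 0) abort("empty traction field.")
  if (!all(is.finite(mag))) abort("traction magnitudes must be finite.")
  vals <- if (identical(projection, "max")) {
    apply(mag, c(1, 2), max)
  } else {
    sl <- as.integer(projection)
    if (sl < 1 || sl > dim(mag)[3]) abort("slice index out of range.")
    mag[, , sl]
  }
  scale_max <- scale_max %||% max(vals)
  pal <- grDevices::colorRampPalette(
    c("#00007F", "blue", "cyan", "yellow", "red", "#7F0000"))(256)
  idx <- if (scale_max > 0) {
    pmin(255L, pmax(0L, as.integer(round(vals / scale_max * 255)))) + 1L
  } else {
    matrix(1L, nrow(vals), ncol(vals))
  }
  cols <- matrix(pal[idx], nrow(vals), ncol(vals))
  structure(list(values = vals, colors = cols, scale_max = scale_max,
                 palette = pal, projection = projection),
            class = "traction_map")
}

#' @export
print.traction_map <- function(x, ...) {
  cat(sprintf("<traction_map> %d x %d, scale 0..%.3g Pa\n",
              nrow(x$values), ncol(x$values), x$scale_max))
  invisible(x)
}
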