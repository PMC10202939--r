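test_that("shear modulus follows E = 2 mu (1 + v)", {
  expect_equal(shear_modulus(28, 0.25), 11.2)
  expect_equal(shear_modulus(10, 0), 5)
  expect_equal(shear_modulus(0, 0.3), 0)
  expect_error(shear_modulus(28, 0.5), "v")
  expect_error(shear_modulus(-1, 0.25), "E")
})

test_that("strain of uniform and linear displacement fields is exact", {
  # uniform displacement: zero strain in both modes, any smoothing
  gu <- synthetic_grid(function(x, y, z) c(2, -1, 0.5))
  for (mode in c("full", "diagonal")) {
    for (sm in c(0, 1)) {
      eps <- strain_field(gu, mode = mode, smoothing = sm)$eps
      expect_lt(max(abs(eps)), 1e-12)
    }
  }

  # u_x = 0.1 x: eps_11 = 0.1 everywhere, all other components zero
  gl <- synthetic_grid(function(x, y, z) c(0.1 * x, 0, 0))
  for (mode in c("full", "diagonal")) {
    eps <- strain_field(gl, mode = mode, smoothing = 0)$eps
    expect_equal(max(abs(eps[, , , 1, 1] - 0.1)), 0, tolerance = 1e-12)
    eps[, , , 1, 1] <- 0
    expect_lt(max(abs(eps)), 1e-12)
  }

  # unfilled grids are rejected
  gb <- gu
  gb$untracked[3] <- TRUE
  expect_error(strain_field(gb), "untracked")
})

test_that("strain matches a central-difference oracle on a smooth field", {
  f <- function(x, y, z) c(0.02 * sin(x / 8) + 0.01 * y,
                           0.03 * cos(y / 10),
                           0.015 * z + 0.02 * sin(x / 12))
  g <- synthetic_grid(f, mesh = c(9, 9, 5), spacing = c(4, 4, 4))
  eps <- strain_field(g, mode = "full", smoothing = 0)$eps
  ga <- mechphen:::grid_to_arrays(g)
  h <- ga$h
  # independent central-difference oracle at an interior node
  for (pt in list(c(4, 5, 3), c(3, 3, 2), c(7, 6, 4))) {
    i <- pt[1]; j <- pt[2]; k <- pt[3]
    o <- matrix(0, 3, 3)
    du <- function(ci, cj) {
      ip <- pt; im <- pt
      ip[cj] <- ip[cj] + 1; im[cj] <- im[cj] - 1
      (ga$u[ip[1], ip[2], ip[3], ci] - ga$u[im[1], im[2], im[3], ci]) /
        (2 * h[cj])
    }
    for (ci in 1:3) for (cj in 1:3) o[ci, cj] <- (du(ci, cj) + du(cj, ci)) / 2
    expect_equal(matrix(eps[i, j, k, , ], 3, 3), o, tolerance = 1e-6)
  }
  # symmetry by construction
  expect_equal(eps[, , , 1, 2], eps[, , , 2, 1])
  expect_equal(eps[, , , 1, 3], eps[, , , 3, 1])
})

test_that("stress is 2 mu times strain and linear", {
  g <- synthetic_grid(function(x, y, z) c(0.1 * x, 0, 0))
  eps <- strain_field(g, mode = "diagonal", smoothing = 0)
  dl <- stress_field(eps, elastic_params(28, 0.25))$delta
  # eps = diag(0.1, 0, 0), mu = 11.2 -> delta = diag(2.24, 0, 0) Pa
  expect_equal(max(abs(dl[, , , 1, 1] - 2.24)), 0, tolerance = 1e-12)
  dl[, , , 1, 1] <- 0
  expect_lt(max(abs(dl)), 1e-12)

  # zero strain -> zero stress
  z <- strain_field(synthetic_grid(function(x, y, z) c(1, 1, 1)),
                    smoothing = 0)
  expect_true(all(stress_field(z)$delta == 0))

  # linearity under scaling
  set.seed(42)
  a <- runif(1, 0.1, 5)
  sc <- eps
  sc$eps <- a * eps$eps
  expect_equal(stress_field(sc)$delta, a * stress_field(eps)$delta,
               tolerance = 1e-12)
})

test_that("principal stresses match hand cases and a cubic-root oracle", {
  mk_stress <- function(m) {
    structure(list(delta = array(rep(c(m), each = 1), c(1, 1, 1, 3, 3)),
                   params = elastic_params(), mesh_dims = c(1, 1, 1),
                   h = c(1, 1, 1)),
              class = "stress_field")
  }
  # diagonal tensor: eigenvalues are the diagonal, sorted descending
  p <- principal_stresses(mk_stress(diag(c(3, 1, -2))))
  expect_equal(c(p$values), c(3, 1, -2))
  expect_equal(abs(matrix(p$vectors[1, 1, 1, , ], 3, 3)), diag(3),
               tolerance = 1e-12)

  # pure shear s in the xy block: eigenvalues (s, 0, -s)
  s <- 1.7
  m <- matrix(0, 3, 3); m[1, 2] <- s; m[2, 1] <- s
  expect_equal(c(principal_stresses(mk_stress(m))$values), c(s, 0, -s),
               tolerance = 1e-12)

  # random symmetric tensors vs the characteristic polynomial solved by
  # polyroot()
  set.seed(7)
  for (rep in 1:20) {
    a <- matrix(rnorm(9), 3, 3)
    m <- (a + t(a)) / 2
    lam <- sort(c(principal_stresses(mk_stress(m))$values),
                decreasing = TRUE)
    # det(m - x I) = -x^3 + tr x^2 - c2 x + det
    tr <- sum(diag(m))
    c2 <- m[1, 1] * m[2, 2] - m[1, 2]^2 + m[1, 1] * m[3, 3] - m[1, 3]^2 +
      m[2, 2] * m[3, 3] - m[2, 3]^2
    roots <- sort(Re(polyroot(c(det(m), -c2, tr, -1))), decreasing = TRUE)
    expect_equal(lam, roots, tolerance = 1e-8)
    # reconstruction sum lambda_i v_i v_i^T
    pv <- principal_stresses(mk_stress(m))
    V <- matrix(pv$vectors[1, 1, 1, , ], 3, 3)
    rec <- V %*% diag(c(pv$values)) %*% t(V)
    expect_equal(rec, m, tolerance = 1e-8)
  }

  # asymmetric input rejected
  bad <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(principal_stresses(mk_stress(bad)), "symmetric")
})

test_that("traction magnitude follows the vector combination relation", {
  mk_principal <- function(lam, V = diag(3)) {
    structure(list(values = array(lam, c(1, 1, 1, 3)),
                   vectors = array(V, c(1, 1, 1, 3, 3)),
                   mesh_dims = c(1, 1, 1), h = c(1, 1, 1)),
              class = "principal_stress_field")
  }
  expect_equal(c(traction_field(mk_principal(c(0, 0, 0)))$magnitude), 0)
  # Pythagorean case in principal mode
  expect_equal(c(traction_field(mk_principal(c(3, 4, 0)))$magnitude), 5)
  # components mode with axis-aligned eigenvectors gives the same
  expect_equal(
    c(traction_field(mk_principal(c(3, 4, 0)), mode = "components")$magnitude),
    5)

  # elementwise |T| = sqrt(Tx^2 + Ty^2 + Tz^2) at random voxels
  set.seed(3)
  md <- c(5, 5, 4)
  lam <- array(rnorm(prod(md) * 3), c(md, 3))
  vec <- array(0, c(md, 3, 3))
  vec[, , , 1, 1] <- 1; vec[, , , 2, 2] <- 1; vec[, , , 3, 3] <- 1
  pf <- structure(list(values = lam, vectors = vec, mesh_dims = md,
                       h = c(1, 1, 1)),
                  class = "principal_stress_field")
  tf <- traction_field(pf)
  for (n in 1:100) {
    i <- sample(md[1], 1); j <- sample(md[2], 1); k <- sample(md[3], 1)
    expect_equal(tf$magnitude[i, j, k],
                 sqrt(tf$Tx[i, j, k]^2 + tf$Ty[i, j, k]^2 + tf$Tz[i, j, k]^2),
                 tolerance = 1e-12)
  }

  # non-unit eigenvectors rejected
  pf_bad <- mk_principal(c(1, 1, 1), V = 2 * diag(3))
  expect_error(traction_field(pf_bad), "unit")
})

test_that("uniform uniaxial strain gives uniform principal stress 2 mu eps0", {
  eps0 <- 0.05
  g <- synthetic_grid(function(x, y, z) c(eps0 * x, 0, 0),
                      mesh = c(7, 7, 5), spacing = c(4, 4, 4))
  pr <- g |>
    strain_field(mode = "diagonal", smoothing = 0) |>
    stress_field(elastic_params(28, 0.25)) |>
    principal_stresses()
  expected <- 2 * 11.2 * eps0  # = E / (1 + v) * eps0
  expect_equal(max(abs(pr$values[, , , 1] - expected)), 0, tolerance = 1e-10)
  expect_equal(expected, 28 / 1.25 * eps0)
  expect_lt(max(abs(pr$values[, , , 2:3])), 1e-10)
})

test_that("rotating the displacement field rotates the traction map", {
  # 90 degree rotation about z on a square mesh with equal spacing
  mesh <- c(9, 9, 5); spacing <- c(4, 4, 4)
  f <- function(x, y, z) c(0.02 * sin(x / 6) * cos(y / 9),
                           0.03 * cos(x / 7) + 0.01 * sin(y / 5),
                           0.01 * sin((x + y) / 10) * cos(z / 6))
  # rotated field: u'(x) = R u(R^-1 x); R: (x, y) -> (-y, x) around centre
  L <- (mesh[1] - 1) * spacing[1]
  f_rot <- function(x, y, z) {
    x0 <- y; y0 <- L - x
    u <- f(x0, y0, z)
    c(-u[2], u[1], u[3])
  }
  t1 <- compute_traction(synthetic_grid(f, mesh, spacing), smoothing = 0)
  t2 <- compute_traction(synthetic_grid(f_rot, mesh, spacing), smoothing = 0)
  # magnitude'(i, j, k) = magnitude(j, n + 1 - i, k)
  n <- mesh[1]
  rot_mag <- array(0, mesh)
  for (i in 1:n) for (j in 1:n) rot_mag[i, j, ] <- t1$magnitude[j, n + 1 - i, ]
  expect_equal(t2$magnitude, rot_mag, tolerance = 1e-8)
})

test_that("stress maps render deterministically with a jet scale", {
  md <- c(6, 6, 3)
  zero <- structure(list(Tx = array(0, md), Ty = array(0, md),
                         Tz = array(0, md), magnitude = array(0, md),
                         mode = "principal", mesh_dims = md, h = c(1, 1, 1)),
                    class = "traction_field")
  m0 <- render_stress_map(zero)
  expect_equal(length(unique(c(m0$colors))), 1)  # uniform minimum colour

  hot <- zero
  hot$magnitude[3, 4, 2] <- 8
  m1 <- render_stress_map(hot, projection = 2, scale_max = 8)
  expect_equal(sum(m1$colors == m1$palette[256]), 1)
  expect_equal(which(m1$colors == m1$palette[256]), 3 + (4 - 1) * 6)

  # MIP equals a per-pixel loop over z
  set.seed(11)
  tf <- zero
  tf$magnitude <- array(abs(rnorm(prod(md))), md)
  mp <- render_stress_map(tf, projection = "max")
  brute <- matrix(0, md[1], md[2])
  for (i in 1:md[1]) for (j in 1:md[2]) brute[i, j] <- max(tf$magnitude[i, j, ])
  expect_equal(mp$values, brute)

  p <- autoplot(mp)
  expect_s3_class(p, "ggplot")
})

test_that("doubling the deformation doubles traction in the small-strain regime", {
  g1 <- synthetic_grid(function(x, y, z) {
    r2 <- (x - 16)^2 + (y - 16)^2 + (z - 8)^2
    -0.5 * exp(-r2 / 200) * c(x - 16, y - 16, z - 8) / sqrt(max(r2, 1e-9))
  }, mesh = c(9, 9, 5), spacing = c(4, 4, 4))
  g2 <- g1
  g2$ux <- 2 * g1$ux; g2$uy <- 2 * g1$uy; g2$uz <- 2 * g1$uz
  t1 <- compute_traction(g1)
  t2 <- compute_traction(g2)
  expect_equal(t2$magnitude, 2 * t1$magnitude, tolerance = 1e-10)
})
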