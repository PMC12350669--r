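# helpers: synthetic incremental fields on a small grid
field_from_fun <- function(grid, fun) {
  pts <- grid_coords(grid)
  u <- fun(pts)
  structure(list(u = list(x = array(u[, 1], grid$shape),
                          y = array(u[, 2], grid$shape),
                          z = array(u[, 3], grid$shape)),
                 grid = grid), class = "displacement_field")
}

test_that("zero displacement gives F = I and E = 0", {
  g <- unit_grid(8)
  f0 <- field_from_fun(g, function(p) 0 * p)
  sf <- deformation_gradient(list(f0), g)
  expect_equal(max(abs(sf[[2]]$F$F11 - 1)), 0)
  expect_equal(max(abs(sf[[2]]$F$F12)), 0)
  expect_equal(max(abs(unlist(sf[[2]]$E))), 0)
  expect_equal(sf[[2]]$n_nonpositive_jacobian, 0)
})

test_that("affine displacements are differentiated exactly", {
  g <- unit_grid(9, spacing = 0.5)
  lam <- 1.1
  f <- field_from_fun(g, function(p) cbind(0 * p[, 1], 0 * p[, 2],
                                           (lam - 1) * p[, 3]))
  sf <- deformation_gradient(list(f), g)
  expect_equal(max(abs(sf[[2]]$F$F33 - lam)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sf[[2]]$F$F11 - 1)), 0)
  expect_equal(max(abs(sf[[2]]$E$E33 - (lam^2 - 1) / 2)), 0, tolerance = 1e-12)
})

test_that("two-increment composition reproduces the composed affine map", {
  g <- unit_grid(10, spacing = 0.8)
  A1 <- diag(c(1.05, 0.97, 1.02)); A1[1, 2] <- 0.03
  A2 <- diag(c(0.98, 1.04, 0.99)); A2[3, 1] <- -0.02
  # increment 1: x -> A1 x ; increment 2 (on deformed coords): y -> A2 y
  f1 <- field_from_fun(g, function(p) p %*% t(A1) - p)
  f2 <- field_from_fun(g, function(p) p %*% t(A2) - p)
  sf <- deformation_gradient(list(f1, f2), g)
  Ftot <- A2 %*% A1
  # compare at an interior voxel (borders use one-sided stencils + advected
  # sampling at clamped points)
  i <- c(5, 5, 5)
  Fv <- matrix(c(sf[[3]]$F$F11[i[1], i[2], i[3]], sf[[3]]$F$F21[i[1], i[2], i[3]],
                 sf[[3]]$F$F31[i[1], i[2], i[3]], sf[[3]]$F$F12[i[1], i[2], i[3]],
                 sf[[3]]$F$F22[i[1], i[2], i[3]], sf[[3]]$F$F32[i[1], i[2], i[3]],
                 sf[[3]]$F$F13[i[1], i[2], i[3]], sf[[3]]$F$F23[i[1], i[2], i[3]],
                 sf[[3]]$F$F33[i[1], i[2], i[3]]), 3, 3)
  expect_equal(Fv, Ftot, tolerance = 1e-8)
})

test_that("Green-Lagrange strain is rotation-invariant and exact", {
  expect_equal(green_lagrange(diag(3)), matrix(0, 3, 3))
  set.seed(5)
  for (i in 1:20) {
    R <- rodrigues_rotation(rnorm(3), runif(1, -pi, pi))$R
    expect_lt(max(abs(green_lagrange(R))), 1e-10)
  }
  F1 <- diag(c(1, 1, 1.1))
  expect_equal(green_lagrange(F1)[3, 3], 0.105, tolerance = 1e-12)
})

cylinder_mask_grid <- function(n = 26, nz = 20) {
  g <- hr_grid(c(n, n, nz), origin = c(-3.25, -3.25, 0.25),
               spacing = c(0.26, 0.26, 0.4))
  pts <- grid_coords(g)
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  mask <- array(rho >= 1.5 & rho <= 3.2, g$shape)
  list(grid = g, mask = mask, pts = pts)
}

test_that("anatomical basis on an ideal cylinder is the cylindrical frame", {
  cm <- cylinder_mask_grid()
  b <- build_anatomical_basis(cm$mask, cm$grid)
  expect_equal(abs(sum(b$long_axis * c(0, 0, 1))), 1, tolerance = 1e-6)
  # radial vector equals the analytic one within 1 degree
  analytic <- cbind(b$points[, 1], b$points[, 2], 0)
  analytic <- analytic / sqrt(rowSums(analytic^2))
  ang <- acos(pmin(1, abs(rowSums(b$e_r * analytic))))
  expect_lt(max(ang) * 180 / pi, 1)
})

test_that("the anatomical transform preserves trace and eigenvalues", {
  cm <- cylinder_mask_grid(16, 12)
  b <- build_anatomical_basis(cm$mask, cm$grid)
  set.seed(3)
  d <- cm$grid$shape
  E <- list(E11 = array(rnorm(prod(d), 0, 0.1), d),
            E22 = array(rnorm(prod(d), 0, 0.1), d),
            E33 = array(rnorm(prod(d), 0, 0.1), d),
            E12 = array(rnorm(prod(d), 0, 0.05), d),
            E13 = array(rnorm(prod(d), 0, 0.05), d),
            E23 = array(rnorm(prod(d), 0, 0.05), d))
  er <- anatomical_strains(E, b)
  m <- as.vector(b$mask)
  tr_cart <- (E$E11 + E$E22 + E$E33)[m]
  expect_equal(er$E_RR + er$E_CC + er$E_ZZ, tr_cart, tolerance = 1e-10)
  # eigenvalues preserved at a sample of voxels
  idx <- sample(sum(m), 10)
  mi <- which(m)[idx]
  for (t in seq_along(idx)) {
    Ec <- matrix(c(E$E11[mi[t]], E$E12[mi[t]], E$E13[mi[t]],
                   E$E12[mi[t]], E$E22[mi[t]], E$E23[mi[t]],
                   E$E13[mi[t]], E$E23[mi[t]], E$E33[mi[t]]), 3, 3)
    Ea <- matrix(c(er$E_RR[idx[t]], er$E_RC[idx[t]], er$E_RZ[idx[t]],
                   er$E_RC[idx[t]], er$E_CC[idx[t]], er$E_CZ[idx[t]],
                   er$E_RZ[idx[t]], er$E_CZ[idx[t]], er$E_ZZ[idx[t]]), 3, 3)
    expect_equal(sort(eigen(Ec)$values), sort(eigen(Ea)$values),
                 tolerance = 1e-9)
  }
})

test_that("uniform radial expansion gives the closed-form anatomical strain", {
  cm <- cylinder_mask_grid(32, 16)
  b <- build_anatomical_basis(cm$mask, cm$grid)
  eps <- 0.05
  f <- field_from_fun(cm$grid, function(p) cbind(eps * p[, 1], eps * p[, 2],
                                                 0 * p[, 3]))
  sf <- deformation_gradient(list(f), cm$grid)
  er <- anatomical_strains(sf[[2]]$E, b)
  expect_equal(mean(er$E_RR), eps + eps^2 / 2, tolerance = 2e-3)
  expect_equal(mean(er$E_CC), eps + eps^2 / 2, tolerance = 2e-3)
  expect_lt(max(abs(er$E_ZZ)), 2e-3)
})

test_that("rigid-body motion yields negligible strain through the pipeline", {
  cm <- cylinder_mask_grid(20, 14)
  b <- build_anatomical_basis(cm$mask, cm$grid)
  R <- rodrigues_rotation(c(0.2, -0.1, 1), 0.03)$R
  tr <- c(0.2, -0.1, 0.15)
  f <- field_from_fun(cm$grid, function(p)
    p %*% t(R) + matrix(tr, nrow(p), 3, byrow = TRUE) - p)
  sf <- deformation_gradient(list(f), cm$grid)
  er <- anatomical_strains(sf[[2]]$E, b)
  expect_lt(max(abs(as.matrix(er))), 1e-3)
})

test_that("GLS is the masked mean longitudinal strain", {
  e1 <- data.frame(E_ZZ = rep(-0.14, 50))
  e0 <- data.frame(E_ZZ = rep(0, 50))
  expect_equal(gls(list(e0, e1)), c(0, -0.14))
  expect_error(gls(list(data.frame(E_ZZ = numeric(0)))), "empty")
})

test_that("non-physical flagging counts by component and principal value", {
  mk <- function(n) data.frame(E_RR = numeric(n), E_CC = numeric(n),
                               E_ZZ = numeric(n), E_RC = numeric(n),
                               E_RZ = numeric(n), E_CZ = numeric(n))
  e <- mk(1000)
  expect_equal(flag_nonphysical(e)$fraction, 0)
  e$E_ZZ[1:10] <- 0.6
  expect_equal(flag_nonphysical(e)$fraction, 0.01)
  # principal value catches a pure-shear state whose components are small
  e2 <- mk(1)
  e2$E_RC <- 0.45  # principal values +-0.45 < 0.5; components fine
  expect_equal(flag_nonphysical(e2)$fraction, 0)
  e2$E_RC <- 0.55
  expect_equal(flag_nonphysical(e2)$fraction, 1)
})

test_that("AHA segmentation partitions the wall into 16 labelled segments", {
  cm <- cylinder_mask_grid(30, 21)
  b <- build_anatomical_basis(cm$mask, cm$grid)
  n <- sum(b$mask)
  e <- data.frame(E_RR = rep(0.1, n), E_CC = rep(-0.1, n),
                  E_ZZ = rep(-0.14, n), E_RC = 0, E_RZ = 0, E_CZ = 0)
  a <- aha_segment(b, e)
  expect_equal(a$n_segments, 16)
  expect_equal(sort(unique(a$segment)), 1:16)
  expect_equal(sum(a$table$n), n)             # partition
  expect_equal(a$table$E_ZZ_mean, rep(-0.14, 16))  # uniform field
  # anterior/posterior split: value depends only on the sign of y
  y <- b$points[, 2]
  e2 <- e; e2$E_CC <- ifelse(y > 0, 0.2, -0.3)
  a2 <- aha_segment(b, e2)
  ant <- a2$table$E_CC_mean[a2$table$segment %in% c(1, 7)]   # anterior sectors
  post <- a2$table$E_CC_mean[a2$table$segment %in% c(4, 10)] # inferior sectors
  expect_true(all(ant > 0.15))
  expect_true(all(post < -0.25))
})
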