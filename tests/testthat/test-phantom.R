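test_that("zero-amplitude phantom is static with identically zero strain", {
  ph <- generate_phantom(phantom_spec(eps_c = 0, eps_z = 0, tau = 0,
                                      noise_sigma = 0, psf_sigma = 0))
  X <- cbind(runif(50, -3, 3), runif(50, -3, 3), runif(50, 0, 8))
  for (f in c(2, ph$es_frame, ph$spec$n_frames)) {
    expect_equal(max(abs(phantom_displacement(ph, X, f))), 0)
    expect_equal(max(abs(as.matrix(phantom_strain_rcz(ph, X, f)))), 0)
  }
  g <- hr_grid(c(20, 20, 12), origin = c(-4, -4, 0), spacing = c(0.4, 0.4, 0.7))
  expect_equal(phantom_volume(ph, g, 1), phantom_volume(ph, g, ph$es_frame))
})

test_that("pure longitudinal shortening has the closed-form E_ZZ", {
  ph <- generate_phantom(phantom_spec(eps_c = 0, eps_z = 0.1, tau = 0))
  X <- cbind(runif(100, 1.6, 3.1), 0, runif(100, 0, 8))
  e <- phantom_strain_rcz(ph, X, ph$es_frame)  # g(ES) = 1
  expect_equal(e$E_ZZ, rep(((1 - 0.1)^2 - 1) / 2, 100), tolerance = 1e-12)
})

test_that("strain at the reference frame is zero and E comes from the
          analytic deformation gradient", {
  ph <- generate_phantom(phantom_spec())
  set.seed(7)
  rho <- runif(200, 1.55, 3.15); th <- runif(200, 0, 2 * pi)
  X <- cbind(rho * cos(th), rho * sin(th), runif(200, 0.2, 7.8))
  expect_equal(max(abs(as.matrix(phantom_strain_rcz(ph, X, 1)))), 0)
  # E = (F'F - I)/2 from phantom_F matches phantom_strain_rcz eigenvalues
  f <- phantom_F(ph, X, ph$es_frame)
  e <- phantom_strain_rcz(ph, X, ph$es_frame)
  i <- 17
  Fm <- matrix(f[i, ], 3, 3)
  Em <- (t(Fm) %*% Fm - diag(3)) / 2
  expect_equal(sort(eigen(Em)$values),
               sort(eigen(matrix(c(e$E_RR[i], 0, 0,
                                   0, e$E_CC[i], e$E_CZ[i],
                                   0, e$E_CZ[i], e$E_ZZ[i]), 3, 3))$values),
               tolerance = 1e-10)
})

test_that("the deformation is incompressible: det(F) = 1 in the wall", {
  ph <- generate_phantom(phantom_spec())
  set.seed(11)
  rho <- runif(300, 1.51, 3.19); th <- runif(300, 0, 2 * pi)
  X <- cbind(rho * cos(th), rho * sin(th), runif(300, 0, 8))
  for (f in c(3, ph$es_frame, 8)) {
    dets <- apply(phantom_F(ph, X, f), 1, function(v) det(matrix(v, 3, 3)))
    expect_lt(max(abs(dets - 1)), 0.01)
  }
})

test_that("rasterized wall volume is conserved over the cycle within 1%", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0, psf_sigma = 0,
                                      cap_thickness = 0, texture_amp = 0))
  g <- hr_grid(c(110, 110, 100), origin = c(-4.36, -4.36, 0.04),
               spacing = c(0.08, 0.08, 0.08))
  vol_of <- function(f) {
    v <- phantom_volume(ph, g, f)
    myo <- v > 55 & v < 150  # myocardium band
    sum(myo) * prod(g$spacing)
  }
  v_ed <- vol_of(1); v_es <- vol_of(ph$es_frame)
  expect_lt(abs(v_es - v_ed) / v_ed, 0.01)
  expect_lt(abs(v_ed - phantom_wall_volume(ph)) / phantom_wall_volume(ph),
            0.05)  # rasterization error at this resolution
})

test_that("rasterized wall volume converges to the analytic value at
          first order in the voxel size", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0, psf_sigma = 0,
                                      cap_thickness = 0, texture_amp = 0))
  err_at <- function(h) {
    n <- ceiling(8.8 / h)
    g <- hr_grid(c(n, n, ceiling(8 / h)),
                 origin = c(-4.4, -4.4, h / 2), spacing = rep(h, 3))
    v <- phantom_volume(ph, g, 1)
    abs(sum(v > 55 & v < 150) * h^3 - phantom_wall_volume(ph))
  }
  e1 <- err_at(0.4); e2 <- err_at(0.2)
  expect_lt(e2, e1 * 0.75)  # at least order-1-ish decay
})

test_that("default slicing protocol yields 8 SA + 5 LA planes per frame", {
  ph <- generate_phantom(phantom_spec(n_frames = 3))
  st <- slice_phantom(ph)
  expect_equal(st$n_frames, 3)
  labs <- vapply(stack_frame(st, 1), function(p) p$view_label, character(1))
  expect_equal(sum(labs == "SA"), 8)
  expect_equal(sum(labs == "LA-orthogonal"), 5)
  expect_equal(length(st$planes), 13 * 3)
})

test_that("a mid-cavity SA slice shows the annular wall at the right radii", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0, psf_sigma = 0,
                                      texture_amp = 0))
  st <- slice_phantom(ph, n_la = 0, sa_positions = 4, oversample = 1)
  px <- st$planes[[1]]$pixels
  w <- plane_to_world(st$planes[[1]])
  rho <- sqrt(w$points[, 1]^2 + w$points[, 2]^2)
  myo <- as.vector(px) > 55 & as.vector(px) < 150
  expect_lt(abs(min(rho[myo]) - 1.5), 0.25)   # one pixel
  expect_lt(abs(max(rho[myo]) - 3.2), 0.25)
  ch <- as.vector(px) > 150
  expect_true(all(rho[ch] < 1.5 + 0.25))
})

test_that("slicing is deterministic under a fixed seed", {
  ph <- generate_phantom(phantom_spec(n_frames = 2))
  s1 <- slice_phantom(ph, n_sa = 3, n_la = 2)
  s2 <- slice_phantom(ph, n_sa = 3, n_la = 2)
  expect_identical(s1$planes[[4]]$pixels, s2$planes[[4]]$pixels)
})

test_that("degrade applies blur then noise with the stated properties", {
  step <- cbind(matrix(0, 40, 20), matrix(100, 40, 20))
  expect_identical(degrade(step, 0, 0), step)
  # 10-90% width of a blurred step matches the erf closed form for sigma 3
  b <- degrade(step, 3, 0)
  prof <- b[20, ]
  x10 <- approx(prof, seq_along(prof), xout = 10, ties = "ordered")$y
  x90 <- approx(prof, seq_along(prof), xout = 90, ties = "ordered")$y
  expect_equal(abs(x90 - x10), 2 * qnorm(0.9) * 3, tolerance = 0.05 * 2 * qnorm(0.9) * 3)
  n1 <- degrade(step, 0, 5, seed = 9)
  n2 <- degrade(step, 0, 5, seed = 9)
  expect_identical(n1, n2)
  expect_gt(sd(n1 - step), 3)
  expect_warning(degrade(step, 0, 60, seed = 1, ref_intensity = 100), "SNR")
})

test_that("wall inversion and bad intensity ordering are rejected", {
  expect_error(phantom_spec(eps_c = 1.2), "invert")
  expect_error(phantom_spec(intensities = c(chamber = 10, myocardium = 100,
                                            background = 5)), "ordered")
  expect_error(phantom_spec(r_endo = 3, r_epi = 2), "r_endo")
})

test_that("orthogonal and radial LA sampling see the same phantom", {
  ph <- generate_phantom(phantom_spec(n_frames = 2, noise_sigma = 0))
  so <- slice_phantom(ph, n_sa = 4, n_la = 3, la_mode = "orthogonal")
  sr <- slice_phantom(ph, n_sa = 4, n_la = 3, la_mode = "radial")
  # the central LA plane of both protocols cuts through the chamber axis:
  # mean myocardial intensity agrees (same object, same degradation model)
  po <- so$planes[[6]]$pixels; pr <- sr$planes[[5]]$pixels
  expect_equal(mean(po[po > 55]), mean(pr[pr > 55]), tolerance = 0.05)
})
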