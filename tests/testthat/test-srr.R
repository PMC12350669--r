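# an isotropic single-stack acquisition whose pixels sit exactly on the
# HR grid voxels
isotropic_stack <- function(fun, n = 12, spacing = 0.5) {
  planes <- list()
  for (k in seq_len(n)) {
    z <- (k - 1) * spacing
    pl <- slice_plane(matrix(0, n, n),
                      origin = c(0, 0, z), row_dir = c(0, 1, 0),
                      col_dir = c(1, 0, 0),
                      pixel_spacing = c(spacing, spacing))
    w <- plane_to_world(pl)
    pl$pixels <- matrix(fun(w$points), n, n)
    planes[[k]] <- pl
  }
  image_stack_set(planes)
}

test_that("reconstruction is exact at sample points for an isotropic stack
          with lambda = 0", {
  fun <- function(p) 100 + 40 * sin(p[, 1]) * cos(p[, 2]) * (p[, 3] + 1) / 6
  st <- isotropic_stack(fun)
  g <- hr_grid(c(12, 12, 12), origin = c(0, 0, 0), spacing = rep(0.5, 3))
  cm <- classify_by_histogram(st, frame = 1)
  for (scheme in c("linear", "natural")) {
    rec <- reconstruct(st, cm,
                       srr_params(scheme = scheme, lambda = 0, radius = NULL),
                       g)
    truthv <- array(fun(grid_coords(g)), g$shape)
    expect_lt(max(abs(rec$volumes[[1]] - truthv)), 1e-6)
  }
})

test_that("the penalty-dominated limit returns the class means", {
  ph <- generate_phantom(phantom_spec(n_frames = 2))
  st <- slice_phantom(ph, n_sa = 4, n_la = 2)
  g <- build_hr_grid(st, r1 = 1)
  cm <- classify_by_histogram(st, frame = 1)
  sg_max <- max(cm$stats$sigma)
  rec <- reconstruct(st, cm, srr_params(lambda = 1e6 * sg_max^2), g,
                     frames = 1)
  mu <- setNames(cm$stats$mu, cm$stats$class)
  v <- rec$volumes[[1]]
  cl <- rec$class_hr[[1]]
  for (j in 1:3)
    expect_equal(mean(abs(v[cl == j] - mu[[as.character(j)]])) /
                   mu[[as.character(j)]], 0, tolerance = 1e-3)
})

test_that("the data-term residual does not increase when lambda decreases", {
  ph <- generate_phantom(phantom_spec(n_frames = 2))
  st <- slice_phantom(ph, n_sa = 6, n_la = 3)
  g <- build_hr_grid(st, r1 = 1)
  cm <- classify_by_histogram(st, frame = 1)
  res <- vapply(c(0, 0.5, 5), function(lam) {
    rec <- reconstruct(st, cm, srr_params(lambda = lam), g, frames = 1)
    pl <- stack_frame(st, 1)[[3]]
    sqrt(mean((apply_acquisition_model(rec$volumes[[1]], g, pl) -
                 pl$pixels)^2))
  }, numeric(1))
  expect_true(all(diff(res) >= -1e-9))
})

test_that("multi-view reconstruction beats SA-only stacking mid-gap on a
          smooth analytic field", {
  fun <- function(p) 100 + 50 * sin(p[, 1]) * cos(p[, 2]) * p[, 3] / 4
  # sparse SA stack (gap 1) + LA planes, vs SA-only
  planes <- list()
  n <- 33; sp <- 0.25
  for (z in seq(0.5, 7.5, by = 1)) {
    pl <- slice_plane(matrix(0, n, n), origin = c(-4, -4, z),
                      row_dir = c(0, 1, 0), col_dir = c(1, 0, 0),
                      pixel_spacing = c(sp, sp))
    pl$pixels <- matrix(fun(plane_to_world(pl)$points), n, n)
    planes[[length(planes) + 1]] <- pl
  }
  sa_only <- image_stack_set(planes)
  nz <- 41
  for (o in -2:2) {
    nrm <- c(1, 1, 0) / sqrt(2)
    cd <- c(1, -1, 0) / sqrt(2)
    org <- c(0, 0, 4) + o * nrm - 5 * cd - 4 * c(0, 0, 1)
    pl <- slice_plane(matrix(0, 33, 41), origin = org,
                      row_dir = c(0, 0, 1), col_dir = cd,
                      pixel_spacing = c(sp, sp), view_label = "LA-orthogonal")
    pl$pixels <- matrix(fun(plane_to_world(pl)$points), 33, 41)
    planes[[length(planes) + 1]] <- pl
  }
  multi <- image_stack_set(planes)
  g <- build_hr_grid(sa_only, r1 = 0.5, z_policy = "sa_extent")
  cm <- classify_by_histogram(multi, frame = 1)
  rec_m <- reconstruct(multi, cm, srr_params(lambda = 0), g)
  rec_s <- lr_baseline(sa_only, g)
  truthv <- array(fun(grid_coords(g)), g$shape)
  # mid-gap voxels: z half-way between SA planes
  zs <- grid_coords(g)[, 3]
  gap <- abs((zs - 0.5) %% 1 - 0.5) > 0.35 & zs > 1 & zs < 7
  err_m <- max(abs(rec_m$volumes[[1]][array(gap, g$shape)] -
                     truthv[array(gap, g$shape)]))
  err_s <- max(abs(rec_s$volumes[[1]][array(gap, g$shape)] -
                     truthv[array(gap, g$shape)]))
  expect_lt(err_m, err_s)
})

test_that("linear and natural schemes agree on a globally affine field", {
  fun <- function(p) 10 + 2 * p[, 1] - 3 * p[, 2] + 0.5 * p[, 3]
  st <- isotropic_stack(fun, n = 10)
  g <- hr_grid(c(19, 19, 19), origin = c(0, 0, 0), spacing = rep(0.25, 3))
  cm <- suppressWarnings(classify_by_histogram(st, frame = 1))
  cm$thresholds <- c(-Inf, Inf)  # single tissue class: the field is smooth
  r1 <- reconstruct(st, cm, srr_params(scheme = "linear", lambda = 0), g)
  r2 <- reconstruct(st, cm, srr_params(scheme = "natural", lambda = 0), g)
  truthv <- array(fun(grid_coords(g)), g$shape)
  rms <- function(a) sqrt(mean((a - truthv)^2)) / sd(truthv)
  expect_lt(rms(r1$volumes[[1]]), 0.02)
  expect_lt(rms(r2$volumes[[1]]), 0.02)
  expect_lt(sqrt(mean((r1$volumes[[1]] - r2$volumes[[1]])^2)) / sd(truthv),
            0.02)
})

test_that("lr_baseline keeps constants, stairs through-plane, and doubles
          in-plane counts at r1 = 0.5", {
  ph <- generate_phantom(phantom_spec(n_frames = 2, noise_sigma = 0))
  st <- slice_phantom(ph, n_sa = 6, n_la = 0)
  g <- build_hr_grid(st, r1 = 0.5, z_policy = "sa_extent")
  expect_equal(g$shape[1], 2L * 32L)
  # constant input -> constant output
  stc <- st
  for (i in seq_along(stc$planes)) stc$planes[[i]]$pixels[] <- 7
  recc <- lr_baseline(stc, g, frames = 1)
  expect_equal(range(recc$volumes[[1]]), c(7, 7), tolerance = 1e-9)
  # stair-like through-plane profile: few unique values along z off-slice
  rec <- lr_baseline(st, g, frames = 1)
  prof <- rec$volumes[[1]][20, 32, ]
  expect_lte(length(unique(round(prof, 6))), 6 + 1)
  # non-parallel slices rejected
  bad <- st
  bad$planes[[2]]$view_label <- "SA"
  bad$planes[[2]]$row_dir <- c(0, 0, 1)
  bad$planes[[2]]$normal <- srrcmr:::cross3(c(0, 0, 1), c(1, 0, 0))
  expect_error(lr_baseline(bad, g), "parallel")
})

test_that("the forward acquisition model is self-consistent and monotone
          in the point-spread width", {
  ph <- fx_phantom()
  res <- fx_sr()
  g <- res$grid
  pl <- stack_frame(res$stacks, 1)[[4]]
  synth <- apply_acquisition_model(res$recon$volumes[[1]], g, pl)
  expect_lt(sqrt(mean((synth - pl$pixels)^2)),
            2 * ph$spec$noise_sigma)
  # constant volume -> constant plane
  vol1 <- array(3, g$shape)
  expect_equal(range(apply_acquisition_model(vol1, g, pl)), c(3, 3))
  # blur widens an edge monotonically (edge along x, visible in-plane)
  edge_vol <- array(0, g$shape)
  edge_vol[seq_len(g$shape[1]) > g$shape[1] / 2, , ] <- 100
  p0 <- apply_acquisition_model(edge_vol, g, pl, psf_sigma = 0)
  p3 <- apply_acquisition_model(edge_vol, g, pl, psf_sigma = 3)
  width <- function(m) {
    pr <- m[, ncol(m) %/% 2]
    sum(pr > 5 & pr < 95)
  }
  expect_gt(width(p3), width(p0))
  # plane fully outside the grid errors
  far <- slice_plane(matrix(0, 4, 4), origin = c(100, 100, 100),
                     row_dir = c(0, 1, 0), col_dir = c(1, 0, 0))
  expect_error(apply_acquisition_model(res$recon$volumes[[1]], g, far),
               "outside")
})

test_that("class-specific interpolants confine chamber intensities", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0, psf_sigma = 0,
                                      n_frames = 2))
  st <- suppressWarnings(slice_phantom(ph))
  g <- build_hr_grid(st, r1 = 0.5)
  cm <- classify_by_histogram(st, frame = 1)
  rec <- reconstruct(st, cm, srr_params(), g, frames = 1)
  stats <- cm$stats
  mu_ch <- stats$mu[stats$class == 1]
  sd_ch <- stats$sigma[stats$class == 1]
  # myocardial voxels beyond one voxel of the tissue-pool boundary stay
  # below the chamber intensity band
  pts <- grid_coords(g)
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  myo <- rec$class_hr[[1]] == 2 &
    array(rho > 1.5 + 0.15 & pts[, 3] > 0.3 & pts[, 3] < 7.7, g$shape)
  expect_lt(max(rec$volumes[[1]][myo]), mu_ch - sd_ch)
})

test_that("reconstruction output is finer through-plane than the input", {
  ph <- generate_phantom(phantom_spec(n_frames = 2))
  st <- slice_phantom(ph, n_sa = 6, n_la = 3)
  g <- build_hr_grid(st, r1 = 0.5)
  expect_lte(g$spacing[3], g$spacing[1])
  expect_lt(g$spacing[3], 1)  # finer than the 1 mm slice gap
})
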