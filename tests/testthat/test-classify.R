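three_level_stack <- function(seed = 1, noise = 3) {
  set.seed(seed)
  px <- matrix(10, 30, 30)
  px[8:22, 8:22] <- 100
  px[12:18, 12:18] <- 200
  px <- px + matrix(rnorm(900, 0, noise), 30, 30)
  image_stack_set(list(slice_plane(px, c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))))
}

test_that("three-class histogram labelling recovers a known mixture", {
  st <- three_level_stack()
  cm <- classify_by_histogram(st, frame = 1)
  expect_equal(cm$stats$name, c("chamber", "myocardium", "surroundings"))
  expect_equal(cm$stats$mu[cm$stats$class == 1], 200, tolerance = 0.05 * 200)
  expect_equal(cm$stats$mu[cm$stats$class == 2], 100, tolerance = 0.05 * 100)
  expect_equal(cm$stats$mu[cm$stats$class == 3], 10, tolerance = 0.05 * 100)
  # partition: every pixel labelled exactly once
  expect_equal(sum(cm$stats$n), 900)
  expect_true(all(cm$labels[[1]] %in% 1:3))
  # monotone contrast ordering preserved
  mu <- setNames(cm$stats$mu, cm$stats$class)
  expect_true(mu["1"] > mu["2"] && mu["2"] > mu["3"])
})

test_that("degenerate intensity histograms fall back with a warning", {
  st <- image_stack_set(list(slice_plane(matrix(5, 10, 10), c(0, 0, 0),
                                         c(0, 1, 0), c(1, 0, 0))))
  expect_warning(classify_by_histogram(st, frame = 1), "single class")
  # two-level image: three modes not resolvable
  px <- matrix(rep(c(0, 100), each = 50), 10, 10)
  st2 <- image_stack_set(list(slice_plane(px, c(0, 0, 0),
                                          c(0, 1, 0), c(1, 0, 0))))
  expect_warning(classify_by_histogram(st2, frame = 1), "quantile|classes")
})

test_that("the chamber is the connected bright interior on a phantom slice", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 2))
  st <- suppressWarnings(slice_phantom(ph, n_sa = 2, n_la = 0,
                                       sa_positions = c(3, 4)))
  cm <- classify_by_histogram(st, frame = 1)
  lab <- cm$labels[[1]]
  w <- plane_to_world(stack_frame(st, 1)[[1]])
  rho <- sqrt(w$points[, 1]^2 + w$points[, 2]^2)
  # chamber voxels concentrate inside the endocardium (one-pixel slack
  # for the partial-volume shell)
  expect_gt(mean(rho[as.vector(lab) == 1] < 1.5 + 0.25), 0.95)
  # deep myocardium labelled as class 2
  mid <- rho > 1.9 & rho < 2.8
  expect_gt(mean(as.vector(lab)[mid] == 2), 0.85)
})

circle_contours <- function(radii, z_levels, n = 36, jitter = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  lapply(seq_along(z_levels), function(i) {
    r <- rep(radii[min(i, length(radii))], n)
    if (!is.null(jitter)) r <- r + jitter[[i]]
    cbind(r * cos(th), r * sin(th), z_levels[i])
  })
}

test_that("stacked circular contours produce a cylinder surface", {
  z <- seq(0, 7, by = 1)
  cs <- contour_set(endo = circle_contours(1.5, z),
                    epi = circle_contours(3, z))
  surf <- contours_to_surface(cs)
  expect_lt(max(abs(surf$r_epi - 3)), 0.05)
  expect_lt(max(abs(surf$r_endo - 1.5)), 0.05)
})

test_that("RBF smoothing at least halves an isolated 0.5 mm outlier", {
  z <- seq(0, 7, by = 1)
  jit <- replicate(8, rep(0, 36), simplify = FALSE)
  jit[[4]][10] <- 0.5
  cs <- contour_set(endo = circle_contours(1.5, z),
                    epi = circle_contours(3, z, jitter = jit))
  surf <- contours_to_surface(cs)
  dev <- abs(surf$r_epi - 3)
  expect_lt(max(dev), 0.25)
  # smoothing never moves the surface further than the outlier itself
  expect_lt(max(dev), 0.5)
})

test_that("crossing endo/epi contours are rejected with the slice index", {
  z <- seq(0, 3, by = 1)
  expect_error(contours_to_surface(
    contour_set(endo = circle_contours(2.0, z),
                epi = circle_contours(c(3, 3, 1.8, 3), z))),
    "slice")
})

test_that("contour sets validate their invariants", {
  z <- c(0, 1)
  expect_error(contour_set(endo = list(matrix(0, 4, 3), matrix(0, 4, 3)),
                           epi = circle_contours(3, z)), "fewer than 8")
})

test_that("surface voxelization matches the analytic annulus fraction", {
  z <- seq(0, 7, by = 1)
  cs <- contour_set(endo = circle_contours(1.5, z),
                    epi = circle_contours(3.2, z))
  surf <- contours_to_surface(cs)
  g <- hr_grid(c(80, 80, 16), origin = c(-3.95, -3.95, 0.1),
               spacing = c(0.1, 0.1, 0.42))
  lab <- surface_to_labels(surf, g)
  pts <- grid_coords(g)
  inz <- pts[, 3] <= 7
  frac_myo <- mean(lab$labels[array(inz, g$shape)] == 2)
  a_myo <- pi * (3.2^2 - 1.5^2) / 8^2  # annulus over the 8x8 mm footprint
  expect_equal(frac_myo, a_myo, tolerance = 0.02)
  # boundary tie-break: a point exactly on the endo surface is myocardium
  gb <- hr_grid(c(2, 1, 2), origin = c(1.5, 0, 2), spacing = c(1, 1, 1))
  lb <- surface_to_labels(surf, gb)
  expect_equal(lb$labels[1, 1, 1], 2L)
  # voxels beyond the surface z-range are surroundings and counted
  g2 <- hr_grid(c(4, 4, 4), origin = c(0, 0, 10), spacing = c(1, 1, 1))
  l2 <- surface_to_labels(surf, g2)
  expect_true(all(l2$labels == 3L))
  expect_equal(l2$n_outside_range, 64)
})

test_that("phantom-derived contours enclose the analytic wall volume", {
  ph <- generate_phantom(phantom_spec())
  cs <- phantom_contours(ph, z_levels = seq(0.25, 7.75, length.out = 9))
  surf <- contours_to_surface(cs)
  g <- hr_grid(c(56, 56, 26), origin = c(-3.5, -3.5, 0.25),
               spacing = c(0.128, 0.128, 0.3))
  lab <- surface_to_labels(surf, g)
  v_est <- sum(lab$labels == 2) * prod(g$spacing)
  # surfaces cover z 0.25..7.75 of the 8 mm wall
  v_true <- phantom_wall_volume(ph) * 7.5 / 8
  expect_equal(v_est, v_true, tolerance = 0.03 * v_true)
})
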