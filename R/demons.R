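#' Parameters of the diffeomorphic demons registration
#'
#' The three scales weight the terms of the registration energy: the
#' intensity-noise scale `sigma_i` (similarity term), the spatial
#' uncertainty `sigma_x` (coupling between the correspondence field and
#' the regular transformation; it bounds the per-iteration update step),
#' and the regularization scale `sigma_t`, realized as Gaussian smoothing
#' of the displacement field (the gradient-penalty term).
#'
#' @param sigma_i intensity-noise scale (> 0, on [0, 1]-normalized
#'   intensities; the default 0.1 matches typical cine noise after
#'   normalization — it must be on the scale of the actual intensity
#'   noise for the similarity term to carry weight in the energy).
#' @param sigma_x spatial uncertainty (voxels, > 0); the per-iteration
#'   update step is clamped at `sigma_x / 2`.
#' @param sigma_t regularization smoothing scale (voxels, > 0), applied
#'   to the total displacement field each iteration.
#' @param sigma_f fluid-like smoothing scale (voxels) applied to each
#'   update field before composition; suppresses spatially white
#'   noise-driven forces (0 disables).
#' @param iterations iteration count per pyramid level, coarse to fine.
#' @param factors downsampling factor per level (must end at 1).
#' @param diffeomorphic exponentiate updates by scaling-and-squaring.
#' @return An object of class `demons_params`.
#' @export
demons_params <- function(sigma_i = 0.05, sigma_x = 1, sigma_t = 1.5,
                          sigma_f = 1, iterations = c(500, 400, 300),
                          factors = c(4, 2, 1), diffeomorphic = TRUE) {
  if (any(c(sigma_i, sigma_x, sigma_t) <= 0)) stop("all sigma must be > 0")
  if (sigma_f < 0) stop("sigma_f must be >= 0")
  if (length(iterations) != length(factors))
    stop("need one iteration count per pyramid level")
  if (any(iterations <= 0)) stop("iterations must be positive")
  if (factors[length(factors)] != 1) stop("finest pyramid factor must be 1")
  structure(list(sigma_i = sigma_i, sigma_x = sigma_x, sigma_t = sigma_t,
                 sigma_f = sigma_f,
                 iterations = as.integer(iterations),
                 factors = as.integer(factors),
                 diffeomorphic = diffeomorphic),
            class = "demons_params")
}

#' Register a moving volume to a fixed volume (diffeomorphic demons)
#'
#' Intensities are min-max normalized over the pair (the similarity scale
#' assumes commensurate intensities), then the demons iteration alternates
#' a step-limited force update of the correspondence field, optional
#' exponentiation of the update (diffeomorphic variant), and Gaussian
#' smoothing of the composed field, over a coarse-to-fine pyramid.  The
#' recorded energy trace of accepted states is non-increasing within each
#' level; if the step collapses (more than five consecutive rejected
#' iterations) the level stops early with a warning.
#'
#' @param fixed,moving 3D arrays on `grid`.
#' @param grid an [hr_grid()] shared by both volumes.
#' @param params a [demons_params()].
#' @param normalize min-max normalize the pair to [0, 1] first.
#' @return An object of class `displacement_field`: `u` (list of `x`,
#'   `y`, `z` arrays, mm), `energy` (trace per pyramid level), `grid`,
#'   `params`.
#' @export
register <- function(fixed, moving, grid, params = demons_params(),
                     normalize = TRUE) {
  if (!identical(dim(fixed), dim(moving)))
    stop("fixed and moving volumes are on different grids")
  if (!identical(dim(fixed), as.integer(grid$shape)))
    stop("volumes do not match the grid shape")
  if (normalize) {
    lo <- min(fixed, moving); hi <- max(fixed, moving)
    if (hi > lo) {
      fixed <- (fixed - lo) / (hi - lo)
      moving <- (moving - lo) / (hi - lo)
    }
  }
  # background level for out-of-volume resampling: a robust estimate from
  # the volume's boundary faces (the minimum would sit ~3 noise SDs low)
  d <- dim(moving)
  face <- c(moving[c(1, d[1]), , ], moving[, c(1, d[2]), ],
            moving[, , c(1, d[3])])
  border <- median(face)
  res <- cpp_demons(fixed, moving, params$sigma_i, params$sigma_x,
                    params$sigma_t, params$sigma_f, params$iterations,
                    params$factors, params$diffeomorphic, border)
  if (isTRUE(res$early_stop))
    warning("registration stopped early: energy could not be decreased")
  u <- list(x = res$ux * grid$spacing[1],
            y = res$uy * grid$spacing[2],
            z = res$uz * grid$spacing[3])
  structure(list(u = u, energy = res$energy, grid = grid, params = params,
                 n_rejected = res$n_rejected),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mx <- sqrt(max(x$u$x^2 + x$u$y^2 + x$u$z^2))
  cat(sprintf("<displacement_field> %s voxels, max |u| = %s mm\n",
              paste(dim(x$u$x), collapse = "x"), fmt_num(mx)))
  invisible(x)
}

#' Evaluate the three-term registration energy of a displacement field
#'
#' Data term `||F - M o c||^2 / sigma_i^2`, coupling
#' `||u - c||^2 / sigma_x^2` and regularization
#' `||grad u||^2 / sigma_t^2`, each as a per-voxel mean; with `c = u`
#' (the converged state) the coupling term vanishes.  Useful for testing
#' and for comparing a recovered field against the zero field.
#'
#' @param fixed,moving 3D arrays (already commensurate in intensity).
#' @param field a [register()] result or `NULL` for the zero field.
#' @param grid an [hr_grid()].
#' @param params a [demons_params()].
#' @return named vector with `data`, `coupling`, `regularization`, `total`.
#' @export
demons_energy <- function(fixed, moving, field, grid,
                          params = demons_params()) {
  d <- dim(fixed)
  if (is.null(field)) {
    uvox <- list(array(0, d), array(0, d), array(0, d))
  } else {
    uvox <- list(field$u$x / grid$spacing[1], field$u$y / grid$spacing[2],
                 field$u$z / grid$spacing[3])
  }
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ix <- rep(seq_len(nx) - 1, times = ny * nz)
  iy <- rep(rep(seq_len(ny) - 1, each = nx), times = nz)
  iz <- rep(seq_len(nz) - 1, each = nx * ny)
  pts <- cbind(ix + as.vector(uvox[[1]]), iy + as.vector(uvox[[2]]),
               iz + as.vector(uvox[[3]]))
  mw <- cpp_sample_trilinear(moving, pts, border = min(moving))
  data <- mean((as.vector(fixed) - mw)^2) / params$sigma_i^2
  reg <- 0
  for (comp in uvox) {
    g <- grad3_r(comp, c(1, 1, 1))
    reg <- reg + mean(g[[1]]^2) + mean(g[[2]]^2) + mean(g[[3]]^2)
  }
  reg <- reg / params$sigma_t^2
  c(data = data, coupling = 0, regularization = reg, total = data + reg)
}

#' Register a cine sequence frame to frame
#'
#' Registers each consecutive frame pair (frame t fixed, frame t+1
#' moving), producing the incremental displacement fields from which the
#' cumulative deformation gradient is propagated.
#'
#' @param seq an `sr_volume_sequence`.
#' @param params a [demons_params()].
#' @param verbose print per-pair progress.
#' @return list of `n_frames - 1` [register()] results, in order.
#' @export
register_sequence <- function(seq, params = demons_params(),
                              verbose = FALSE) {
  n <- length(seq$volumes)
  if (n < 2) stop("need at least 2 frames")
  out <- vector("list", n - 1)
  for (t in seq_len(n - 1)) {
    if (verbose) message("registering frame pair ", t, " -> ", t + 1)
    out[[t]] <- tryCatch(
      register(seq$volumes[[t]], seq$volumes[[t + 1]], seq$grid, params),
      error = function(e) stop("registration failed at frame pair ", t,
                               ": ", conditionMessage(e), call. = FALSE))
  }
  out
}
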