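#' Rotation about an arbitrary axis (Rodrigues construction)
#'
#' Builds the rotation matrix `R = I + S sin(phi) + (1 - cos(phi)) S^2`,
#' where `S` is the cross-product (skew-symmetric) matrix of the unit
#' rotation axis.  This is the construction used to orient arbitrarily
#' tilted imaging planes in world space.
#'
#' @param axis numeric length-3 rotation axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return An object of class `rotation_spec` with elements `axis`, `angle`,
#'   `S` (skew matrix) and `R` (3x3 rotation matrix).
#' @examples
#' r <- rodrigues_rotation(c(0, 0, 1), pi / 2)
#' r$R %*% c(1, 0, 0)  # maps x to y
#' @export
rodrigues_rotation <- function(axis, angle) {
  if (!is.finite(angle)) stop("angle must be finite")
  n <- vnorm(axis)
  if (n < .Machine$double.eps) {
    if (abs(angle) < .Machine$double.eps) {
      axis <- c(0, 0, 1)  # identity; axis immaterial
    } else {
      stop("zero-length axis with a non-zero angle")
    }
  }
  a <- axis / max(n, .Machine$double.eps)
  S <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  R <- diag(3) + S * sin(angle) + (1 - cos(angle)) * (S %*% S)
  structure(list(axis = a, angle = angle, S = S, R = R),
            class = "rotation_spec")
}

#' @export
print.rotation_spec <- function(x, ...) {
  cat("Rotation: angle", fmt_num(x$angle), "rad about axis (",
      paste(fmt_num(x$axis), collapse = ", "), ")\n")
  invisible(x)
}

#' One 2D cine frame with full world-space geometry
#'
#' A slice plane holds the pixel intensities of a single low-resolution
#' acquisition together with the metadata needed to place every pixel in
#' the scanner's world frame: the world position of pixel (0,0), the row
#' and column direction cosines, the pixel spacing, the slice thickness
#' and cardiac-phase timing.  Pixel `(i, j)` (0-based row, column; the
#' coordinate refers to the pixel centre) sits at
#' `origin + i * dr * row_dir + j * dc * col_dir`.
#'
#' @param pixels numeric matrix of intensities (rows x columns).
#' @param origin world position (mm) of the centre of pixel (0, 0).
#' @param row_dir,col_dir unit direction cosines of increasing row/column
#'   index; must be orthonormal.
#' @param pixel_spacing `(dr, dc)` in mm.
#' @param thickness slice thickness in mm (metadata; pixels are treated as
#'   point samples at the slice mid-plane).
#' @param trigger_time frame trigger time in ms.
#' @param frame_index 1-based cardiac phase index.
#' @param view_label one of `"SA"`, `"LA-orthogonal"`, `"LA-radial"`.
#' @return An object of class `slice_plane`.
#' @export
slice_plane <- function(pixels, origin, row_dir, col_dir,
                        pixel_spacing = c(1, 1), thickness = 1,
                        trigger_time = 0, frame_index = 1L,
                        view_label = "SA") {
  pixels <- as.matrix(pixels)
  if (abs(vnorm(row_dir) - 1) > 1e-8 || abs(vnorm(col_dir) - 1) > 1e-8)
    stop("row_dir and col_dir must be unit vectors (non-unit direction cosines)")
  if (abs(sum(row_dir * col_dir)) > 1e-8)
    stop("row_dir and col_dir must be orthogonal (row_dir . col_dir != 0)")
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be positive")
  if (thickness <= 0) stop("thickness must be positive")
  normal <- cross3(row_dir, col_dir)
  structure(list(pixels = pixels, origin = as.numeric(origin),
                 row_dir = as.numeric(row_dir), col_dir = as.numeric(col_dir),
                 normal = normal, pixel_spacing = as.numeric(pixel_spacing),
                 thickness = thickness, trigger_time = trigger_time,
                 frame_index = as.integer(frame_index),
                 view_label = view_label),
            class = "slice_plane")
}

#' @export
print.slice_plane <- function(x, ...) {
  cat(sprintf("<slice_plane %s> %d x %d px, spacing (%s, %s) mm, frame %d\n",
              x$view_label, nrow(x$pixels), ncol(x$pixels),
              fmt_num(x$pixel_spacing[1]), fmt_num(x$pixel_spacing[2]),
              x$frame_index))
  invisible(x)
}

#' Scatter a slice plane into world space
#'
#' Maps every pixel of a slice plane to its world coordinate (mm) and
#' carries the intensity unchanged.  This is the geometric step that turns
#' a stack of oriented 2D acquisitions into the scattered observation set
#' that the reconstruction interpolates.
#'
#' @param plane a [slice_plane()].
#' @return A list with `points` (n x 3 matrix, mm) and `intensities`
#'   (length-n vector); row order is column-major over the pixel matrix.
#' @export
plane_to_world <- function(plane) {
  stopifnot(inherits(plane, "slice_plane"))
  nr <- nrow(plane$pixels); nc <- ncol(plane$pixels)
  i <- rep(seq_len(nr) - 1L, times = nc)
  j <- rep(seq_len(nc) - 1L, each = nr)
  dr <- plane$pixel_spacing[1]; dc <- plane$pixel_spacing[2]
  pts <- outer(i * dr, plane$row_dir) + outer(j * dc, plane$col_dir)
  pts <- sweep(pts, 2, plane$origin, "+")
  list(points = pts, intensities = as.vector(plane$pixels))
}

#' A multi-view cine acquisition: planes for every cardiac phase
#'
#' @param planes list of [slice_plane()] objects (all frames pooled; each
#'   carries its `frame_index`).
#' @param rr_interval cardiac cycle length in ms (metadata).
#' @return An object of class `image_stack_set` with `planes`, `n_frames`,
#'   and `rr_interval`.
#' @export
image_stack_set <- function(planes, rr_interval = NA_real_) {
  stopifnot(length(planes) >= 1)
  ok <- vapply(planes, inherits, logical(1), "slice_plane")
  if (!all(ok)) stop("all elements must be slice_plane objects")
  fr <- vapply(planes, function(p) p$frame_index, integer(1))
  n_frames <- max(fr)
  # short-axis planes must share one normal (up to sign, within 1e-6)
  sa <- planes[vapply(planes, function(p) identical(p$view_label, "SA"), logical(1))]
  if (length(sa) > 1) {
    n0 <- sa[[1]]$normal
    for (p in sa[-1]) {
      if (min(vnorm(p$normal - n0), vnorm(p$normal + n0)) > 1e-6)
        stop("all SA planes must share a common normal")
    }
  }
  structure(list(planes = planes, n_frames = n_frames,
                 rr_interval = rr_interval),
            class = "image_stack_set")
}

#' @export
print.image_stack_set <- function(x, ...) {
  nv <- table(vapply(x$planes, function(p) p$view_label, character(1)))
  cat(sprintf("<image_stack_set> %d planes (%s), %d frames\n",
              length(x$planes),
              paste(names(nv), as.integer(nv) / x$n_frames, collapse = ", "),
              x$n_frames))
  invisible(x)
}

#' Planes belonging to one cardiac frame
#' @param stacks an [image_stack_set()].
#' @param frame 1-based frame index.
#' @return list of `slice_plane` objects.
#' @export
stack_frame <- function(stacks, frame) {
  stacks$planes[vapply(stacks$planes, function(p) p$frame_index, integer(1)) == frame]
}

#' Structured isotropic high-resolution query grid
#'
#' @param shape voxel counts `(nx, ny, nz)`.
#' @param origin world coordinate (mm) of the centre of voxel (0, 0, 0).
#' @param spacing voxel spacing `(sx, sy, sz)` in mm.
#' @param r1 in-plane resampling ratio the grid was built with.
#' @return An object of class `hr_grid`; `axes` is the identity (the grid
#'   is world-axis aligned).
#' @export
hr_grid <- function(shape, origin, spacing, r1 = 1) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(shape = as.integer(shape), origin = as.numeric(origin),
                 spacing = as.numeric(spacing), axes = diag(3), r1 = r1),
            class = "hr_grid")
}

#' @export
print.hr_grid <- function(x, ...) {
  cat(sprintf("<hr_grid> %s voxels, spacing (%s) mm, r1 = %s\n",
              paste(x$shape, collapse = " x "),
              paste(fmt_num(x$spacing), collapse = ", "), fmt_num(x$r1)))
  invisible(x)
}

#' Voxel-centre world coordinates of a grid
#' @param grid an [hr_grid()].
#' @return n x 3 matrix (column-major voxel order, matching R arrays).
#' @export
grid_coords <- function(grid) {
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  ix <- rep(seq_len(nx) - 1L, times = ny * nz)
  iy <- rep(rep(seq_len(ny) - 1L, each = nx), times = nz)
  iz <- rep(seq_len(nz) - 1L, each = nx * ny)
  cbind(grid$origin[1] + ix * grid$spacing[1],
        grid$origin[2] + iy * grid$spacing[2],
        grid$origin[3] + iz * grid$spacing[3])
}

#' Convert world coordinates (mm) to 0-based voxel coordinates
#' @param grid an [hr_grid()].
#' @param pts n x 3 matrix of world points.
#' @return n x 3 matrix of fractional voxel coordinates.
#' @export
world_to_voxel <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Define the high-resolution reconstruction grid from an acquisition
#'
#' In-plane voxel counts equal the low-resolution counts divided by the
#' resampling ratio `r1` (`r1 = 0.5` doubles them); in-plane spacing is
#' `r1` times the LR in-plane spacing.  The through-plane spacing is set
#' to `r1` times the smallest LR in-plane spacing so that the output is
#' near-isotropic and strictly finer than every LR slice gap.  The grid
#' covers the union bounding box of the short-axis plane footprints
#' in-plane; the longitudinal extent is chosen by `z_policy`:
#' `"la_extent"` (default) uses the long-axis plane coverage, which
#' extends beyond the SA stack, `"sa_extent"` the SA slice positions, and
#' `"union"` their union.
#'
#' @param stacks an [image_stack_set()].
#' @param r1 in-plane resampling ratio in (0, 1].
#' @param z_policy longitudinal coverage rule (see above).
#' @return An [hr_grid()].
#' @export
build_hr_grid <- function(stacks, r1 = 0.5,
                          z_policy = c("la_extent", "sa_extent", "union")) {
  z_policy <- match.arg(z_policy)
  if (r1 <= 0 || r1 > 1) stop("r1 must lie in (0, 1]")
  f1 <- stack_frame(stacks, 1)
  is_sa <- vapply(f1, function(p) identical(p$view_label, "SA"), logical(1))
  sa <- f1[is_sa]; la <- f1[!is_sa]
  if (length(sa) == 0) stop("acquisition contains no SA planes")
  # in-plane counts and spacing from the SA planes
  n_in <- max(vapply(sa, function(p) max(dim(p$pixels)), numeric(1)))
  sp_in <- min(vapply(f1, function(p) min(p$pixel_spacing), numeric(1)))
  n_hr <- as.integer(round(n_in / r1))
  s_hr <- sp_in * r1
  sz <- r1 * sp_in
  corners <- function(p) {
    nr <- nrow(p$pixels); nc <- ncol(p$pixels)
    idx <- rbind(c(0, 0), c(nr - 1, 0), c(0, nc - 1), c(nr - 1, nc - 1))
    t(apply(idx, 1, function(ij)
      p$origin + ij[1] * p$pixel_spacing[1] * p$row_dir +
        ij[2] * p$pixel_spacing[2] * p$col_dir))
  }
  sa_c <- do.call(rbind, lapply(sa, corners))
  xr <- range(sa_c[, 1]); yr <- range(sa_c[, 2])
  z_sa <- range(sa_c[, 3])
  z_la <- if (length(la)) range(do.call(rbind, lapply(la, corners))[, 3]) else z_sa
  zr <- switch(z_policy,
               la_extent = z_la,
               sa_extent = z_sa,
               union = range(c(z_sa, z_la)))
  # count at unit ratio, then scale by 1/r1 so voxel counts scale exactly
  nz_base <- as.integer(floor(diff(zr) / sp_in)) + 1L
  nz <- max(4L, as.integer(round(nz_base / r1)))
  # centre the in-plane HR footprint on the SA footprint
  ox <- mean(xr) - (n_hr - 1) / 2 * s_hr
  oy <- mean(yr) - (n_hr - 1) / 2 * s_hr
  hr_grid(shape = c(n_hr, n_hr, nz), origin = c(ox, oy, zr[1]),
          spacing = c(s_hr, s_hr, sz), r1 = r1)
}
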