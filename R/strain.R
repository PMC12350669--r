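# 3x3-per-voxel tensor fields are stored as named lists of arrays with
# components F11, F21, ..., F33 (column-major) or E11, E22, E33, E12,
# E13, E23 for symmetric tensors.

tensor_identity <- function(d) {
  one <- array(1, d); zero <- array(0, d)
  list(F11 = one, F21 = zero, F31 = zero,
       F12 = zero, F22 = one, F32 = zero,
       F13 = zero, F23 = zero, F33 = one)
}

# C = A %*% B per voxel
tensor_mult <- function(A, B) {
  out <- list()
  for (j in 1:3) for (i in 1:3) {
    nm <- paste0("F", i, j)
    out[[nm]] <- A[[paste0("F", i, 1)]] * B[[paste0("F", 1, j)]] +
      A[[paste0("F", i, 2)]] * B[[paste0("F", 2, j)]] +
      A[[paste0("F", i, 3)]] * B[[paste0("F", 3, j)]]
  }
  out
}

tensor_det <- function(F) {
  F$F11 * (F$F22 * F$F33 - F$F23 * F$F32) -
    F$F12 * (F$F21 * F$F33 - F$F23 * F$F31) +
    F$F13 * (F$F21 * F$F32 - F$F22 * F$F31)
}

#' Propagate the cumulative deformation gradient from incremental fields
#'
#' Each incremental field contributes `F_i = I + du_i/dX` (second-order
#' central differences in mm, one-sided at the borders).  The cumulative
#' gradient is the ordered product `F(t) = F_t ... F_1`, with each later
#' increment evaluated at the material points advected by the composed
#' prior displacement (`method = "advected"`, the default) or at fixed
#' voxels (`method = "eulerian"`, the literal product).
#'
#' @param fields list of incremental [register()] results (displacements
#'   in mm), ordered ED to t.
#' @param grid the shared [hr_grid()].
#' @param method `"advected"` or `"eulerian"` (see above).
#' @param smooth_sigma optional Gaussian smoothing (voxels) of each
#'   incremental field before differentiation.  Strain is a derivative of
#'   a noisy estimated displacement; a smoothing scale of about two
#'   voxels suppresses derivative-scale registration noise at the cost of
#'   sharp transmural gradients (0 disables).
#' @return list of per-frame deformation states of class `strain_field`,
#'   frame 1 being the identity at ED; each holds `F` (tensor field),
#'   `E` (Green-Lagrange components), the composed displacement `u_total`
#'   (mm), and `n_nonpositive_jacobian`.
#' @export
deformation_gradient <- function(fields, grid,
                                 method = c("advected", "eulerian"),
                                 smooth_sigma = 0) {
  method <- match.arg(method)
  d <- as.integer(grid$shape)
  for (f in fields)
    if (!identical(dim(f$u$x), d)) stop("fields do not share the grid")
  if (smooth_sigma > 0)
    fields <- lapply(fields, function(f) {
      f$u <- lapply(f$u, cpp_gauss_blur3, sigma = smooth_sigma)
      f
    })
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ix <- rep(seq_len(nx) - 1, times = ny * nz)
  iy <- rep(rep(seq_len(ny) - 1, each = nx), times = nz)
  iz <- rep(seq_len(nz) - 1, each = nx * ny)
  Fcum <- tensor_identity(d)
  U <- list(x = array(0, d), y = array(0, d), z = array(0, d))
  out <- vector("list", length(fields) + 1)
  out[[1]] <- new_strain_field(Fcum, U, grid)
  for (t in seq_along(fields)) {
    u <- fields[[t]]$u
    gx <- grad3_r(u$x, grid$spacing)
    gy <- grad3_r(u$y, grid$spacing)
    gz <- grad3_r(u$z, grid$spacing)
    if (method == "advected") {
      pts <- cbind(ix + as.vector(U$x) / grid$spacing[1],
                   iy + as.vector(U$y) / grid$spacing[2],
                   iz + as.vector(U$z) / grid$spacing[3])
      samp <- function(a) array(cpp_sample_trilinear(a, pts, -1e30), d)
      Fi <- list(F11 = 1 + samp(gx[[1]]), F21 = samp(gy[[1]]),
                 F31 = samp(gz[[1]]),
                 F12 = samp(gx[[2]]), F22 = 1 + samp(gy[[2]]),
                 F32 = samp(gz[[2]]),
                 F13 = samp(gx[[3]]), F23 = samp(gy[[3]]),
                 F33 = 1 + samp(gz[[3]]))
      du <- list(x = samp(u$x), y = samp(u$y), z = samp(u$z))
    } else {
      Fi <- list(F11 = 1 + gx[[1]], F21 = gy[[1]], F31 = gz[[1]],
                 F12 = gx[[2]], F22 = 1 + gy[[2]], F32 = gz[[2]],
                 F13 = gx[[3]], F23 = gy[[3]], F33 = 1 + gz[[3]])
      du <- u
    }
    Fcum <- tensor_mult(Fi, Fcum)
    U <- list(x = U$x + du$x, y = U$y + du$y, z = U$z + du$z)
    out[[t + 1]] <- new_strain_field(Fcum, U, grid)
  }
  out
}

new_strain_field <- function(F, U, grid) {
  E <- green_lagrange(F)
  J <- tensor_det(F)
  structure(list(F = F, E = E, u_total = U, grid = grid,
                 jacobian = J,
                 n_nonpositive_jacobian = sum(J <= 0)),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %s voxels; %d voxels with det(F) <= 0\n",
              paste(dim(x$E$E11), collapse = "x"),
              x$n_nonpositive_jacobian))
  invisible(x)
}

#' Green-Lagrange strain from a deformation gradient field
#'
#' `E = (F^T F - I) / 2`, evaluated per voxel; exactly symmetric and
#' invariant to rigid rotation.
#'
#' @param F tensor field (named list `F11`..`F33`) or a single 3x3 matrix.
#' @return symmetric tensor components `E11, E22, E33, E12, E13, E23`
#'   (same container type as the input), or a 3x3 matrix for matrix input.
#' @export
green_lagrange <- function(F) {
  if (is.matrix(F)) {
    return((t(F) %*% F - diag(3)) / 2)
  }
  C11 <- F$F11^2 + F$F21^2 + F$F31^2
  C22 <- F$F12^2 + F$F22^2 + F$F32^2
  C33 <- F$F13^2 + F$F23^2 + F$F33^2
  C12 <- F$F11 * F$F12 + F$F21 * F$F22 + F$F31 * F$F32
  C13 <- F$F11 * F$F13 + F$F21 * F$F23 + F$F31 * F$F33
  C23 <- F$F12 * F$F13 + F$F22 * F$F23 + F$F32 * F$F33
  list(E11 = (C11 - 1) / 2, E22 = (C22 - 1) / 2, E33 = (C33 - 1) / 2,
       E12 = C12 / 2, E13 = C13 / 2, E23 = C23 / 2)
}

#' Per-voxel anatomical (radial-circumferential-longitudinal) basis
#'
#' The long-axis direction is the principal axis of the reference mask
#' (sign chosen toward +z); per-slice centroids along that axis define
#' the chamber centreline; the radial unit vector points from the
#' centreline to the voxel (in the plane orthogonal to the long axis) and
#' the circumferential vector completes the right-handed triad.  The
#' orthonormal transform built from the triad rotates Cartesian strain
#' into anatomical components.
#'
#' @param mask logical array of wall voxels on `grid` (the reference
#'   configuration).
#' @param grid an [hr_grid()].
#' @return An object of class `anatomical_basis` with `e_r`, `e_c`, `e_z`
#'   (n_mask x 3 matrices), `mask` (possibly reduced: on-axis voxels are
#'   excluded), `long_axis` and `centroids`.
#' @export
build_anatomical_basis <- function(mask, grid) {
  pts <- grid_coords(grid)[as.vector(mask), , drop = FALSE]
  if (!nrow(pts)) stop("empty mask")
  ctr <- colMeans(pts)
  cv <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  ev <- eigen(cv, symmetric = TRUE)
  ez <- ev$vectors[, 1]
  if (ez[3] < 0) ez <- -ez
  s <- as.vector(pts %*% ez)               # axial coordinate
  # per-slab centroids along the axis, interpolated at voxel positions
  nb <- max(3L, min(24L, as.integer(round(diff(range(s)) /
                                            max(grid$spacing)))))
  br <- seq(min(s) - 1e-9, max(s) + 1e-9, length.out = nb + 1)
  bin <- findInterval(s, br, rightmost.closed = TRUE)
  cent_s <- (br[-1] + br[-(nb + 1)]) / 2
  cx <- tapply(pts[, 1], factor(bin, levels = seq_len(nb)), mean)
  cy <- tapply(pts[, 2], factor(bin, levels = seq_len(nb)), mean)
  cz <- tapply(pts[, 3], factor(bin, levels = seq_len(nb)), mean)
  keep <- !is.na(cx)
  cfun <- function(v) approx(cent_s[keep], v[keep], xout = s, rule = 2)$y
  cpts <- cbind(cfun(cx), cfun(cy), cfun(cz))
  v <- pts - cpts
  v <- v - outer(as.vector(v %*% ez), ez)  # remove axial component
  nv <- sqrt(rowSums(v^2))
  ok <- nv > 1e-9                          # on-axis voxels are undefined
  e_r <- v / pmax(nv, 1e-12)
  e_c <- cbind(ez[2] * e_r[, 3] - ez[3] * e_r[, 2],
               ez[3] * e_r[, 1] - ez[1] * e_r[, 3],
               ez[1] * e_r[, 2] - ez[2] * e_r[, 1])
  mask2 <- mask
  idx <- which(as.vector(mask))
  mask2[idx[!ok]] <- FALSE
  structure(list(e_r = e_r[ok, , drop = FALSE],
                 e_c = e_c[ok, , drop = FALSE],
                 e_z = matrix(ez, sum(ok), 3, byrow = TRUE),
                 mask = mask2, long_axis = ez,
                 centroids = cbind(s = cent_s[keep], x = cx[keep],
                                   y = cy[keep], z = cz[keep]),
                 axial = s[ok], points = pts[ok, , drop = FALSE]),
            class = "anatomical_basis")
}

#' Rotate Cartesian strain into anatomical components
#'
#' Computes `Q E Q^T` per masked voxel, with `Q` rows the radial,
#' circumferential and longitudinal unit vectors of the basis.  The
#' similarity transform preserves the trace and eigenvalues of `E`.
#'
#' @param E symmetric tensor field (from a `strain_field`'s `E`).
#' @param basis an [build_anatomical_basis()] result.
#' @return data.frame with one row per masked voxel: `E_RR`, `E_CC`,
#'   `E_ZZ`, `E_RC`, `E_RZ`, `E_CZ`.
#' @export
anatomical_strains <- function(E, basis) {
  m <- as.vector(basis$mask)
  comp <- function(a) as.vector(a)[m]
  e11 <- comp(E$E11); e22 <- comp(E$E22); e33 <- comp(E$E33)
  e12 <- comp(E$E12); e13 <- comp(E$E13); e23 <- comp(E$E23)
  quad <- function(a, b) {
    # a' E b for per-voxel vectors
    a[, 1] * (e11 * b[, 1] + e12 * b[, 2] + e13 * b[, 3]) +
      a[, 2] * (e12 * b[, 1] + e22 * b[, 2] + e23 * b[, 3]) +
      a[, 3] * (e13 * b[, 1] + e23 * b[, 2] + e33 * b[, 3])
  }
  data.frame(E_RR = quad(basis$e_r, basis$e_r),
             E_CC = quad(basis$e_c, basis$e_c),
             E_ZZ = quad(basis$e_z, basis$e_z),
             E_RC = quad(basis$e_r, basis$e_c),
             E_RZ = quad(basis$e_r, basis$e_z),
             E_CZ = quad(basis$e_c, basis$e_z))
}

#' Global longitudinal strain
#'
#' The mean of the voxelwise longitudinal strain over the myocardial
#' mask, per frame; zero at the reference frame by construction.
#'
#' @param strain_rcz_frames list (per frame) of [anatomical_strains()]
#'   data frames.
#' @return numeric vector, one GLS value per frame (unitless; multiply by
#'   100 for percent).
#' @export
gls <- function(strain_rcz_frames) {
  vapply(strain_rcz_frames, function(e) {
    if (!nrow(e)) stop("empty mask in GLS computation")
    mean(e$E_ZZ)
  }, numeric(1))
}

#' Flag non-physical strain voxels
#'
#' A voxel is non-physical when any anatomical component or any principal
#' strain exceeds the threshold in magnitude (default 50 %).
#'
#' @param e_rcz an [anatomical_strains()] data frame.
#' @param threshold strain magnitude limit (default 0.5).
#' @return list with `flag` (logical per voxel) and `fraction`.
#' @export
flag_nonphysical <- function(e_rcz, threshold = 0.5) {
  comp_max <- pmax(abs(e_rcz$E_RR), abs(e_rcz$E_CC), abs(e_rcz$E_ZZ),
                   abs(e_rcz$E_RC), abs(e_rcz$E_RZ), abs(e_rcz$E_CZ))
  pr <- principal_strains(e_rcz)
  flag <- comp_max > threshold | pr > threshold
  list(flag = flag, fraction = mean(flag))
}

# largest absolute eigenvalue of each symmetric 3x3 strain tensor
# (vectorized trigonometric solution)
principal_strains <- function(e) {
  a <- e$E_RR; b <- e$E_CC; c <- e$E_ZZ
  d <- e$E_RC; f <- e$E_CZ; g <- e$E_RZ
  p1 <- d^2 + g^2 + f^2
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  out <- numeric(length(a))
  z <- p < 1e-14
  out[z] <- pmax(abs(a[z]), abs(b[z]), abs(c[z]))
  if (any(!z)) {
    i <- !z
    # det of (E - qI)/p
    B11 <- (a[i] - q[i]) / p[i]; B22 <- (b[i] - q[i]) / p[i]
    B33 <- (c[i] - q[i]) / p[i]
    B12 <- d[i] / p[i]; B13 <- g[i] / p[i]; B23 <- f[i] / p[i]
    detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
      B13 * (B12 * B23 - B22 * B13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[i] + 2 * p[i] * cos(phi)
    e3 <- q[i] + 2 * p[i] * cos(phi + 2 * pi / 3)
    out[i] <- pmax(abs(e1), abs(e3))
  }
  out
}

#' AHA 16-segment map of the left-ventricular wall
#'
#' Splits the wall into equal basal/mid/apical thirds along the long axis
#' and into 6/6/4 angular sectors (segments 1-6 basal, 7-12 mid, 13-16
#' apical).  The angular reference (0 degrees) is the anterior wall (+y),
#' counterclockwise viewed from the apex.
#'
#' @param basis an [build_anatomical_basis()] result.
#' @param e_rcz an [anatomical_strains()] data frame on the same mask.
#' @param apex_high if `TRUE` the apical third is at high axial
#'   coordinate (default; the phantom's apex is at large z).
#' @return An object of class `aha_map` with `segment` (integer per
#'   masked voxel) and `table` (per-segment mean/SD per component).
#' @export
aha_segment <- function(basis, e_rcz, apex_high = TRUE) {
  s <- basis$axial
  sn <- (s - min(s)) / max(max(s) - min(s), 1e-12)
  if (!apex_high) sn <- 1 - sn
  third <- pmin(findInterval(sn, c(0, 1 / 3, 2 / 3), rightmost.closed = FALSE),
                3L)  # 1 basal, 2 mid, 3 apical
  # angle about the long axis, 0 at anterior (+y), counterclockwise
  ref <- c(0, 1, 0)
  ref <- ref - sum(ref * basis$long_axis) * basis$long_axis
  ref <- unit(ref)
  ref2 <- cross3(basis$long_axis, ref)
  ang <- atan2(basis$e_r %*% ref2, basis$e_r %*% ref) %% (2 * pi)
  seg <- integer(length(s))
  nsec <- c(6L, 6L, 4L)
  base_id <- c(0L, 6L, 12L)
  for (t in 1:3) {
    i <- third == t
    seg[i] <- base_id[t] + pmin(floor(ang[i] / (2 * pi / nsec[t])), nsec[t] - 1) + 1L
  }
  comps <- intersect(c("E_RR", "E_CC", "E_ZZ", "E_RC", "E_RZ", "E_CZ"),
                     names(e_rcz))
  tab <- do.call(rbind, lapply(sort(unique(seg)), function(sg) {
    i <- seg == sg
    row <- data.frame(segment = sg, n = sum(i))
    for (cmp in comps) {
      row[[paste0(cmp, "_mean")]] <- mean(e_rcz[[cmp]][i])
      row[[paste0(cmp, "_sd")]] <- sd(e_rcz[[cmp]][i])
    }
    row
  }))
  structure(list(segment = seg, table = tab, n_segments = length(unique(seg))),
            class = "aha_map")
}

#' @export
print.aha_map <- function(x, ...) {
  cat(sprintf("<aha_map> %d segments\n", x$n_segments))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
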