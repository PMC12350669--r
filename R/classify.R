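#' Ordered endo/epicardial contour stacks
#'
#' @param endo,epi lists of n x 3 world-coordinate matrices (mm), one
#'   closed ordered contour per slice level, ordered base to apex (or any
#'   consistent order along the long axis).
#' @param provenance `"manual_input"` or `"threshold_auto"`.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(endo, epi, provenance = "manual_input") {
  stopifnot(length(endo) == length(epi), length(endo) >= 1)
  for (i in seq_along(endo)) {
    for (cc in list(endo[[i]], epi[[i]])) {
      if (nrow(cc) < 8) stop("contour at level ", i, " has fewer than 8 points")
    }
    ce <- colMeans(endo[[i]])
    re <- sqrt(rowSums(sweep(endo[[i]][, 1:2, drop = FALSE], 2, ce[1:2])^2))
    rp <- sqrt(rowSums(sweep(epi[[i]][, 1:2, drop = FALSE], 2, ce[1:2])^2))
    if (max(re) > min(rp) + 1e-9 && median(re) > median(rp))
      stop("epicardial contour does not enclose endocardial contour at slice ", i)
  }
  structure(list(endo = endo, epi = epi, provenance = provenance),
            class = "contour_set")
}

# two-threshold (three-class) Otsu on a histogram
otsu3 <- function(x, n_bins = 128) {
  rng <- range(x)
  if (diff(rng) <= 0) return(NULL)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  total_mean <- cm[n_bins]
  best <- -Inf; t_best <- c(NA, NA)
  for (t1 in 1:(n_bins - 2)) {
    w1 <- cw[t1]
    if (w1 <= 0) next
    m1 <- cm[t1] / w1
    for (t2 in (t1 + 1):(n_bins - 1)) {
      w2 <- cw[t2] - cw[t1]
      w3 <- 1 - cw[t2]
      if (w2 <= 0 || w3 <= 0) next
      m2 <- (cm[t2] - cm[t1]) / w2
      m3 <- (total_mean - cm[t2]) / w3
      v <- w1 * (m1 - total_mean)^2 + w2 * (m2 - total_mean)^2 +
        w3 * (m3 - total_mean)^2
      if (v > best) { best <- v; t_best <- c(mids[t1], mids[t2]) }
    }
  }
  t_best
}

#' Three-class intensity classification of one cine frame
#'
#' Partitions every LR pixel of a frame into chamber (blood pool, class 1),
#' myocardium (class 2) and surroundings (class 3) by two intensity
#' thresholds chosen from the pooled frame histogram (three-class Otsu).
#' Class identity follows the bright-blood cine contrast ordering: the
#' chamber is brightest, the surroundings darkest.  If the histogram does
#' not resolve three populations the thresholds fall back to terciles with
#' a warning.
#'
#' @param stacks an [image_stack_set()].
#' @param frame 1-based frame index (`NULL` pools all frames for the
#'   thresholds but still labels every plane).
#' @param pooled if `TRUE`, class statistics are pooled over the cycle
#'   instead of per frame.
#' @return An object of class `tissue_class_map`: `labels` (list of
#'   integer matrices aligned with the frame's planes), `plane_index`
#'   (indices into `stacks$planes`), `stats` (per-class mean/sd), and the
#'   `thresholds`.
#' @export
classify_by_histogram <- function(stacks, frame = 1, pooled = FALSE) {
  idx <- if (is.null(frame)) seq_along(stacks$planes) else
    which(vapply(stacks$planes, function(p) p$frame_index, integer(1)) == frame)
  if (!length(idx)) stop("no planes for frame ", frame)
  pool_idx <- if (pooled) seq_along(stacks$planes) else idx
  vals <- unlist(lapply(stacks$planes[pool_idx], function(p) as.vector(p$pixels)))
  if (diff(range(vals)) <= .Machine$double.eps * max(abs(vals), 1)) {
    warning("degenerate intensity range: single class (all surroundings)")
    thr <- c(Inf, Inf)
  } else {
    thr <- otsu3(vals)
    if (is.null(thr) || anyNA(thr)) {
      warning("histogram does not resolve three classes; quantile fallback")
      thr <- as.numeric(quantile(vals, c(1 / 3, 2 / 3)))
    } else {
      # degenerate (empty-class) solution: tercile fallback
      n1 <- sum(vals <= thr[1]); n2 <- sum(vals > thr[1] & vals <= thr[2])
      n3 <- sum(vals > thr[2])
      if (min(n1, n2, n3) == 0) {
        warning("histogram does not resolve three classes; quantile fallback")
        thr <- as.numeric(quantile(vals, c(1 / 3, 2 / 3)))
      }
    }
  }
  lab_of <- function(px) {
    l <- matrix(3L, nrow(px), ncol(px))        # surroundings
    l[px > thr[1]] <- 2L                       # myocardium
    l[px > thr[2]] <- 1L                       # chamber
    l
  }
  labels <- lapply(stacks$planes[idx], function(p) lab_of(p$pixels))
  sv <- unlist(lapply(stacks$planes[pool_idx], function(p) as.vector(p$pixels)))
  sl <- unlist(lapply(stacks$planes[pool_idx], function(p) as.vector(lab_of(p$pixels))))
  stats <- do.call(rbind, lapply(1:3, function(j) {
    v <- sv[sl == j]
    data.frame(class = j,
               name = c("chamber", "myocardium", "surroundings")[j],
               mu = if (length(v)) mean(v) else NA_real_,
               sigma = if (length(v)) sd(v) else NA_real_,
               n = length(v))
  }))
  structure(list(labels = labels, plane_index = idx, stats = stats,
                 thresholds = thr, frame = frame),
            class = "tissue_class_map")
}

#' @export
print.tissue_class_map <- function(x, ...) {
  cat("<tissue_class_map> thresholds:",
      paste(fmt_num(x$thresholds), collapse = ", "), "\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

# polyharmonic RBF smoother for radius-vs-(angle, z) surfaces; periodic in
# angle via (cos, sin) embedding.  `scale` is the kernel length scale,
# `ridge` the smoothing weight.
rbf_smooth_radius <- function(theta, z, r, scale, ridge) {
  emb <- cbind(cos(theta), sin(theta), z / scale)
  d <- as.matrix(dist(emb))
  k <- d^3                      # polyharmonic (thin-plate family) kernel
  n <- length(r)
  A <- rbind(cbind(k + ridge * diag(n), 1), c(rep(1, n), 0))
  w <- solve(A, c(r, 0))
  list(emb = emb, w = w, scale = scale)
}

rbf_eval_radius <- function(model, theta, z) {
  emb <- cbind(cos(theta), sin(theta), z / model$scale)
  n <- nrow(model$emb)
  d2 <- outer(rowSums(emb^2), rep(1, n)) +
    outer(rep(1, nrow(emb)), rowSums(model$emb^2)) -
    2 * emb %*% t(model$emb)
  d <- sqrt(pmax(d2, 0))
  as.vector(d^3 %*% model$w[1:n] + model$w[n + 1])
}

#' Resample 2D contours into smooth 3D iso-surfaces
#'
#' Each contour level is resampled at uniform angles about its centroid,
#' levels are stitched by triangulating consecutive rings, and the radius
#' field r(angle, z) is smoothed with a polyharmonic radial-basis-function
#' regression whose length scale follows the inter-slice spacing, limiting
#' the effect of through-plane anisotropy on the segmentation.
#'
#' @param contours a [contour_set()].
#' @param n_theta angular resampling count.
#' @param smoothing RBF ridge weight (0 disables smoothing).
#' @return An object of class `iso_surface`: smoothed radius matrices
#'   (`z` levels x `n_theta`) for endo and epi, per-level centroids, the
#'   angle/level grids, and a triangle mesh per surface.
#' @export
contours_to_surface <- function(contours, n_theta = 72, smoothing = 1e-3) {
  stopifnot(inherits(contours, "contour_set"))
  n_lev <- length(contours$endo)
  if (n_lev < 2) stop("need at least 2 contour levels per surface")
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  resample <- function(cc, centroid) {
    th <- atan2(cc[, 2] - centroid[2], cc[, 1] - centroid[1])
    rr <- sqrt((cc[, 1] - centroid[1])^2 + (cc[, 2] - centroid[2])^2)
    o <- order(th)
    th <- th[o]; rr <- rr[o]
    th_ext <- c(th - 2 * pi, th, th + 2 * pi)
    rr_ext <- rep(rr, 3)
    approx(th_ext, rr_ext, xout = theta, rule = 2)$y
  }
  z_lev <- vapply(contours$endo, function(cc) mean(cc[, 3]), numeric(1))
  cent <- t(vapply(contours$endo, colMeans, numeric(3)))
  # crossing check
  for (i in seq_len(n_lev)) {
    re <- resample(contours$endo[[i]], cent[i, ])
    rp <- resample(contours$epi[[i]], cent[i, ])
    if (any(re >= rp))
      stop("endo/epi contours cross at slice index ", i)
  }
  fit_surface <- function(lst) {
    rmat <- t(vapply(seq_len(n_lev), function(i)
      resample(lst[[i]], cent[i, ]), numeric(n_theta)))
    if (smoothing > 0) {
      dz <- if (n_lev > 1) mean(diff(sort(z_lev))) else 1
      th_all <- rep(theta, each = n_lev)
      z_all <- rep(z_lev, times = n_theta)
      model <- rbf_smooth_radius(th_all, z_all, as.vector(rmat),
                                 scale = max(dz, 1e-6),
                                 ridge = smoothing * n_lev * n_theta)
      rmat <- matrix(rbf_eval_radius(model, th_all, z_all), n_lev, n_theta)
    }
    rmat
  }
  r_endo <- fit_surface(contours$endo)
  r_epi <- fit_surface(contours$epi)
  mesh <- function(rmat) {
    verts <- do.call(rbind, lapply(seq_len(n_lev), function(i)
      cbind(cent[i, 1] + rmat[i, ] * cos(theta),
            cent[i, 2] + rmat[i, ] * sin(theta), z_lev[i])))
    faces <- NULL
    for (i in seq_len(n_lev - 1)) {
      a <- (i - 1) * n_theta + seq_len(n_theta)
      b <- i * n_theta + seq_len(n_theta)
      an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
      faces <- rbind(faces, cbind(a, b, bn), cbind(a, bn, an))
    }
    list(vertices = verts, faces = faces)
  }
  structure(list(theta = theta, z_levels = z_lev, centroids = cent,
                 r_endo = r_endo, r_epi = r_epi,
                 endo_mesh = mesh(r_endo), epi_mesh = mesh(r_epi),
                 smoothing = smoothing),
            class = "iso_surface")
}

#' @export
print.iso_surface <- function(x, ...) {
  cat(sprintf("<iso_surface> %d levels x %d angles, z in [%s, %s] mm\n",
              length(x$z_levels), length(x$theta),
              fmt_num(min(x$z_levels)), fmt_num(max(x$z_levels))))
  invisible(x)
}

# bilinear lookup of the surface radius at (theta, z); clamped in z
surface_radius_at <- function(surface, which, theta, z) {
  rmat <- surface[[which]]
  zl <- surface$z_levels
  th_grid <- surface$theta
  n_th <- length(th_grid)
  dth <- 2 * pi / n_th
  ti <- (theta %% (2 * pi)) / dth
  i0 <- floor(ti); ft <- ti - i0
  i0 <- (as.integer(i0) %% n_th) + 1L
  i1 <- (i0 %% n_th) + 1L
  zi <- approx(zl, seq_along(zl), xout = pmin(pmax(z, min(zl)), max(zl)))$y
  k0 <- pmin(floor(zi), length(zl) - 1); fz <- zi - k0
  k0 <- as.integer(k0); k1 <- k0 + 1L
  r00 <- rmat[cbind(k0, i0)]; r01 <- rmat[cbind(k0, i1)]
  r10 <- rmat[cbind(k1, i0)]; r11 <- rmat[cbind(k1, i1)]
  (r00 * (1 - ft) + r01 * ft) * (1 - fz) + (r10 * (1 - ft) + r11 * ft) * fz
}

#' Voxelize iso-surfaces into a tissue label volume
#'
#' Voxel centres strictly inside the endocardial surface are chamber,
#' between endo and epi (boundaries inclusive: a point exactly on a
#' surface is myocardium) are myocardium, outside the epicardial surface
#' or beyond the surface z-range are surroundings.
#'
#' @param surface an [contours_to_surface()] result.
#' @param grid an [hr_grid()].
#' @return list with `labels` (integer array: 1 chamber, 2 myocardium,
#'   3 surroundings) and `n_outside_range` (voxels beyond the covered
#'   z-range, all labelled surroundings).
#' @export
surface_to_labels <- function(surface, grid) {
  pts <- grid_coords(grid)
  z <- pts[, 3]
  inz <- z >= min(surface$z_levels) - 1e-9 & z <= max(surface$z_levels) + 1e-9
  lab <- rep(3L, nrow(pts))
  if (any(inz)) {
    cx <- approx(surface$z_levels, surface$centroids[, 1], xout = z[inz],
                 rule = 2)$y
    cy <- approx(surface$z_levels, surface$centroids[, 2], xout = z[inz],
                 rule = 2)$y
    dx <- pts[inz, 1] - cx; dy <- pts[inz, 2] - cy
    rho <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    re <- surface_radius_at(surface, "r_endo", th, z[inz])
    rp <- surface_radius_at(surface, "r_epi", th, z[inz])
    li <- rep(3L, sum(inz))
    li[rho < re] <- 1L
    li[rho >= re & rho <= rp] <- 2L
    lab[inz] <- li
  }
  list(labels = array(lab, dim = grid$shape), n_outside_range = sum(!inz))
}
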