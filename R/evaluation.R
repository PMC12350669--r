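#' Strain-accuracy MSE time courses against phantom ground truth
#'
#' Mean squared error between estimated and ground-truth anatomical
#' strain over the masked wall, per frame, per component, at each of the
#' basal/mid/apical levels and overall.  Strains are expressed on the
#' percent scale before squaring (`MSE = mean((100 dE)^2)`), matching the
#' convention in which errors "under 10" correspond to strain
#' discrepancies of about 3 percent RMS.
#'
#' @param est_frames list (per frame) of [anatomical_strains()] data
#'   frames on `basis`'s mask.
#' @param truth a [phantom_truth()] result on the same grid.
#' @param basis the [build_anatomical_basis()] used for the estimates.
#' @param components strain components to score.
#' @return data.frame with columns `frame`, `level`
#'   (`basal`/`mid`/`apical`/`all`), `component`, `mse` (percent^2 scale).
#' @export
strain_mse_timecourse <- function(est_frames, truth, basis,
                                  components = c("E_RR", "E_CC", "E_ZZ")) {
  mvec <- as.vector(basis$mask)
  sn <- (basis$axial - min(basis$axial)) /
    max(diff(range(basis$axial)), 1e-12)
  level_all <- c("basal", "mid", "apical")[pmin(findInterval(
    sn, c(0, 1 / 3, 2 / 3)), 3L)]
  out <- NULL
  for (f in seq_along(est_frames)) {
    for (cmp in components) {
      tv <- as.vector(truth$frames[[f]][[cmp]])[mvec]
      ev <- est_frames[[f]][[cmp]]
      ok <- !is.na(tv)
      if (!any(ok)) stop("mask/level mismatch: no overlap with ground truth")
      d2 <- (100 * (ev[ok] - tv[ok]))^2
      level <- level_all[ok]
      rows <- data.frame(frame = f,
                         level = c("basal", "mid", "apical", "all"),
                         component = cmp,
                         mse = c(vapply(c("basal", "mid", "apical"),
                                        function(l) mean(d2[level == l]),
                                        numeric(1)),
                                 mean(d2)))
      out <- rbind(out, rows)
    }
  }
  rownames(out) <- NULL
  out
}

#' End-systolic summary of an MSE time course
#' @param report a [strain_mse_timecourse()] data frame.
#' @param es_frame 1-based ES frame index.
#' @param level which level to summarize (default the mean over
#'   basal/mid/apical, as reported for ES accuracy).
#' @return named vector of per-component ES MSE.
#' @export
es_mse <- function(report, es_frame, level = c("mean_levels", "all")) {
  level <- match.arg(level)
  r <- report[report$frame == es_frame, ]
  comps <- unique(r$component)
  vapply(comps, function(cmp) {
    if (level == "all") r$mse[r$component == cmp & r$level == "all"]
    else mean(r$mse[r$component == cmp & r$level != "all"])
  }, numeric(1))
}

#' Structural similarity index between two images
#'
#' Gaussian-windowed SSIM (window sigma 1.5, kernel radius 3 — a 7-pixel
#' support) with the standard stabilization constants on a dynamic range
#' of 1; inputs are expected on a common [0, 1] normalization.
#'
#' @param a,b intensity matrices of equal shape.
#' @param sigma window sigma in pixels.
#' @return scalar mean SSIM.
#' @export
ssim <- function(a, b, sigma = 1.5) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_a <- cpp_gauss_blur2(a, sigma)
  mu_b <- cpp_gauss_blur2(b, sigma)
  va <- cpp_gauss_blur2(a * a, sigma) - mu_a^2
  vb <- cpp_gauss_blur2(b * b, sigma) - mu_b^2
  cab <- cpp_gauss_blur2(a * b, sigma) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Image-quality report: SSIM and RMS per reconstructed plane
#'
#' Each pair is normalized jointly to [0, 1]; SSIM and root-mean-square
#' error are reported per plane with means and SDs.
#'
#' @param rec_planes,ref_planes lists of matched intensity matrices.
#' @return data.frame (`plane`, `ssim`, `rms`) with attributes
#'   `mean_ssim`, `sd_ssim`, `mean_rms`, `sd_rms`.
#' @export
image_quality <- function(rec_planes, ref_planes) {
  if (length(rec_planes) != length(ref_planes))
    stop("plane lists must be matched")
  rows <- do.call(rbind, lapply(seq_along(rec_planes), function(i) {
    a <- rec_planes[[i]]; b <- ref_planes[[i]]
    if (!all(dim(a) == dim(b))) stop("plane ", i, " shape mismatch")
    lo <- min(a, b); hi <- max(a, b)
    if (hi > lo) { a <- (a - lo) / (hi - lo); b <- (b - lo) / (hi - lo) }
    data.frame(plane = i, ssim = ssim(a, b),
               rms = sqrt(mean((a - b)^2)))
  }))
  attr(rows, "mean_ssim") <- mean(rows$ssim)
  attr(rows, "sd_ssim") <- sd(rows$ssim)
  attr(rows, "mean_rms") <- mean(rows$rms)
  attr(rows, "sd_rms") <- sd(rows$rms)
  rows
}

#' Slice-protocol ablation on one phantom
#'
#' Runs the full reconstruction-registration-strain pipeline for each
#' (n_SA, n_LA, sampling) configuration on a shared phantom and reports
#' the end-systolic strain MSE per component.  A configuration with
#' `n_la = 0` is handled as the conventional SA-only baseline.
#'
#' @param configs data.frame with columns `n_sa`, `n_la`, `sampling`
#'   (`"orthogonal"` or `"radial"`).
#' @param phantom a [generate_phantom()] object.
#' @param ... passed to [run_pipeline()] (e.g. `pixel_spacing`,
#'   `srr = srr_params(...)`).
#' @return data.frame with one row per configuration and the ES MSE of
#'   each strain component, ordered as given.
#' @export
ablation <- function(configs, phantom, ...) {
  if (nrow(configs) < 2) stop("need at least 2 configurations")
  if (any(configs$n_sa <= 0)) stop("configurations need at least one SA slice")
  out <- NULL
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    res <- run_pipeline(phantom = phantom, n_sa = cf$n_sa, n_la = cf$n_la,
                        la_mode = as.character(cf$sampling),
                        reconstruction = if (cf$n_la == 0) "lr" else "srr",
                        ...)
    e <- res$es_mse
    out <- rbind(out, data.frame(n_sa = cf$n_sa, n_la = cf$n_la,
                                 sampling = as.character(cf$sampling),
                                 mse_E_RR = e[["E_RR"]],
                                 mse_E_CC = e[["E_CC"]],
                                 mse_E_ZZ = e[["E_ZZ"]]))
  }
  out
}

#' Cohort homogeneity: per-segment coefficient of variation
#'
#' Across-subject SD, mean and CV (= SD/mean, keeping the sign of the
#' mean) of a strain component per AHA segment, optionally with a paired
#' t-test of SR versus LR per-segment values.
#'
#' @param aha_maps list of [aha_segment()] results, one per subject.
#' @param aha_maps_ref optional matched list from the comparison pipeline
#'   (paired test SR vs reference).
#' @param component strain component (default longitudinal).
#' @return list with `per_segment` (data.frame: segment, mean, sd, cv)
#'   and, when a reference is given, `paired_test` (t statistic, p value,
#'   confidence interval) and `per_segment_ref`.
#' @export
cohort_cv <- function(aha_maps, aha_maps_ref = NULL, component = "E_ZZ") {
  if (length(aha_maps) < 2) stop("need at least 2 subjects")
  col <- paste0(component, "_mean")
  seg_matrix <- function(maps) {
    segs <- sort(unique(unlist(lapply(maps, function(m) m$table$segment))))
    mat <- sapply(maps, function(m)
      m$table[[col]][match(segs, m$table$segment)])
    rownames(mat) <- segs
    mat
  }
  m <- seg_matrix(aha_maps)
  per_seg <- data.frame(segment = as.integer(rownames(m)),
                        mean = rowMeans(m),
                        sd = apply(m, 1, sd))
  per_seg$cv <- ifelse(abs(per_seg$mean) > 1e-12,
                       per_seg$sd / per_seg$mean, NA_real_)
  out <- list(per_segment = per_seg)
  if (!is.null(aha_maps_ref)) {
    m2 <- seg_matrix(aha_maps_ref)
    x <- rowMeans(m); y <- rowMeans(m2)
    tt <- t.test(x, y, paired = TRUE)
    per2 <- data.frame(segment = as.integer(rownames(m2)),
                       mean = rowMeans(m2), sd = apply(m2, 1, sd))
    per2$cv <- ifelse(abs(per2$mean) > 1e-12, per2$sd / per2$mean, NA_real_)
    out$per_segment_ref <- per2
    out$paired_test <- list(statistic = unname(tt$statistic),
                            p_value = tt$p.value,
                            conf_int = as.numeric(tt$conf.int))
  }
  out
}
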