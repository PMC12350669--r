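#' Write a multi-view slice stack to disk (json_array dialect)
#'
#' The json_array dialect is a plain-text exchange format: one JSON header
#' (`stack.json`) carrying the full per-plane geometry, plus one
#' whitespace-delimited text matrix per plane.  Geometry round-trips to
#' better than 1e-6 mm and intensities bit-exactly.
#'
#' @param stacks an [image_stack_set()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stacks, path) {
  stopifnot(inherits(stacks, "image_stack_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "srrcmr-json-array", version = 1L,
               n_frames = stacks$n_frames, rr_interval = stacks$rr_interval,
               planes = lapply(seq_along(stacks$planes), function(i) {
                 p <- stacks$planes[[i]]
                 list(file = sprintf("plane_%04d.txt", i),
                      shape = dim(p$pixels),
                      origin = p$origin, row_dir = p$row_dir,
                      col_dir = p$col_dir, pixel_spacing = p$pixel_spacing,
                      thickness = p$thickness, trigger_time = p$trigger_time,
                      frame_index = p$frame_index, view_label = p$view_label)
               }))
  jsonlite::write_json(meta, file.path(path, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(stacks$planes)) {
    px <- stacks$planes[[i]]$pixels
    lines <- apply(px, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " "))
    writeLines(lines, file.path(path, sprintf("plane_%04d.txt", i)))
  }
  invisible(path)
}

#' Read a multi-view slice stack
#'
#' @param path directory written by [write_stack()] (json_array dialect)
#'   or a NIfTI file (nifti dialect; one volume read back as parallel SA
#'   planes using the image affine).
#' @param dialect `"json_array"` or `"nifti"`.
#' @return An [image_stack_set()].
#' @export
read_stack <- function(path, dialect = c("json_array", "nifti")) {
  dialect <- match.arg(dialect)
  if (dialect == "json_array") {
    hdr_file <- file.path(path, "stack.json")
    if (!file.exists(hdr_file)) stop("missing stack.json header in ", path)
    meta <- jsonlite::read_json(hdr_file, simplifyVector = TRUE)
    need <- c("origin", "row_dir", "col_dir", "pixel_spacing")
    planes <- lapply(seq_len(nrow(meta$planes)), function(i) {
      m <- meta$planes[i, ]
      for (f in need)
        if (is.null(m[[f]][[1]]) || anyNA(m[[f]][[1]]))
          stop("plane ", i, " is missing orientation metadata field '", f, "'")
      px <- as.matrix(read.table(file.path(path, m$file)))
      dimnames(px) <- NULL
      slice_plane(px, origin = m$origin[[1]], row_dir = m$row_dir[[1]],
                  col_dir = m$col_dir[[1]],
                  pixel_spacing = m$pixel_spacing[[1]],
                  thickness = m$thickness, trigger_time = m$trigger_time,
                  frame_index = m$frame_index, view_label = m$view_label)
    })
    image_stack_set(planes, rr_interval = meta$rr_interval)
  } else {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) < 3) stop("nifti stack must be a 3D (or 3D+t) volume")
    aff <- RNifti::xform(img)
    sp <- sqrt(colSums(aff[1:3, 1:3]^2))
    row_dir <- unit(aff[1:3, 2])  # rows index the second array axis here
    col_dir <- unit(aff[1:3, 1])
    n_frames <- if (length(d) >= 4) d[4] else 1L
    planes <- list()
    for (f in seq_len(n_frames)) {
      for (k in seq_len(d[3])) {
        px <- if (length(d) >= 4) t(img[, , k, f]) else t(img[, , k])
        origin <- as.numeric(aff %*% c(0, 0, k - 1, 1))[1:3]
        planes[[length(planes) + 1L]] <-
          slice_plane(px, origin = origin, row_dir = row_dir,
                      col_dir = col_dir, pixel_spacing = c(sp[2], sp[1]),
                      thickness = sp[3], frame_index = f, view_label = "SA")
      }
    }
    image_stack_set(planes)
  }
}

#' Write a reconstructed volume as NIfTI-1
#'
#' @param volume 3D array on `grid`.
#' @param grid the [hr_grid()] the volume lives on.
#' @param path output file (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, grid, path) {
  aff <- diag(4)
  aff[1, 1] <- grid$spacing[1]; aff[2, 2] <- grid$spacing[2]
  aff[3, 3] <- grid$spacing[3]
  aff[1:3, 4] <- grid$origin
  img <- RNifti::asNifti(volume)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export scattered points with attached scalars as a legacy VTK file
#'
#' Plain-text (ASCII) unstructured-grid export of phantom ground truth or
#' reconstruction samples for visual QC in ParaView.
#'
#' @param points n x 3 matrix (mm).
#' @param scalars named list of length-n numeric vectors.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk_points <- function(points, scalars, path) {
  n <- nrow(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "srrcmr export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(points, 1, function(p)
    paste(formatC(p, format = "g", digits = 9), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", n, 2 * n), con)
  writeLines(paste("1", seq_len(n) - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", n), con)
  writeLines(rep("1", n), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(formatC(scalars[[nm]], format = "g", digits = 9), con)
  }
  invisible(path)
}
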