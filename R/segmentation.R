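#' Sum-project a Z-stack
#'
#' Collapses each channel of a 3-D stack to a 2-D image by summing all
#' optical sections per pixel. Summation comes first in the quantification
#' workflow: segmentation and all intensity measurements operate on the
#' projection. Accumulation is in double precision, so 16-bit input cannot
#' saturate.
#'
#' @param field An [image_field()].
#' @return A `projected_field`: per-channel 2-D sum images plus the number of
#'   sections summed (`n_sections`).
#' @export
sum_project <- function(field) {
  if (!inherits(field, "image_field")) abort("`field` must be an image_field.")
  d <- dim(field$data)
  proj <- array(0, c(d[1L], d[3L], d[4L]))
  for (ch in seq_len(d[1L])) {
    sl <- field$data[ch, , , , drop = FALSE]
    dim(sl) <- d[-1L]
    proj[ch, , ] <- colSums(sl, dims = 1L)
  }
  structure(
    list(data = proj, channel_names = field$channel_names,
         n_sections = d[2L]),
    class = "projected_field"
  )
}

#' @export
print.projected_field <- function(x, ...) {
  d <- dim(x$data)
  cat("<projected_field> ", d[2L], " x ", d[3L], " px (sum of ", x$n_sections,
      " sections), channels: ", paste(x$channel_names, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`. Otsu is computed
#'   on the 256-bin histogram of the combined cytosolic projection over its
#'   own range, which makes the foreground decision invariant to a constant
#'   offset added to all channels.
#' @param fixed_threshold Threshold in summed-projection ADU, used when
#'   `threshold_method = "fixed"`.
#' @param hysteresis_fraction Position of the lower hysteresis cut between
#'   the image median (background) and the seed threshold, in (0, 1]
#'   (default 0.1). Only used with Otsu thresholding.
#' @param min_object_pixels Objects smaller than this are discarded before
#'   labelling (default 100; a speck filter, distinct from the biological
#'   2400-pixel volume filter applied later).
#' @param wall_width Width of the cell-wall ring in projected pixels
#'   (default 3, roughly 200 nm at the 65 nm/pixel scale of a 100x
#'   objective on an sCMOS camera).
#' @param split_touching Split touching cells by distance-transform watershed
#'   (default `TRUE`).
#' @param watershed_tolerance Minimum distance-map depth between two maxima
#'   for them to seed separate objects (default 1).
#' @param exclude_border Drop cells touching the image border, whose wall
#'   ring would be truncated (default `TRUE`).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                hysteresis_fraction = 0.1,
                                min_object_pixels = 100L, wall_width = 3L,
                                split_touching = TRUE,
                                watershed_tolerance = 1,
                                exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    abort("`fixed_threshold` is required when threshold_method = 'fixed'.")
  }
  if (hysteresis_fraction <= 0 || hysteresis_fraction > 1) {
    abort("`hysteresis_fraction` must lie in (0, 1].")
  }
  if (min_object_pixels < 1L) abort("`min_object_pixels` must be >= 1.")
  if (wall_width < 1L) abort("`wall_width` must be >= 1 pixel.")
  structure(
    list(threshold_method = threshold_method, fixed_threshold = fixed_threshold,
         hysteresis_fraction = hysteresis_fraction,
         min_object_pixels = as.integer(min_object_pixels),
         wall_width = wall_width, split_touching = isTRUE(split_touching),
         watershed_tolerance = watershed_tolerance,
         exclude_border = isTRUE(exclude_border)),
    class = "segmentation_params"
  )
}

# Relabel a label matrix 1..k in raster scan order (top-left first).
relabel_raster <- function(labels) {
  old <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(old) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  ny <- nrow(labels); nx <- ncol(labels)
  pos <- which(labels > 0L)
  row <- (pos - 1L) %% ny + 1L
  col <- (pos - 1L) %/% ny + 1L
  raster <- (row - 1L) * nx + col
  first <- vapply(old, function(k) min(raster[labels[pos] == k]), 0)
  new_of_old <- integer(max(old))
  new_of_old[old[order(first)]] <- seq_along(old)
  out <- matrix(0L, ny, nx)
  out[pos] <- new_of_old[labels[pos]]
  out
}

#' Segment cells from the cytosolic channels
#'
#' Every cell carries exactly one cytosolic marker (Citrin in the reference
#' strain, CFP in testers), so the pixel-wise sum of the two cytosolic
#' projections is a cell-filled image. Because the marker is cytosolic it is
#' excluded from the wall itself, and its projected intensity tapers toward
#' the cell rim; a single global cut would clip both. Segmentation therefore
#' proceeds in three steps: (1) hysteresis thresholding — confident seed
#' pixels above the Otsu (or fixed) threshold are extended into every
#' connected pixel above a lower cut interpolated between the image median
#' (the background level) and the seed threshold; (2) hole filling, optional
#' distance-transform watershed splitting of touching cells, and speck
#' removal; (3) each cytosol mask is grown outward by `wall_width` pixels
#' (Euclidean dilation, nearest-cell wins, lower label wins ties) to
#' reconstruct the cell outline including the marker-free wall annulus.
#' Border-touching cells are optionally dropped and labels are assigned in
#' raster order (top-left object first), so repeated runs are bit-identical.
#'
#' @param proj A `projected_field` from [sum_project()].
#' @param params A [segmentation_params()].
#' @return A 2-D integer label matrix; 0 is background, labels are
#'   consecutive from 1. An all-background image yields an all-zero matrix.
#' @export
segment_cells <- function(proj, params = segmentation_params()) {
  if (!inherits(proj, "projected_field")) {
    abort("`proj` must be a projected_field (see sum_project()).")
  }
  combined <- get_channel(proj, "Citrin") + get_channel(proj, "CFP")
  empty <- matrix(0L, nrow(combined), ncol(combined))
  if (params$threshold_method == "otsu") {
    rng <- range(combined)
    if (rng[1L] == rng[2L]) return(empty)
    th_high <- EBImage::otsu(combined, range = rng, levels = 256L)
    bg <- median(combined)
    th_low <- if (th_high > bg) bg + params$hysteresis_fraction * (th_high - bg)
      else th_high
  } else {
    th_high <- params$fixed_threshold
    th_low <- th_high
  }
  seeds <- combined > th_high
  if (!any(seeds)) return(empty)
  ext <- EBImage::bwlabel((combined > th_low) + 0)
  keep <- setdiff(unique(ext[seeds]), 0L)
  fg <- matrix(ext %in% keep, nrow(ext), ncol(ext))
  fg <- EBImage::fillHull(fg + 0) > 0
  if (params$split_touching) {
    labels <- EBImage::watershed(EBImage::distmap(fg + 0),
                                 tolerance = params$watershed_tolerance)
  } else {
    labels <- EBImage::bwlabel(fg + 0)
  }
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  labels <- grow_labels(labels, params$wall_width + 0.25)
  sizes <- tabulate(labels[labels > 0L])
  drop <- which(sizes < params$min_object_pixels)
  if (params$exclude_border) {
    edge <- c(labels[1L, ], labels[nrow(labels), ],
              labels[, 1L], labels[, ncol(labels)])
    drop <- union(drop, setdiff(unique(edge), 0L))
  }
  if (length(drop) > 0L) labels[labels %in% drop] <- 0L
  relabel_raster(labels)
}

# Grow every labeled object outward by `width` pixels (Euclidean criterion).
# Background pixels within `width` of several objects go to the nearest one;
# exact ties go to the lower label. Existing object pixels are never
# reassigned.
grow_labels <- function(labels, width) {
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(labs) == 0L || width <= 0) return(labels)
  out <- labels
  best <- matrix(Inf, nrow(labels), ncol(labels))
  for (k in labs) {
    dm <- EBImage::distmap((labels != k) + 0)  # distance to object k
    cand <- labels == 0L & dm <= width & dm < best
    out[cand] <- k
    best[cand] <- dm[cand]
  }
  out
}

#' Segment the cell wall as a peripheral ring
#'
#' For each labelled cell, the wall is the band of pixels lying within
#' `wall_width` of the cell boundary under the Euclidean distance transform
#' (pixels whose distance to the nearest background pixel is `<= wall_width`);
#' the interior is the remainder. This Euclidean erosion criterion is
#' rotation-invariant, unlike a square structuring element. Cells whose
#' interior would be empty are flagged degenerate and excluded from
#' measurement.
#'
#' @param labels 2-D integer label matrix from [segment_cells()].
#' @param wall_width Ring width in pixels (>= 1).
#' @return A `wall_segmentation`: the label matrix, a logical `wall_mask`
#'   (TRUE on every wall pixel of every cell), the labels present, the
#'   degenerate labels, and `wall_width`.
#' @export
segment_wall <- function(labels, wall_width = 3) {
  if (wall_width <= 0) abort("`wall_width` must be positive.")
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  wall_mask <- matrix(FALSE, nrow(labels), ncol(labels))
  degenerate <- integer(0)
  for (k in labs) {
    mask <- labels == k
    dm <- EBImage::distmap(mask + 0)
    wall_k <- mask & dm <= wall_width
    if (!any(mask & !wall_k)) degenerate <- c(degenerate, k)
    wall_mask[wall_k] <- TRUE
  }
  structure(
    list(labels = labels, wall_mask = wall_mask, cell_ids = labs,
         degenerate = degenerate, wall_width = wall_width),
    class = "wall_segmentation"
  )
}

#' @export
print.wall_segmentation <- function(x, ...) {
  cat("<wall_segmentation> ", length(x$cell_ids), " cell(s), wall width ",
      x$wall_width, " px", sep = "")
  if (length(x$degenerate) > 0L) {
    cat(", degenerate: ", paste(x$degenerate, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

# Pixel index sets for one cell's wall and interior.
region_pixels <- function(seg, label) {
  cell <- seg$labels == label
  wall <- cell & seg$wall_mask
  list(wall = which(wall), interior = which(cell & !wall))
}
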