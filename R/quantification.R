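#' Classification parameters
#'
#' Thresholds for assigning strain identity from the cytosolic markers, and
#' the interior-size filter, both expressed in summed-projection ADU /
#' projected pixels. The defaults are the workflow's published operating
#' point: cells with an interior between 2400 and 55,000 pixels (closed
#' interval) are analyzed, and identity requires the correct cytosolic
#' channel's interior maximum above 200 ADU with the other below 200 ADU.
#'
#' @param cfp_threshold CFP interior-maximum threshold, ADU (default 200).
#' @param citrin_threshold Citrin interior-maximum threshold, ADU
#'   (default 200).
#' @param volume_min,volume_max Interior pixel-count filter bounds
#'   (defaults 2400 and 55000, inclusive).
#' @param swap_identity_channels If `TRUE`, invert the channel-to-identity
#'   mapping (reference = CFP-high instead of Citrin-high). The default
#'   mapping follows the strain design: the reference strain expresses
#'   cytosolic Citrin and tester strains cytosolic CFP.
#' @return A `classification_params` list.
#' @export
classification_params <- function(cfp_threshold = 200, citrin_threshold = 200,
                                  volume_min = 2400, volume_max = 55000,
                                  swap_identity_channels = FALSE) {
  if (cfp_threshold <= 0 || citrin_threshold <= 0) {
    abort("Identity thresholds must be positive.")
  }
  if (volume_min >= volume_max) abort("`volume_min` must be below `volume_max`.")
  structure(
    list(cfp_threshold = cfp_threshold, citrin_threshold = citrin_threshold,
         volume_min = volume_min, volume_max = volume_max,
         swap_identity_channels = isTRUE(swap_identity_channels)),
    class = "classification_params"
  )
}

#' Measure one segmented cell
#'
#' Computes the full intensity accounting of the workflow's measurement step:
#' pixel counts and exact min / max / integral of every channel over the wall
#' ring and the interior, plus the per-cell statistic `mean_wall_mcherry`
#' (integral wall mCherry divided by the wall pixel count). Identity is left
#' `"unclassified"`; see [classify_identity()].
#'
#' @param proj A `projected_field` from [sum_project()].
#' @param seg A `wall_segmentation` from [segment_wall()].
#' @param label Cell label to measure; must be present and non-degenerate.
#' @param field_id Identifier recorded in the output row.
#' @return A one-row tibble (a cell record).
#' @export
measure_cell <- function(proj, seg, label, field_id = "field") {
  if (!label %in% seg$cell_ids) {
    abort(paste0("Label ", label, " is not present in the segmentation."))
  }
  if (label %in% seg$degenerate) {
    abort(paste0("Label ", label, " is degenerate (empty interior) and cannot ",
                 "be measured."))
  }
  px <- region_pixels(seg, label)
  rec <- tibble(field_id = field_id, label = as.integer(label),
                identity = "unclassified",
                interior_pixels = length(px$interior),
                wall_pixels = length(px$wall))
  for (region in c("wall", "interior")) {
    idx <- px[[region]]
    for (ch in c("mCherry", "Citrin", "CFP")) {
      v <- get_channel(proj, ch)[idx]
      rec[[paste(region, ch, "min", sep = "_")]] <- min(v)
      rec[[paste(region, ch, "max", sep = "_")]] <- max(v)
      rec[[paste(region, ch, "integral", sep = "_")]] <- sum(v)
    }
  }
  rec$mean_wall_mcherry <- rec$wall_mCherry_integral / rec$wall_pixels
  rec
}

#' Measure every non-degenerate cell of a segmentation
#'
#' @inheritParams measure_cell
#' @return A tibble with one cell record per row (possibly zero rows).
#' @export
measure_cells <- function(proj, seg, field_id = "field") {
  ok <- setdiff(seg$cell_ids, seg$degenerate)
  if (length(ok) == 0L) return(empty_cell_table())
  bind_rows(lapply(ok, function(k) measure_cell(proj, seg, k, field_id)))
}

empty_cell_table <- function() {
  cols <- c("field_id", "label", "identity", "interior_pixels", "wall_pixels")
  for (region in c("wall", "interior")) {
    for (ch in c("mCherry", "Citrin", "CFP")) {
      cols <- c(cols, paste(region, ch, c("min", "max", "integral"), sep = "_"))
    }
  }
  cols <- c(cols, "mean_wall_mcherry")
  out <- lapply(cols, function(.) numeric(0))
  names(out) <- cols
  out$field_id <- character(0); out$identity <- character(0)
  out$label <- integer(0)
  as_tibble(out)
}

#' Keep cells within the interior-size window
#'
#' Retains records whose `interior_pixels` fall in the closed interval
#' `[volume_min, volume_max]` (defaults 2400 and 55,000 projected pixels,
#' an empirically assigned window that rejects debris and clumps). Order is
#' preserved; the number of removed records is reported as a message.
#'
#' @param records A cell-record tibble.
#' @param params A [classification_params()].
#' @return The filtered tibble.
#' @export
filter_by_volume <- function(records, params = classification_params()) {
  keep <- records$interior_pixels >= params$volume_min &
    records$interior_pixels <= params$volume_max
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message(n_removed, " cell(s) outside the ", params$volume_min, "-",
            params$volume_max, " pixel interior window removed.")
  }
  records[keep, , drop = FALSE]
}

#' Assign strain identity from the cytosolic markers
#'
#' A cell is called `reference` when its interior Citrin maximum exceeds
#' `citrin_threshold` while its interior CFP maximum stays below
#' `cfp_threshold`, and `tester` for the mirrored pattern; anything else —
#' both channels bright, both dim, or a value exactly at a threshold (the
#' inequalities are strict) — is `unclassified` and excluded from group
#' statistics downstream, though kept in the table for audit.
#'
#' @param records A cell-record tibble with interior maxima set.
#' @param params A [classification_params()].
#' @return `records` with the `identity` column filled in.
#' @export
classify_identity <- function(records, params = classification_params()) {
  hi_citrin <- records$interior_Citrin_max > params$citrin_threshold &
    records$interior_CFP_max < params$cfp_threshold
  hi_cfp <- records$interior_CFP_max > params$cfp_threshold &
    records$interior_Citrin_max < params$citrin_threshold
  if (params$swap_identity_channels) {
    tmp <- hi_citrin; hi_citrin <- hi_cfp; hi_cfp <- tmp
  }
  records$identity <- dplyr::case_when(
    hi_citrin ~ "reference",
    hi_cfp ~ "tester",
    .default = "unclassified"
  )
  records
}

#' Quantify wall mCherry for every analyzable cell in a field
#'
#' Runs the full workflow on one field: sum projection, cytosol-marker cell
#' segmentation, wall-ring segmentation, per-cell intensity accounting, the
#' interior-size filter, and strain-identity assignment. Unclassified cells
#' are retained in the output, flagged `identity = "unclassified"`.
#'
#' @param field An [image_field()].
#' @param seg_params A [segmentation_params()].
#' @param class_params A [classification_params()].
#' @param field_id Identifier recorded on every record.
#' @return A cell-record tibble (one row per analyzed cell).
#' @examples
#' sp <- scene_spec(image_shape = c(6, 96, 96), camera_offset = 100, cells = list(
#'   cell_spec(c(3, 48, 48), c(2.5, 30, 30), identity = "tester",
#'             cytosol_intensity = 500, wall_intensity = 400)))
#' cells <- quantify_field(generate_field(sp)$field,
#'                         seg_params = segmentation_params(),
#'                         class_params = classification_params(volume_min = 100))
#' cells[, c("label", "identity", "interior_pixels", "mean_wall_mcherry")]
#' @export
quantify_field <- function(field, seg_params = segmentation_params(),
                           class_params = classification_params(),
                           field_id = "field") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  proj <- stage("sum_project", sum_project(field))
  labels <- stage("segment_cells", segment_cells(proj, seg_params))
  seg <- stage("segment_wall", segment_wall(labels, seg_params$wall_width))
  records <- stage("measure_cells", measure_cells(proj, seg, field_id))
  records <- stage("filter_by_volume", filter_by_volume(records, class_params))
  stage("classify_identity", classify_identity(records, class_params))
}
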