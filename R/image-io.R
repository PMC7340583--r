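#' Write a field to multi-channel TIFF
#'
#' The stack is stored as a 16-bit multi-page TIFF in channel-major page
#' order (all sections of channel 1, then channel 2, ...), with a JSON
#' sidecar `<path>.meta.json` recording the axis lengths, channel names and
#' voxel geometry. Intensities are quantized to integer ADU in 0..65535;
#' integer-valued fields round-trip exactly.
#'
#' @param field An [image_field()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "image_field")) abort("`field` must be an image_field.")
  d <- dim(field$data)
  if (any(field$data > 65535)) abort("Intensities exceed the 16-bit range.")
  pages <- vector("list", d[1L] * d[2L])
  i <- 0L
  for (ch in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      i <- i + 1L
      pages[[i]] <- round(field$data[ch, z, , ]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(axes = "CZYX",
               shape = as.integer(d),
               channels = field$channel_names,
               voxel_step_z = field$voxel_step_z,
               pixel_size_xy = field$pixel_size_xy)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF field
#'
#' Reads a stack written by [write_field()] (or any multi-page TIFF
#' accompanied by a compatible `<path>.meta.json` axis sidecar). Channels are
#' mapped by name; a file whose metadata lacks one of mCherry, Citrin or CFP
#' is rejected.
#'
#' @param path TIFF path.
#' @return An [image_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    abort(paste0("No axis metadata found (expected ", meta_path, "); ",
                 "cannot identify channels."), class = "wallquant_metadata_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  if (length(shape) != 4L) {
    abort("Metadata does not describe a 4-D (C,Z,Y,X) stack.",
          class = "wallquant_shape_error")
  }
  required <- c("mCherry", "Citrin", "CFP")
  if (!all(required %in% meta$channels)) {
    abort(paste0("Required channel(s) missing from file: ",
                 paste(setdiff(required, meta$channels), collapse = ", ")),
          class = "wallquant_channel_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != shape[1L] * shape[2L]) {
    abort(paste0("Page count ", length(pages), " does not match metadata shape ",
                 paste(shape, collapse = "x"), "."),
          class = "wallquant_shape_error")
  }
  data <- array(0, shape)
  i <- 0L
  for (ch in seq_len(shape[1L])) {
    for (z in seq_len(shape[2L])) {
      i <- i + 1L
      pg <- pages[[i]]
      if (!is.matrix(pg) || !all(dim(pg) == shape[3:4])) {
        abort("TIFF page dimensions do not match metadata.",
              class = "wallquant_shape_error")
      }
      data[ch, z, , ] <- round(pg * 65535)
    }
  }
  image_field(data, channel_names = meta$channels,
              voxel_step_z = meta$voxel_step_z %||% 300,
              pixel_size_xy = meta$pixel_size_xy)
}

#' Write a label image as integer TIFF
#'
#' @param labels 2-D integer matrix (or 3-D array) of cell labels,
#'   0 = background.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535) abort("More labels than the 16-bit range allows.")
  if (is.matrix(labels)) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  } else {
    pages <- lapply(seq_len(dim(labels)[1L]), function(z) labels[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  }
  invisible(path)
}

#' Read a label image written by [write_labels()]
#' @param path TIFF path.
#' @return An integer matrix (single page) or 3-D array (multi-page).
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ints <- lapply(pages, function(p) {
    storage.mode(p) <- "double"
    matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  })
  if (length(ints) == 1L) return(ints[[1L]])
  arr <- array(0L, c(length(ints), dim(ints[[1L]])))
  for (z in seq_along(ints)) arr[z, , ] <- ints[[z]]
  arr
}

#' Write a per-cell measurement table to CSV
#'
#' One row per cell with the full intensity accounting (pixel counts and
#' per-channel min/max/integral in wall and interior). Doubles are written
#' with 17 significant digits so a read-back is numerically identical.
#'
#' @param records A cell-record tibble, e.g. from [quantify_field()]; an
#'   empty tibble writes the header only.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell measurement table written by [write_cell_table()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  int_cols <- c("label", "interior_pixels", "wall_pixels")
  for (j in setdiff(names(df), int_cols)) {
    if (is.integer(df[[j]])) df[[j]] <- as.double(df[[j]])
  }
  as_tibble(df)
}

#' Read segmentation and classification parameters from a YAML config
#'
#' The file may contain `segmentation:` and `classification:` blocks whose
#' keys match the arguments of [segmentation_params()] and
#' [classification_params()]; absent keys keep their defaults.
#'
#' @param path YAML path.
#' @return A list with elements `segmentation` and `classification`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    segmentation = do.call(segmentation_params, cfg$segmentation %||% list()),
    classification = do.call(classification_params, cfg$classification %||% list())
  )
}

#' Serialize a scene description to YAML
#' @param spec A [scene_spec()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  lst <- unclass(spec)
  lst$cells <- lapply(lst$cells, function(cl) Filter(Negate(is.null), unclass(cl)))
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' Read a scene description from YAML
#' @param path YAML path written by [write_scene_spec()].
#' @return A [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  cells <- lapply(lst$cells, function(cl) do.call(cell_spec, cl))
  lst$cells <- NULL
  do.call(scene_spec, c(lst, list(cells = cells)))
}
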