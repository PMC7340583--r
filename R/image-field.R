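#' Three-channel fluorescence image stack
#'
#' An `image_field` bundles a 4-D intensity array with channel identities and
#' voxel geometry. The axis order is fixed as (channel, section, row, column)
#' and channels are always addressed by name, never by position, so the three
#' fluorophores used in the cell-wall quantification workflow (mCherry for the
#' wall fusion protein, Citrin marking the cytosol of the reference strain,
#' CFP marking the cytosol of tester strains) cannot be confused downstream.
#'
#' @param data Numeric 4-D array with axes (channel, section, row, column);
#'   all values must be finite and non-negative.
#' @param channel_names Character vector naming the channel axis; must contain
#'   at least `"mCherry"`, `"Citrin"` and `"CFP"`.
#' @param voxel_step_z Axial step between optical sections, in nm.
#' @param pixel_size_xy Optional lateral pixel size, in nm.
#'
#' @return An object of class `image_field`.
#' @seealso [generate_field()], [read_field()], [sum_project()]
#' @export
image_field <- function(data, channel_names = c("mCherry", "Citrin", "CFP"),
                        voxel_step_z = 300, pixel_size_xy = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4-D array with axes (channel, section, row, column).")
  }
  if (length(channel_names) != dim(data)[1L]) {
    abort("`channel_names` must have one name per channel-axis slice.")
  }
  required <- c("mCherry", "Citrin", "CFP")
  missing_ch <- setdiff(required, channel_names)
  if (length(missing_ch) > 0L) {
    abort(paste0("Required channel(s) missing: ", paste(missing_ch, collapse = ", ")))
  }
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0)) {
    abort("Intensities must be finite and non-negative.")
  }
  structure(
    list(data = data, channel_names = as.character(channel_names),
         voxel_step_z = voxel_step_z, pixel_size_xy = pixel_size_xy),
    class = "image_field"
  )
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_field> ", d[2L], " sections x ", d[3L], " x ", d[4L], " px, ",
      "channels: ", paste(x$channel_names, collapse = ", "),
      ", z-step ", x$voxel_step_z, " nm\n", sep = "")
  invisible(x)
}

#' Extract one channel of a field or projection by name
#'
#' @param x An `image_field` or `projected_field`.
#' @param channel Channel name, e.g. `"mCherry"`.
#' @return For an `image_field`, a 3-D array (section, row, column); for a
#'   `projected_field`, a 2-D matrix.
#' @export
get_channel <- function(x, channel) {
  idx <- match(channel, x$channel_names)
  if (is.na(idx)) {
    abort(paste0("Channel '", channel, "' not present (have: ",
                 paste(x$channel_names, collapse = ", "), ")."))
  }
  if (inherits(x, "image_field")) {
    arr <- x$data[idx, , , , drop = FALSE]
    dim(arr) <- dim(x$data)[-1L]
    arr
  } else if (inherits(x, "projected_field")) {
    m <- x$data[idx, , , drop = FALSE]
    dim(m) <- dim(x$data)[-1L]
    m
  } else {
    abort("`x` must be an image_field or projected_field.")
  }
}
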