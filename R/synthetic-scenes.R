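#' Describe one synthetic yeast cell
#'
#' Cells are modelled as axis-aligned ellipsoids with a cytosolic fluorophore
#' filling the interior and a thin high-mCherry shell standing in for the
#' wall-anchored fusion protein. The shell can be uniform around the whole
#' periphery or restricted to a polarized crescent, emulating the two surface
#' localization patterns seen for GPI-anchored wall proteins.
#'
#' @param center Numeric length-3, voxel coordinates (z, y, x) of the centre.
#' @param radii Numeric length-3, ellipsoid semi-axes (rz, ry, rx) in voxels.
#' @param identity `"reference"` (cytosolic Citrin) or `"tester"`
#'   (cytosolic CFP).
#' @param cytosol_intensity Cytosolic marker intensity, ADU.
#' @param wall_intensity mCherry shell intensity, ADU.
#' @param wall_thickness Shell thickness in voxels; must be `>= 1` and smaller
#'   than every semi-axis.
#' @param localization `"uniform"` or `"crescent"`.
#' @param crescent_axis Length-3 direction (z, y, x) of the crescent pole;
#'   required iff `localization = "crescent"`.
#' @param crescent_halfangle Half-opening angle of the crescent cone in
#'   degrees; 180 reproduces the uniform shell.
#'
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(center, radii, identity = c("tester", "reference"),
                      cytosol_intensity = 400, wall_intensity = 400,
                      wall_thickness = 3, localization = c("uniform", "crescent"),
                      crescent_axis = NULL, crescent_halfangle = NULL) {
  identity <- match.arg(identity)
  localization <- match.arg(localization)
  center <- as.numeric(center); radii <- as.numeric(radii)
  if (length(center) != 3L || length(radii) != 3L) {
    abort("`center` and `radii` must have length 3 (z, y, x).")
  }
  if (wall_thickness < 1) abort("`wall_thickness` must be >= 1 voxel.")
  if (any(radii <= wall_thickness)) {
    abort("All radii must exceed `wall_thickness` (the interior would be empty).")
  }
  if (cytosol_intensity < 0 || wall_intensity < 0) {
    abort("Intensities must be non-negative.")
  }
  if (localization == "crescent") {
    if (is.null(crescent_axis) || is.null(crescent_halfangle)) {
      abort("Crescent cells need `crescent_axis` and `crescent_halfangle`.")
    }
    nrm <- sqrt(sum(as.numeric(crescent_axis)^2))
    if (nrm == 0) abort("`crescent_axis` must be a nonzero direction.")
    crescent_axis <- as.numeric(crescent_axis) / nrm
  } else if (!is.null(crescent_axis) || !is.null(crescent_halfangle)) {
    abort("Crescent fields are only allowed when localization = 'crescent'.")
  }
  structure(
    list(center = center, radii = radii, identity = identity,
         cytosol_intensity = cytosol_intensity, wall_intensity = wall_intensity,
         wall_thickness = wall_thickness, localization = localization,
         crescent_axis = crescent_axis, crescent_halfangle = crescent_halfangle),
    class = "cell_spec"
  )
}

#' Describe a synthetic microscopy scene
#'
#' A scene fixes the stack geometry (by default 28 optical sections at a
#' 300 nm step, the acquisition geometry of the quantification workflow this
#' package implements), the cells it contains, and a first-order sCMOS noise
#' model: shot noise `Poisson(signal * poisson_scale) / poisson_scale`, read
#' noise `Normal(0, gaussian_sd)`, and a constant camera offset, with the
#' result quantized to integer ADU. With `gaussian_sd = 0` and
#' `poisson_scale = 0` the scene is rendered noiselessly and exactly.
#'
#' @param image_shape Integer length-3 `(n_sections, height, width)` in voxels.
#' @param cells List of [cell_spec()] objects.
#' @param voxel_step_z Axial step in nm (default 300).
#' @param camera_offset Constant offset added everywhere, ADU (default 100).
#' @param gaussian_sd Read-noise standard deviation, ADU; 0 disables.
#' @param poisson_scale Photons-per-ADU conversion for shot noise; 0 disables.
#' @param seed Integer seed; fully determines the rendered stack.
#' @param overlap_tolerance Maximum number of voxels any two cells may share
#'   before generation aborts (default 0). Small positive values let tests
#'   build touching "clumps" for watershed splitting.
#'
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(28L, 256L, 256L), cells = list(),
                       voxel_step_z = 300, camera_offset = 100,
                       gaussian_sd = 0, poisson_scale = 0, seed = 1L,
                       overlap_tolerance = 0L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 3L || image_shape[1L] < 1L ||
      any(image_shape[2:3] < 1L)) {
    abort("`image_shape` must be (n_sections >= 1, height, width).")
  }
  if (gaussian_sd < 0 || poisson_scale < 0) abort("Noise parameters must be >= 0.")
  if (camera_offset < 0) abort("`camera_offset` must be >= 0.")
  for (cl in cells) {
    if (!inherits(cl, "cell_spec")) abort("`cells` must be a list of cell_spec objects.")
    if (any(cl$center < 1) || any(cl$center > image_shape)) {
      abort("All cell centers must lie inside the image bounds.")
    }
  }
  structure(
    list(image_shape = image_shape, cells = cells, voxel_step_z = voxel_step_z,
         camera_offset = camera_offset, gaussian_sd = gaussian_sd,
         poisson_scale = poisson_scale, seed = as.integer(seed),
         overlap_tolerance = as.integer(overlap_tolerance)),
    class = "scene_spec"
  )
}

# Rasterize one cell into logical masks over its bounding box.
# Returns box index ranges and cell/interior/wall/mcherry-wall masks.
rasterize_cell <- function(cl, shape) {
  zr <- max(1L, floor(cl$center[1L] - cl$radii[1L])):min(shape[1L], ceiling(cl$center[1L] + cl$radii[1L]))
  yr <- max(1L, floor(cl$center[2L] - cl$radii[2L])):min(shape[2L], ceiling(cl$center[2L] + cl$radii[2L]))
  xr <- max(1L, floor(cl$center[3L] - cl$radii[3L])):min(shape[3L], ceiling(cl$center[3L] + cl$radii[3L]))
  dz <- zr - cl$center[1L]; dy <- yr - cl$center[2L]; dx <- xr - cl$center[3L]
  sq <- function(r) {
    outer(outer((dz / r[1L])^2, (dy / r[2L])^2, "+"), (dx / r[3L])^2, "+")
  }
  cell <- sq(cl$radii) <= 1
  interior <- sq(cl$radii - cl$wall_thickness) < 1
  wall <- cell & !interior
  if (cl$localization == "crescent") {
    nd <- length(dz); ny <- length(dy); nx <- length(dx)
    az <- array(dz, c(nd, ny, nx))
    ay <- array(rep(dy, each = nd), c(nd, ny, nx))
    ax <- array(rep(dx, each = nd * ny), c(nd, ny, nx))
    nrm <- sqrt(az^2 + ay^2 + ax^2)
    cosang <- (az * cl$crescent_axis[1L] + ay * cl$crescent_axis[2L] +
                 ax * cl$crescent_axis[3L]) / pmax(nrm, .Machine$double.eps)
    cone <- nrm > 0 & cosang >= cos(cl$crescent_halfangle * pi / 180)
    wall_mch <- wall & cone
  } else {
    wall_mch <- wall
  }
  list(zr = zr, yr = yr, xr = xr, cell = cell, interior = interior,
       wall = wall, wall_mch = wall_mch)
}

#' Render a synthetic field with voxel-level ground truth
#'
#' Deposits each cell's cytosolic marker into exactly one cytosolic channel
#' (Citrin for the reference strain, CFP for testers), its wall shell into
#' mCherry, adds the camera offset everywhere, and applies the scene's noise
#' model. The returned ground truth carries the 3-D label and wall-mask
#' volumes plus, per cell, the voxel counts and the mean wall mCherry a
#' perfect measurement in the sum projection would report
#' (`true_mean_wall_mcherry`): the mean of the noiseless projected mCherry
#' over the cell's true projected wall band of width `wall_thickness`.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `field` (an [image_field()]) and `truth`
#'   (a `ground_truth` list with `label_volume`, `wall_mask_volume`, and a
#'   per-cell tibble `cells`).
#' @examples
#' sp <- scene_spec(image_shape = c(8, 64, 64), cells = list(
#'   cell_spec(center = c(4, 32, 32), radii = c(3.5, 12, 12),
#'             identity = "tester", wall_intensity = 400)))
#' out <- generate_field(sp)
#' dim(out$field$data)
#' @export
generate_field <- function(spec) {
  if (!inherits(spec, "scene_spec")) abort("`spec` must be a scene_spec.")
  shape <- spec$image_shape
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  chan <- c("mCherry", "Citrin", "CFP")
  signal <- lapply(chan, function(.) array(0, c(nz, ny, nx)))
  names(signal) <- chan
  label_volume <- array(0L, c(nz, ny, nx))
  wall_mask_volume <- array(FALSE, c(nz, ny, nx))
  info <- vector("list", length(spec$cells))

  for (k in seq_along(spec$cells)) {
    cl <- spec$cells[[k]]
    rs <- rasterize_cell(cl, shape)
    prev <- label_volume[rs$zr, rs$yr, rs$xr]
    n_overlap <- sum(prev[rs$cell] > 0L)
    if (n_overlap > spec$overlap_tolerance) {
      abort(paste0("Cell ", k, " overlaps an earlier cell by ", n_overlap,
                   " voxels (tolerance ", spec$overlap_tolerance,
                   "); ground truth would be ambiguous."))
    }
    prev[rs$cell] <- k
    label_volume[rs$zr, rs$yr, rs$xr] <- prev
    wm <- wall_mask_volume[rs$zr, rs$yr, rs$xr]
    wm[rs$wall] <- TRUE
    wall_mask_volume[rs$zr, rs$yr, rs$xr] <- wm
    cyt_channel <- if (cl$identity == "reference") "Citrin" else "CFP"
    sg <- signal[[cyt_channel]][rs$zr, rs$yr, rs$xr]
    sg[rs$interior] <- sg[rs$interior] + cl$cytosol_intensity
    signal[[cyt_channel]][rs$zr, rs$yr, rs$xr] <- sg
    sm <- signal[["mCherry"]][rs$zr, rs$yr, rs$xr]
    sm[rs$wall_mch] <- sm[rs$wall_mch] + cl$wall_intensity
    signal[["mCherry"]][rs$zr, rs$yr, rs$xr] <- sm
    info[[k]] <- tibble(
      label = k, identity = cl$identity,
      interior_voxels = sum(rs$interior), wall_voxels = sum(rs$wall),
      wall_mcherry_voxels = sum(rs$wall_mch),
      wall_thickness = cl$wall_thickness
    )
  }

  # Projected-space oracle for the per-cell wall-mCherry statistic.
  proj_mch <- colSums(signal[["mCherry"]], dims = 1) + spec$camera_offset * nz
  true_mean <- rep(NA_real_, length(spec$cells))
  for (k in seq_along(spec$cells)) {
    mask2d <- colSums(label_volume == k, dims = 1) > 0
    dm <- EBImage::distmap(mask2d + 0)
    band <- mask2d & dm <= spec$cells[[k]]$wall_thickness
    if (any(band)) true_mean[k] <- mean(proj_mch[band])
  }
  cells_tbl <- if (length(info) > 0L) {
    mutate(bind_rows(info), true_mean_wall_mcherry = true_mean)
  } else {
    tibble(label = integer(), identity = character(),
           interior_voxels = integer(), wall_voxels = integer(),
           wall_mcherry_voxels = integer(), wall_thickness = numeric(),
           true_mean_wall_mcherry = numeric())
  }

  noisy <- spec$gaussian_sd > 0 || spec$poisson_scale > 0
  data <- array(0, c(3L, nz, ny, nx))
  with_seed(spec$seed, {
    for (i in seq_along(chan)) {
      v <- signal[[chan[i]]]
      if (spec$poisson_scale > 0) {
        v <- array(rpois(length(v), v * spec$poisson_scale) / spec$poisson_scale,
                   dim(v))
      }
      if (spec$gaussian_sd > 0) {
        v <- v + array(rnorm(length(v), 0, spec$gaussian_sd), dim(v))
      }
      v <- v + spec$camera_offset
      if (noisy) v <- pmin(pmax(round(v), 0), 65535)
      data[i, , , ] <- v
    }
  })

  field <- image_field(data, channel_names = chan,
                       voxel_step_z = spec$voxel_step_z)
  truth <- structure(
    list(label_volume = label_volume, wall_mask_volume = wall_mask_volume,
         cells = cells_tbl),
    class = "ground_truth"
  )
  list(field = field, truth = truth)
}
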