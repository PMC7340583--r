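test_that("constant-region measurement reproduces the arithmetic identities", {
  # uniform wall: integral = intensity * pixels, min = max = mean
  n <- 60L
  data <- array(0, c(3, 1, n, n))
  yy <- matrix(rep(1:n, n), n, n); xx <- t(yy)
  disk <- ((yy - 30)^2 + (xx - 30)^2) <= 20^2
  data[1, 1, , ][disk] <- 100   # mCherry everywhere in the cell
  data[3, 1, , ][disk] <- 500   # CFP cytosol
  f <- image_field(data)
  proj <- sum_project(f)
  labels <- matrix(0L, n, n); labels[disk] <- 1L
  seg <- segment_wall(labels, 3)
  rec <- measure_cell(proj, seg, 1)
  expect_equal(rec$wall_mCherry_min, 100)
  expect_equal(rec$wall_mCherry_max, 100)
  expect_equal(rec$wall_mCherry_integral, 100 * rec$wall_pixels)
  expect_equal(rec$mean_wall_mcherry, 100)
})

test_that("integrals match a naive per-pixel loop over the masks", {
  sp <- make_test_scene(seed = 31, gaussian_sd = 5, poisson_scale = 1,
                        shape = c(8L, 256L, 256L))
  out <- generate_field(sp)
  proj <- sum_project(out$field)
  labels <- segment_cells(proj, segmentation_params())
  seg <- segment_wall(labels, 3)
  recs <- measure_cells(proj, seg)
  for (k in seg$cell_ids) {
    px <- wallquant:::region_pixels(seg, k)
    for (ch in c("mCherry", "Citrin", "CFP")) {
      img <- get_channel(proj, ch)
      acc_wall <- 0; mn <- Inf; mx <- -Inf
      for (i in px$wall) {
        acc_wall <- acc_wall + img[i]
        mn <- min(mn, img[i]); mx <- max(mx, img[i])
      }
      row <- recs[recs$label == k, ]
      expect_equal(row[[paste0("wall_", ch, "_integral")]], acc_wall)
      expect_equal(row[[paste0("wall_", ch, "_min")]], mn)
      expect_equal(row[[paste0("wall_", ch, "_max")]], mx)
    }
  }
})

test_that("accounting identity: wall + interior integral equals whole-cell integral", {
  sp <- make_test_scene(seed = 32, gaussian_sd = 5, poisson_scale = 1)
  out <- generate_field(sp)
  proj <- sum_project(out$field)
  labels <- segment_cells(proj, segmentation_params())
  seg <- segment_wall(labels, 3)
  recs <- measure_cells(proj, seg)
  for (k in seg$cell_ids) {
    cellpx <- which(labels == k)
    row <- recs[recs$label == k, ]
    for (ch in c("mCherry", "Citrin", "CFP")) {
      whole <- sum(get_channel(proj, ch)[cellpx])
      expect_identical(row[[paste0("wall_", ch, "_integral")]] +
                         row[[paste0("interior_", ch, "_integral")]], whole)
    }
  }
})

test_that("crescent mCherry accounting matches ground-truth voxel counts", {
  # noiseless, no offset: the whole-cell projected mCherry integral equals
  # wall_intensity x (number of mCherry-carrying shell voxels)
  sp <- scene_spec(image_shape = c(20, 64, 64), camera_offset = 0, cells = list(
    cell_spec(c(10, 32, 32), c(9, 22, 22), identity = "tester",
              cytosol_intensity = 600, wall_intensity = 350, wall_thickness = 3,
              localization = "crescent", crescent_axis = c(0, 1, 0),
              crescent_halfangle = 90)))
  out <- generate_field(sp)
  proj <- sum_project(out$field)
  labels <- segment_cells(proj, segmentation_params(min_object_pixels = 50))
  seg <- segment_wall(labels, 3)
  rec <- measure_cell(proj, seg, 1)
  total <- rec$wall_mCherry_integral + rec$interior_mCherry_integral
  truth <- out$truth$cells
  expected <- 350 * truth$wall_mcherry_voxels
  # segmentation-boundary pixels can drop a sliver of shell signal
  expect_equal(total, expected, tolerance = 0.02)
  expect_lt(truth$wall_mcherry_voxels, truth$wall_voxels)
})

test_that("the interior-size filter applies the closed 2400-55000 window", {
  recs <- tibble::tibble(field_id = "f", label = 1:4,
                         interior_pixels = c(2399, 2400, 55000, 55001))
  kept <- suppressMessages(filter_by_volume(recs, classification_params()))
  expect_identical(kept$interior_pixels, c(2400, 55000))
  expect_identical(kept$label, c(2L, 3L))          # order preserved
  expect_message(filter_by_volume(recs), "2 cell")
  # idempotent; empty in, empty out
  again <- suppressMessages(filter_by_volume(kept))
  expect_identical(again, kept)
  empty <- recs[0, ]
  expect_identical(nrow(filter_by_volume(empty)), 0L)
})

test_that("identity assignment follows the strict dual-threshold rule", {
  mk <- function(cfp, citrin) {
    tibble::tibble(interior_CFP_max = cfp, interior_Citrin_max = citrin,
                   identity = "unclassified")
  }
  pars <- classification_params()
  expect_equal(classify_identity(mk(300, 100), pars)$identity, "tester")
  expect_equal(classify_identity(mk(100, 300), pars)$identity, "reference")
  expect_equal(classify_identity(mk(300, 300), pars)$identity, "unclassified")
  expect_equal(classify_identity(mk(100, 100), pars)$identity, "unclassified")
  # values exactly at a threshold satisfy neither strict inequality
  expect_equal(classify_identity(mk(200, 100), pars)$identity, "unclassified")
  expect_equal(classify_identity(mk(300, 200), pars)$identity, "unclassified")
  # channel-swap symmetry
  swapped <- classification_params(swap_identity_channels = TRUE)
  expect_equal(classify_identity(mk(300, 100), swapped)$identity, "reference")
  expect_equal(classify_identity(mk(100, 300), swapped)$identity, "tester")
})

test_that("swapping the cytosolic channel images swaps identities of every cell", {
  sp <- make_test_scene(seed = 33, camera_offset = 0,
                        shape = c(8L, 320L, 320L))
  f <- generate_field(sp)$field
  recs <- quantify_field(f)
  swapped_field <- f
  i_cit <- match("Citrin", f$channel_names); i_cfp <- match("CFP", f$channel_names)
  swapped_field$data[i_cit, , , ] <- f$data[i_cfp, , , ]
  swapped_field$data[i_cfp, , , ] <- f$data[i_cit, , , ]
  recs_sw <- quantify_field(swapped_field)
  flip <- c(reference = "tester", tester = "reference",
            unclassified = "unclassified")
  expect_identical(unname(flip[recs$identity]), recs_sw$identity)
})

test_that("quantify_field recovers identities and wall means end to end", {
  # identity accuracy needs the 200-ADU thresholds to be meaningful, i.e. a
  # dark (offset-subtracted) background in the summed projection
  sp0 <- make_test_scene(seed = 34, camera_offset = 0, n_cells = 3,
                         identity = c("reference", "tester", "tester"),
                         wall_intensity = c(0, 400, 400))
  out0 <- generate_field(sp0)
  recs0 <- quantify_field(out0$field, field_id = "f1")
  expect_equal(nrow(recs0), 3L)
  truep0 <- project_labels(out0$truth$label_volume)
  mp0 <- match_labels(segment_cells(sum_project(out0$field)), truep0)
  expect_identical(recs0$identity,
                   out0$truth$cells$identity[mp0[recs0$label]])
  # determinism end to end
  expect_identical(recs0, quantify_field(out0$field, field_id = "f1"))

  # wall-mean recovery is asserted on raw-camera conditions (offset kept),
  # matching how the measurement and its ground truth are both defined
  sp <- make_test_scene(seed = 34)
  out <- generate_field(sp)
  recs <- quantify_field(out$field, field_id = "f1")
  truep <- project_labels(out$truth$label_volume)
  mp <- match_labels(segment_cells(sum_project(out$field)), truep)
  truth <- out$truth$cells
  for (k in seq_len(nrow(recs))) {
    expect_equal(recs$mean_wall_mcherry[k],
                 truth$true_mean_wall_mcherry[mp[recs$label[k]]],
                 tolerance = 0.05)
  }
})

test_that("a single giant blob above volume_max yields no analyzed records", {
  n <- 340L
  data <- array(0, c(3, 1, n, n))
  yy <- matrix(rep(1:n, n), n, n); xx <- t(yy)
  blob <- ((yy - 170)^2 + (xx - 170)^2) <= 140^2   # interior >> 55,000 px
  data[3, 1, , ][blob] <- 600
  recs <- quantify_field(image_field(data))
  expect_equal(nrow(recs), 0L)
})

test_that("measurement bias shrinks with the noise level", {
  biases <- vapply(c(12, 6, 0), function(sdv) {
    sp <- make_test_scene(seed = 35, gaussian_sd = sdv)
    out <- generate_field(sp)
    recs <- quantify_field(out$field,
                           class_params = classification_params(volume_min = 100))
    truep <- project_labels(out$truth$label_volume)
    labels <- segment_cells(sum_project(out$field), segmentation_params())
    mp <- match_labels(labels, truep)
    mean(abs(recs$mean_wall_mcherry /
               out$truth$cells$true_mean_wall_mcherry[mp[recs$label]] - 1))
  }, 0)
  expect_true(biases[3] <= biases[1] + 1e-9)
  expect_lt(biases[3], 0.05)
})
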