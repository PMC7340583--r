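# Shared fixtures: all synthetic, built in code at test time.

# A standard three-cell field in the acquisition geometry of the workflow
# (28 sections); cells sized so their interiors pass the 2400-pixel filter.
make_test_scene <- function(seed = 1, camera_offset = 100, gaussian_sd = 0,
                            poisson_scale = 0, n_cells = 3,
                            wall_intensity = c(0, 400, 400),
                            identity = c("reference", "tester", "tester"),
                            shape = c(28L, 320L, 320L)) {
  sc <- min(shape[2:3]) / 320           # lateral geometry scales with the frame
  zc <- (shape[1] + 1) / 2
  centers <- list(c(zc, 0.266 * shape[2], 0.266 * shape[3]),
                  c(zc, 0.266 * shape[2], 0.719 * shape[3]),
                  c(zc, 0.719 * shape[2], 0.5 * shape[3]))
  rng_state <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv()))
  set.seed(seed + 7000L)
  cells <- lapply(seq_len(n_cells), function(j) {
    rz <- max(4.2, runif(1, 10, 13) * shape[1] / 28)
    cell_spec(center = centers[[j]],
              radii = c(rz, runif(1, 31, 40) * sc, runif(1, 31, 40) * sc),
              identity = identity[j],
              cytosol_intensity = runif(1, 400, 700),
              wall_intensity = wall_intensity[j])
  })
  scene_spec(image_shape = shape, cells = cells, camera_offset = camera_offset,
             gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
             seed = seed)
}

# Map each recovered label to the ground-truth label it overlaps most.
match_labels <- function(recovered, true_projected) {
  labs <- sort(setdiff(unique(as.vector(recovered)), 0L))
  vapply(labs, function(k) {
    ov <- table(true_projected[recovered == k])
    ov <- ov[names(ov) != "0"]
    as.integer(names(ov)[which.max(ov)])
  }, integer(1))
}

# Projection of a 3-D label volume: per-pixel dominant (max) label.
project_labels <- function(label_volume) {
  apply(label_volume, c(2, 3), max)
}
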