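#' Simulate a saturation radioligand binding experiment
#'
#' Draws total-binding measurements from the one-site hyperbola
#' `bound = bmax * L / (kd + L) + background_slope * L` plus Gaussian
#' replicate noise, together with a matched protein-free background series
#' (`background_slope * L` plus noise), mirroring a binding assay run with
#' and without purified protein.
#'
#' @param kd Generative dissociation constant, in the ligand unit (µM).
#' @param bmax Generative maximal specific binding, pmol.
#' @param ligand_points Ligand concentrations to sample, strictly positive.
#' @param background_slope Linear nonspecific-binding slope, pmol per µM.
#' @param replicate_sd Gaussian replicate noise s.d., pmol; 0 for noiseless.
#' @param n_replicates Replicates per ligand point.
#' @param seed Integer seed; fully determines the output.
#'
#' @return A tibble with columns `ligand`, `bound`, `series`
#'   (`"total"` or `"background"`) and `replicate`.
#' @seealso [fit_binding()], [subtract_background()]
#' @export
generate_binding_curve <- function(kd, bmax, ligand_points,
                                   background_slope = 0, replicate_sd = 0,
                                   n_replicates = 1L, seed = 1L) {
  if (kd <= 0 || bmax <= 0) abort("`kd` and `bmax` must be positive.")
  if (length(ligand_points) == 0L || any(ligand_points <= 0)) {
    abort("`ligand_points` must be non-empty and strictly positive.")
  }
  if (replicate_sd < 0) abort("`replicate_sd` must be >= 0.")
  if (background_slope < 0) abort("`background_slope` must be >= 0.")
  L <- rep(sort(as.numeric(ligand_points)), each = n_replicates)
  rep_id <- rep(seq_len(n_replicates), times = length(ligand_points))
  with_seed(seed, {
    total <- one_site(L, kd, bmax, background_slope) +
      rnorm(length(L), 0, replicate_sd)
    bg <- background_slope * L + rnorm(length(L), 0, replicate_sd)
  })
  tibble(
    ligand = c(L, L),
    bound = c(total, bg),
    series = rep(c("total", "background"), each = length(L)),
    replicate = c(rep_id, rep_id)
  )
}

#' Simulate colony counts from a quantitative mating assay
#'
#' Each replicate titers `n_cells_sampled` colonies on the single-selection
#' plate (diploids plus MATa haploids) and draws the diploid count on the
#' double-selection plate binomially at the true mating efficiency.
#'
#' @param true_efficiency Generative mating efficiency, a fraction in [0, 1].
#' @param n_cells_sampled Total colonies titered per replicate.
#' @param n_replicates Number of independent determinations.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `replicate`, `diploids`, `total`.
#' @seealso [mating_efficiency()], [summarize_mating()]
#' @export
generate_mating_counts <- function(true_efficiency, n_cells_sampled,
                                   n_replicates = 4L, seed = 1L) {
  if (true_efficiency < 0 || true_efficiency > 1) {
    abort("`true_efficiency` must lie in [0, 1].")
  }
  if (n_cells_sampled < 1) abort("`n_cells_sampled` must be >= 1.")
  dip <- with_seed(seed, rbinom(n_replicates, n_cells_sampled, true_efficiency))
  tibble(replicate = seq_len(n_replicates), diploids = dip,
         total = rep(as.integer(n_cells_sampled), n_replicates))
}
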