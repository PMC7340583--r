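#' Compare tester against reference cells within one field
#'
#' Because both strains share the field of view and hence identical exposure,
#' the tester's mean wall-mCherry level can be normalized by the co-imaged
#' reference strain: the comparison reports the arithmetic group means with
#' s.d. ("mean of the per-cell means"), their ratio, and a two-sided
#' Mann-Whitney U test on the per-cell `mean_wall_mcherry` values.
#'
#' The exact U distribution is used when both groups have at most 20 cells
#' and the data are tie-free; otherwise the tie-corrected normal
#' approximation (with continuity correction) is used. `method` can force
#' either branch.
#'
#' @param records A cell-record tibble with identities assigned; unclassified
#'   cells are ignored.
#' @param min_n Warn when either group has fewer cells than this
#'   (default 80, the workflow's customary minimum per group).
#' @param method `"auto"` (default), `"exact"`, or `"approximate"`.
#' @return A one-row tibble: `field_id`, group sizes, group means and s.d.,
#'   `normalized_ratio` (tester mean / reference mean), the Mann-Whitney `U`
#'   for the tester group, the two-sided `p_value`, its `stars`, and the
#'   p-value `method` used.
#' @export
compare_strains <- function(records, min_n = 80L,
                            method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  tester <- records$mean_wall_mcherry[records$identity == "tester"]
  ref <- records$mean_wall_mcherry[records$identity == "reference"]
  if (length(tester) == 0L || length(ref) == 0L) {
    abort("Both a tester and a reference group are required for a comparison.")
  }
  if (length(tester) < min_n || length(ref) < min_n) {
    warn(paste0("Group sizes (tester ", length(tester), ", reference ",
                length(ref), ") below min_n = ", min_n,
                "; the comparison may be underpowered."))
  }
  exact <- switch(method,
    exact = TRUE, approximate = FALSE,
    auto = length(tester) <= 20L && length(ref) <= 20L &&
      !any(duplicated(c(tester, ref)))
  )
  ht <- suppressWarnings(
    wilcox.test(tester, ref, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  field_id <- if ("field_id" %in% names(records) && nrow(records) > 0L) {
    records$field_id[1L]
  } else "field"
  tibble(
    field_id = field_id,
    n_reference = length(ref), n_tester = length(tester),
    mean_reference = mean(ref), sd_reference = sd(ref),
    mean_tester = mean(tester), sd_tester = sd(tester),
    normalized_ratio = mean(tester) / mean(ref),
    U = unname(ht$statistic),
    p_value = ht$p.value,
    stars = star_code(ht$p.value),
    method = if (exact) "exact" else "approximate"
  )
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with Welch-Satterthwaite
#' degrees of freedom, the replicate-level comparison used for
#' mating-efficiency figures.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2; at least one
#'   group must have nonzero variance.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value` (two-sided).
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs at least 2 observations.")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    abort("Both groups have zero variance; the Welch statistic is undefined.")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE,
               alternative = "two.sided")
  tibble(statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Significance star code
#'
#' Maps a p-value to the decoration used in the figures:
#' `p < 0.001` to `"***"`, `p < 0.01` to `"**"`, `p < 0.05` to `"*"`, and
#' anything else to `"n.s."`. The inequalities are strict, so `p = 0.05`
#' is not significant.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Character vector of the same length.
#' @export
star_code <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = "n.s."
  )
}
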