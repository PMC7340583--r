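#' Mating efficiency from colony counts
#'
#' Efficiency = diploid colonies on the double-selection plate divided by
#' total colonies on the single-selection plate (diploids plus MATa
#' haploids).
#'
#' @param diploids Diploid colony count(s); `0 <= diploids <= total`.
#' @param total Total colony count(s); must be positive.
#' @return Efficiency fraction(s) in [0, 1].
#' @examples
#' mating_efficiency(25, 100)  # 0.25
#' @export
mating_efficiency <- function(diploids, total) {
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(diploids < 0) || any(diploids > total)) {
    abort("`diploids` must lie in [0, total].")
  }
  diploids / total
}

#' Summarize replicate mating counts against a baseline
#'
#' Computes per-replicate efficiencies, their mean and sample s.d. (n - 1
#' denominator), and a Welch t comparison of the replicate-level efficiencies
#' against a baseline group (e.g. the empty-plasmid control), with the
#' significance star code attached.
#'
#' @param counts Tibble with columns `diploids` and `total`
#'   (one row per replicate), e.g. from [generate_mating_counts()].
#' @param baseline Same-shaped tibble for the comparison group.
#' @return A one-row tibble: `n`, `mean_efficiency`, `sd_efficiency`,
#'   `baseline_n`, `baseline_mean`, `baseline_sd`, `statistic`, `df`,
#'   `p_value`, `stars`.
#' @export
summarize_mating <- function(counts, baseline) {
  eff <- mating_efficiency(counts$diploids, counts$total)
  eff_base <- mating_efficiency(baseline$diploids, baseline$total)
  test <- welch_t(eff, eff_base)
  tibble(
    n = length(eff), mean_efficiency = mean(eff), sd_efficiency = sd(eff),
    baseline_n = length(eff_base), baseline_mean = mean(eff_base),
    baseline_sd = sd(eff_base),
    statistic = test$statistic, df = test$df, p_value = test$p_value,
    stars = star_code(test$p_value)
  )
}
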