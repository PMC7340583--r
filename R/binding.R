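#' One-site saturation binding model
#'
#' Specific binding follows the single-site hyperbola
#' `B = Bmax * L / (Kd + L)`, optionally plus a linear nonspecific component
#' `background_slope * L`. Free ligand is approximated by total ligand, the
#' standard assumption when ligand is in excess of the bound fraction; see
#' [one_site_depletion()] for the depletion-corrected form.
#'
#' @param L Ligand concentration(s), µM; non-negative.
#' @param kd Dissociation constant, µM; must be positive.
#' @param bmax Maximal specific binding, pmol.
#' @param background_slope Nonspecific slope, pmol per µM.
#' @return Bound ligand, pmol, same length as `L`.
#' @examples
#' one_site(10, kd = 10, bmax = 1)      # half-saturation: 0.5
#' one_site(3 * 1, kd = 1, bmax = 4)    # 4 * 3 / (1 + 3) = 3
#' @export
one_site <- function(L, kd, bmax, background_slope = 0) {
  if (kd <= 0) abort("`kd` must be positive.")
  if (any(L < 0) || bmax < 0 || background_slope < 0) {
    abort("`L`, `bmax` and `background_slope` must be non-negative.")
  }
  bmax * L / (kd + L) + background_slope * L
}

#' Depletion-corrected one-site binding
#'
#' When the protein amount is comparable to the ligand amount, the free
#' concentration is materially below total and the hyperbola on total ligand
#' biases Kd. This form solves the mass-balance quadratic
#' `B^2 - B (L + Kd + Bmax) + Bmax * L = 0` for the physical root.
#'
#' @inheritParams one_site
#' @return Bound ligand, pmol.
#' @export
one_site_depletion <- function(L, kd, bmax, background_slope = 0) {
  if (kd <= 0) abort("`kd` must be positive.")
  s <- L + kd + bmax
  spec <- (s - sqrt(pmax(s^2 - 4 * bmax * L, 0))) / 2
  spec + background_slope * L
}

# Normalize user input into a (ligand, bound) data frame for the total
# series, averaging replicates per ligand point is NOT done: all points
# enter the fit individually.
binding_series <- function(curve, which = "total") {
  df <- as.data.frame(curve)
  if (!all(c("ligand", "bound") %in% names(df))) {
    abort("A binding curve needs `ligand` and `bound` columns.")
  }
  if ("series" %in% names(df)) df <- df[df$series == which, , drop = FALSE]
  if (any(!is.finite(df$bound)) || any(df$ligand <= 0)) {
    abort("Ligand values must be positive and bound values finite.")
  }
  df[order(df$ligand), , drop = FALSE]
}

#' Subtract the protein-free background series
#'
#' Point-wise subtraction of the matched background measurements (an assay
#' run without protein) from the total-binding series. Negative corrected
#' values are clipped to zero with a warning.
#'
#' @param curve A tibble with columns `ligand`, `bound`, `series`
#'   (`"total"` and `"background"`), and optionally `replicate` for matching.
#' @return A tibble with columns `ligand`, `bound` (and `replicate` if
#'   present) holding the corrected specific binding; the background series
#'   is removed.
#' @export
subtract_background <- function(curve) {
  if (!"series" %in% names(curve) || !any(curve$series == "background")) {
    abort("`curve` has no background series to subtract.")
  }
  tot <- binding_series(curve, "total")
  bg <- binding_series(curve, "background")
  key <- function(df) {
    if ("replicate" %in% names(df)) paste(df$ligand, df$replicate) else
      as.character(df$ligand)
  }
  if (nrow(tot) != nrow(bg) || !identical(sort(key(tot)), sort(key(bg)))) {
    abort("Total and background series are on different ligand grids.")
  }
  bg_bound <- bg$bound[match(key(tot), key(bg))]
  corrected <- tot$bound - bg_bound
  if (any(corrected < 0)) {
    warn(paste0(sum(corrected < 0), " corrected value(s) were negative and ",
                "clipped to zero."))
    corrected <- pmax(corrected, 0)
  }
  out <- tibble(ligand = tot$ligand, bound = corrected)
  if ("replicate" %in% names(tot)) out$replicate <- tot$replicate
  out
}

#' Fit the one-site binding model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the one-site hyperbola
#' to a saturation binding curve. If the curve carries a background series it
#' is subtracted point-wise first. Default starting values are
#' `kd = median(ligand)`, `bmax = max(bound)`. When the largest ligand
#' concentration is below the fitted Kd the data do not constrain the
#' saturation plateau; the fit then carries a `"weak-saturation"` warning
#' flag but may still converge.
#'
#' @param curve A binding-curve tibble (`ligand`, `bound`, optional `series`
#'   and `replicate`), e.g. from [generate_binding_curve()] or read from CSV.
#' @param start Optional named list with elements `kd` and `bmax`.
#' @param depletion Use the depletion-corrected model ([one_site_depletion()])
#'   instead of the total-ligand hyperbola.
#' @return A `binding_fit` object; see [tidy.binding_fit()] and
#'   [glance.binding_fit()].
#' @examples
#' curve <- generate_binding_curve(kd = 13.08, bmax = 1,
#'                                 ligand_points = seq(2, 40, length.out = 8))
#' fit_binding(curve)
#' @export
fit_binding <- function(curve, start = NULL, depletion = FALSE) {
  if ("series" %in% names(curve) && any(curve$series == "background")) {
    curve <- subtract_background(curve)
  }
  df <- binding_series(curve)
  if (length(unique(df$ligand)) < 3L) {
    abort("At least 3 distinct ligand points are required to fit Kd and Bmax.")
  }
  if (all(df$bound == 0)) abort("All bound values are zero; nothing to fit.")
  model <- if (depletion) one_site_depletion else one_site
  # Levenberg-Marquardt on the log scale: both parameters stay positive by
  # construction, the problem is better conditioned, and the kd -> 0
  # constant-model corner (a spurious local minimum for noisy low-L points)
  # is unreachable. A small multi-start over kd guards against the remaining
  # flat directions of weakly saturating data.
  kd0 <- if (!is.null(start)) start$kd else median(df$ligand)
  bmax0 <- if (!is.null(start)) start$bmax else max(df$bound)
  kd_starts <- if (is.null(start)) kd0 * c(1, 0.2, 5) else kd0
  fit <- NULL
  for (k0 in kd_starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = list(lkd = log(k0), lbmax = log(bmax0)),
        fn = function(p) df$bound - model(df$ligand, exp(p$lkd), exp(p$lbmax)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
  }
  if (is.null(fit)) abort("Binding fit failed to converge within the iteration cap.")
  est <- exp(unlist(fit$par))
  names(est) <- c("kd", "bmax")
  rss <- fit$deviance
  n <- nrow(df)
  # parameter covariance from the Gauss-Newton Hessian (J'J) at the optimum,
  # mapped back from the log scale by the delta method
  se <- tryCatch({
    sigma2 <- rss / max(n - 2L, 1L)
    se_log <- sqrt(diag(sigma2 * solve(fit$hessian)))
    unname(est * se_log)
  }, error = function(e) rep(NA_real_, 2L))
  warnings <- character(0)
  if (max(df$ligand) < est[["kd"]]) {
    warn("Largest ligand concentration is below the fitted Kd; the plateau is unconstrained (weak saturation).")
    warnings <- c(warnings, "weak-saturation")
  }
  structure(
    list(kd = unname(est[["kd"]]), bmax = unname(est[["bmax"]]),
         kd_se = se[1L], bmax_se = se[2L],
         rss = rss, converged = fit$info %in% 1:4,
         n = n, depletion = depletion, warnings = warnings,
         data = as_tibble(df), fit = fit),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> one-site", if (x$depletion) "(depletion-corrected)" else "",
      "\n  Kd   =", format(x$kd, digits = 5), "+/-",
      format(x$kd_se, digits = 3),
      "\n  Bmax =", format(x$bmax, digits = 5), "+/-",
      format(x$bmax_se, digits = 3),
      "\n  n =", x$n, " RSS =", format(x$rss, digits = 4),
      if (length(x$warnings) > 0) paste0("  [", paste(x$warnings, collapse = ", "), "]"),
      "\n")
  invisible(x)
}

#' Tidy a binding fit
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("kd", "bmax"), estimate = c(x$kd, x$bmax),
         std.error = c(x$kd_se, x$bmax_se))
}

#' One-row summary of a binding fit
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `kd`, `bmax`, `rss`, `n`, `converged`,
#'   `weak_saturation`.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(kd = x$kd, bmax = x$bmax, rss = x$rss, n = x$n,
         converged = x$converged,
         weak_saturation = "weak-saturation" %in% x$warnings)
}

#' Plot a binding fit
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot: measured points and the fitted hyperbola, with the
#'   fitted Kd marked.
#' @export
autoplot.binding_fit <- function(object, ...) {
  grid <- tibble(ligand = seq(0, max(object$data$ligand), length.out = 200))
  model <- if (object$depletion) one_site_depletion else one_site
  grid$bound <- model(grid$ligand, object$kd, object$bmax)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ligand, y = .data$bound)) +
    ggplot2::geom_point(shape = 21, fill = "grey70") +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$kd, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::annotate("text", x = object$kd, y = 0, hjust = -0.1, vjust = -0.5,
                      label = paste0("Kd = ", format(object$kd, digits = 4))) +
    ggplot2::labs(x = "Ligand (µM)", y = "Bound (pmol)",
                  title = "One-site saturation binding") +
    ggplot2::theme_classic()
}
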