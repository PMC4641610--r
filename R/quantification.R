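# Standard-curve quantification for 10-fold dilution series: OLS of Cq on
# log10(concentration), amplification efficiency from the slope, and a
# detection floor from replicate completeness.

#' Fit a standard curve to a dilution series
#'
#' Ordinary least squares of Cq on log10(concentration). By default the
#' regression uses the per-concentration mean Cq (replicate series are
#' averaged before fitting, matching how dilution replicates are normally
#' summarised); set `use_means = FALSE` to regress on raw replicates.
#' Amplification efficiency is derived from the slope as
#' \eqn{E = 10^{-1/slope} - 1} (1.0 = perfect doubling, slope
#' \eqn{-1/\log_{10} 2 \approx -3.3219}). The detection floor is the lowest
#' concentration at which every replicate was detected, requiring all higher
#' concentrations to be complete as well.
#'
#' @param points Data frame with columns `concentration` (ng/ul, > 0) and
#'   `cq` (`NA` marks a dropped-out replicate); `replicate`/`channel` columns
#'   are passed through if present.
#' @param use_means Regress on per-concentration means (default) or on raw
#'   replicate Cqs.
#' @return A list of class `"standard_curve_fit"`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_points`, `detection_floor`, `degenerate`.
#'   A flat series (slope ~ 0) is returned with `degenerate = TRUE` and `NA`
#'   efficiency.
#' @examples
#' pts <- data.frame(concentration = 10^(2:-2), cq = 40 - 3.3219 * (2:-2))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points, use_means = TRUE) {
  stopifnot(all(c("concentration", "cq") %in% names(points)))
  if (any(points$concentration <= 0, na.rm = TRUE)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  detected <- points[!is.na(points$cq), , drop = FALSE]
  concs <- sort(unique(detected$concentration), decreasing = TRUE)
  if (length(concs) < 3L) {
    stop(sprintf("standard curve needs >= 3 distinct concentrations with a Cq; got %d",
                 length(concs)), call. = FALSE)
  }
  if (use_means) {
    cq <- vapply(concs, function(k) mean(detected$cq[detected$concentration == k]),
                 numeric(1))
    x <- log10(concs)
  } else {
    cq <- detected$cq
    x <- log10(detected$concentration)
  }
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact series trip summary.lm
  degenerate <- !is.finite(slope) || abs(slope) < 1e-9
  efficiency <- if (degenerate) NA_real_ else 10^(-1 / slope) - 1

  # replicate completeness per concentration, judged against the series'
  # replicate count (the modal number of rows per concentration)
  n_per <- table(points$concentration)
  expected <- max(n_per)
  complete <- vapply(sort(unique(points$concentration), decreasing = TRUE),
                     function(k) {
                       rows <- points[points$concentration == k, ]
                       nrow(rows) == expected && !anyNA(rows$cq)
                     }, logical(1))
  all_concs <- sort(unique(points$concentration), decreasing = TRUE)
  floor_idx <- which(cumsum(!complete) == 0)  # longest complete prefix from the top
  detection_floor <- if (length(floor_idx) == 0L) NA_real_ else all_concs[max(floor_idx)]

  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = efficiency, n_points = length(cq),
                 detection_floor = detection_floor, degenerate = degenerate),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat("<standard_curve_fit>\n")
  cat(sprintf("  Cq = %.4f %+.4f * log10(conc)   (n = %d)\n",
              x$intercept, x$slope, x$n_points))
  cat(sprintf("  r^2 = %.4f, efficiency = %s, detection floor = %s ng/ul%s\n",
              x$r_squared,
              if (is.na(x$efficiency)) "undefined" else sprintf("%.1f%%", 100 * x$efficiency),
              if (is.na(x$detection_floor)) "none" else format(x$detection_floor),
              if (x$degenerate) "  [degenerate: flat series]" else ""))
  invisible(x)
}

#' Compare Cq values across multiplexing modes
#'
#' Pairwise per-concentration mean Cq differences between simplex, duplex and
#' triplex runs of the same dilution series, flagging any difference beyond an
#' equivalence margin. Used to confirm that multiplexing the probe systems
#' has no interactive effect.
#'
#' @param runs Named list of data frames (`concentration`, `cq`), one per
#'   mode, e.g. `list(simplex = ..., duplex = ..., triplex = ...)`.
#' @param margin Equivalence margin in cycles.
#' @return A tibble with `concentration`, `mode_a`, `mode_b`, `delta_cq`
#'   (mean a - mean b) and `flagged`.
#' @export
compare_multiplex_modes <- function(runs, margin = 0.5) {
  stopifnot(is.list(runs), length(runs) >= 2L, !is.null(names(runs)))
  concs <- lapply(runs, function(r) sort(unique(r$concentration)))
  for (i in seq_along(runs)[-1]) {
    if (!isTRUE(all.equal(concs[[1]], concs[[i]]))) {
      stop("runs must share the same concentration design (mode '",
           names(runs)[i], "' differs)", call. = FALSE)
    }
  }
  modes <- names(runs)
  means <- lapply(runs, function(r) {
    vapply(concs[[1]], function(k) mean(r$cq[r$concentration == k], na.rm = TRUE),
           numeric(1))
  })
  out <- list()
  for (i in seq_along(modes)) {
    for (j in seq_along(modes)) {
      if (i < j) {
        delta <- means[[i]] - means[[j]]
        out[[length(out) + 1L]] <- tibble::tibble(
          concentration = concs[[1]], mode_a = modes[i], mode_b = modes[j],
          delta_cq = delta, flagged = abs(delta) > margin
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Plot a standard curve
#'
#' @param fit A [fit_standard_curve()] result.
#' @param points The dilution points the fit was made from.
#' @return A ggplot object of Cq vs log10(concentration) with the fitted line.
#' @export
plot_standard_curve <- function(fit, points) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  df <- points[!is.na(points$cq), , drop = FALSE]
  df$log_conc <- log10(df$concentration)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_conc, y = .data$cq)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 DNA concentration (ng/ul)", y = "Cq",
      title = sprintf("Standard curve: slope %.3f, r^2 %.3f%s",
                      fit$slope, fit$r_squared,
                      if (is.na(fit$efficiency)) ""
                      else sprintf(", efficiency %.0f%%", 100 * fit$efficiency))
    ) +
    ggplot2::theme_minimal()
}
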