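# Dose-response analysis: viability normalisation, 4PL fitting with censored
# IC50s, sensitivity classification, and IC50-profile clustering.

#' Four-parameter logistic viability
#'
#' `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`.
#'
#' @param conc Concentrations (positive).
#' @param top,bottom Asymptotic viability percentages.
#' @param hill Hill slope (positive for decreasing curves).
#' @param ic50 Curve midpoint concentration.
#' @return Viability percentages.
#' @export
four_pl <- function(conc, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Normalise treated wells to percent of control
#'
#' Viability is `100 * mean(treated) / mean(control)`; the SD is the
#' replicate SD of the treated wells propagated onto the percentage scale.
#'
#' @param treated,control Numeric RFU well readings (at least one each).
#' @return Tibble with `viability` (percent) and `sd`.
#' @export
#' @examples
#' normalize_viability(c(40, 60), c(100, 100))
normalize_viability <- function(treated, control) {
  if (!length(treated) || !length(control)) {
    abort("need at least one treated and one control well")
  }
  cbar <- mean(control)
  if (!is.finite(cbar) || cbar <= 0) {
    abort("invalid plate: control mean is not positive")
  }
  v <- 100 * mean(treated) / cbar
  s <- if (length(treated) > 1) 100 * sd(treated) / cbar else 0
  tibble(viability = v, sd = s)
}

#' Summarise a plate table into per-curve viability points
#'
#' Collapses a long plate table (replicate treated and control wells) into
#' one viability curve per (drug, sample): mean percent-of-control viability
#' and replicate SD at each tested concentration.
#'
#' @param plates Long tibble with columns `drug`, `sample`, `conc`, `rfu`,
#'   `is_control` (and optionally `unit`).
#' @return Tibble: `drug`, `sample`, `conc`, `viability`, `sd` (and `unit`
#'   if supplied), concentrations increasing within each curve.
#' @export
viability_curves <- function(plates) {
  assert_cols(plates, c("drug", "sample", "conc", "rfu", "is_control"),
              "plate table")
  has_unit <- "unit" %in% names(plates)
  ctrl <- plates |>
    filter(.data$is_control) |>
    summarise(control_mean = mean(.data$rfu), .by = c("drug", "sample"))
  out <- plates |>
    filter(!.data$is_control) |>
    summarise(m = mean(.data$rfu), s = if (n() > 1) sd(.data$rfu) else 0,
              .by = dplyr::all_of(c("drug", "sample", "conc",
                                    if (has_unit) "unit"))) |>
    left_join(ctrl, by = c("drug", "sample"))
  if (any(!is.finite(out$control_mean) | out$control_mean <= 0)) {
    abort("invalid plate: control mean is not positive")
  }
  out |>
    mutate(viability = 100 * .data$m / .data$control_mean,
           sd = 100 * .data$s / .data$control_mean) |>
    select(dplyr::all_of(c("drug", "sample", if (has_unit) "unit")),
           "conc", "viability", "sd") |>
    arrange(.data$drug, .data$sample, .data$conc)
}

# Grid-search 4PL least squares over (log10 ic50, hill), profiling top and
# bottom on a coarse grid; used to initialise and as a fallback when the
# Levenberg-Marquardt fit does not converge.
fit_4pl_grid <- function(conc, viab, top_range = c(80, 120),
                         bottom_range = c(0, 40), n_grid = 40) {
  lc <- log10(conc)
  grid_lic50 <- seq(min(lc) - 1, max(lc) + 1, length.out = n_grid)
  grid_hill <- exp(seq(log(0.2), log(6), length.out = 25))
  grid_top <- seq(top_range[1], top_range[2], length.out = 9)
  grid_bottom <- seq(bottom_range[1], bottom_range[2], length.out = 9)
  best <- list(rss = Inf)
  for (top in grid_top) for (bottom in grid_bottom) {
    for (h in grid_hill) for (l in grid_lic50) {
      v <- four_pl(conc, top, bottom, h, 10^l)
      rss <- sum((viab - v)^2)
      if (rss < best$rss) {
        best <- list(top = top, bottom = bottom, hill = h, lic50 = l,
                     rss = rss)
      }
    }
  }
  best
}

#' Fit a 4PL dose-response curve and estimate the IC50
#'
#' Least-squares 4PL fit on log10 concentration with bounds
#' `top` in \[80, 120\], `bottom` in \[0, 40\] and `hill > 0`.  Start values
#' come from the extreme observed viabilities and the linear interpolation
#' of the 50% crossing.  The reported IC50 is the concentration at which the
#' fitted curve crosses 50% of control; no extrapolation is performed: when
#' the crossing lies above the top tested concentration, or the fitted curve
#' never reaches 50% within range, the IC50 is reported as the maximum
#' tested concentration with `censored = TRUE`.
#'
#' @param curve Tibble with columns `conc` (strictly increasing, positive)
#'   and `viability` (percent of control); at least 4 concentrations.
#' @param exclude_outliers Optional studentised-residual exclusion
#'   (`|t| > 3`) followed by a refit; off by default.
#' @return A `dose_response_fit` object: `top`, `bottom`, `hill`, `ic50`,
#'   `censored`, `rss`, plus the data fitted.
#' @export
#' @examples
#' conc <- exp(seq(log(2.5), log(100), length.out = 8))
#' fit <- fit_ic50(tibble::tibble(conc = conc,
#'                                viability = four_pl(conc, 100, 0, 1, 10)))
#' fit$ic50
fit_ic50 <- function(curve, exclude_outliers = FALSE) {
  assert_cols(curve, c("conc", "viability"), "viability curve")
  curve <- arrange(curve, .data$conc)
  conc <- curve$conc
  viab <- curve$viability
  if (length(conc) < 4) abort("need at least 4 concentrations to fit a 4PL")
  if (any(conc <= 0)) abort("concentrations must be positive")
  if (any(diff(conc) <= 0)) abort("concentrations must be strictly increasing")
  if (any(viab < 0)) abort("viability must be non-negative")

  fit <- fit_4pl_once(conc, viab)
  if (exclude_outliers && length(conc) >= 6) {
    res <- viab - four_pl(conc, fit$top, fit$bottom, fit$hill, 10^fit$lic50)
    s <- sd(res)
    if (s > 0) {
      keep <- abs(res / s) <= 3
      if (sum(keep) >= 4 && any(!keep)) {
        fit <- fit_4pl_once(conc[keep], viab[keep])
        conc_kept <- conc[keep]; viab_kept <- viab[keep]
        curve <- tibble(conc = conc_kept, viability = viab_kept)
        conc <- conc_kept; viab <- viab_kept
      }
    }
  }

  # 50% crossing of the fitted curve (percent-of-control scale).
  top <- fit$top; bottom <- fit$bottom; hill <- fit$hill
  ic50_param <- 10^fit$lic50
  ratio <- (top - 50) / (50 - bottom)
  cmax <- max(conc)
  if (!is.finite(ratio) || ratio <= 0) {
    ic50 <- cmax; censored <- TRUE
  } else {
    crossing <- ic50_param * ratio^(1 / hill)
    if (crossing > cmax) {
      ic50 <- cmax; censored <- TRUE
    } else {
      ic50 <- crossing; censored <- FALSE
    }
  }
  structure(
    list(top = top, bottom = bottom, hill = hill, ic50 = ic50,
         censored = censored, rss = fit$rss, ic50_param = ic50_param,
         data = curve),
    class = "dose_response_fit"
  )
}

fit_4pl_objective <- function(lc, viab) {
  function(p) {
    pred <- p[2] + (p[1] - p[2]) / (1 + 10^((lc - p[4]) * p[3]))
    sum((viab - pred)^2)
  }
}

polish_4pl <- function(lc, viab, start) {
  obj <- fit_4pl_objective(lc, viab)
  lower <- c(80, 0, 1e-3, min(lc) - 3)
  upper <- c(120, 40, 20, max(lc) + 3)
  start <- pmin(pmax(start, lower), upper)
  res <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(factr = 1e3, pgtol = 1e-12, maxit = 500)),
    error = function(e) NULL)
  if (is.null(res)) return(list(par = start, value = obj(start)))
  res
}

fit_4pl_once <- function(conc, viab) {
  lc <- log10(conc)
  top0 <- min(max(viab), 120); top0 <- max(top0, 80)
  bottom0 <- max(min(viab), 0); bottom0 <- min(bottom0, 40)
  # linear interpolation of the 50% crossing for the start value
  lic50_0 <- if (any(viab <= 50) && any(viab >= 50)) {
    below <- which(viab <= 50)[1]
    if (below > 1) {
      x1 <- lc[below - 1]; x2 <- lc[below]
      y1 <- viab[below - 1]; y2 <- viab[below]
      if (y1 != y2) x1 + (50 - y1) * (x2 - x1) / (y2 - y1) else mean(lc)
    } else lc[1]
  } else mean(lc)

  # Levenberg-Marquardt from the data-driven start, then a bounded
  # quasi-Newton polish; both are tried because each can stall on its own
  # (L-M reports singular gradients at near-perfect fits).
  lm_fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      viab ~ bottom + (top - bottom) / (1 + 10^((lc - lic50) * hill)),
      start = list(top = top0, bottom = bottom0, hill = 1, lic50 = lic50_0),
      lower = c(top = 80, bottom = 0, hill = 1e-3, lic50 = min(lc) - 3),
      upper = c(top = 120, bottom = 40, hill = 20, lic50 = max(lc) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    p <- coef(m)[c("top", "bottom", "hill", "lic50")]
    list(par = unname(p), value = sum(stats::resid(m)^2))
  }, error = function(e) NULL)

  cand <- list(polish_4pl(lc, viab, c(top0, bottom0, 1, lic50_0)))
  if (!is.null(lm_fit)) {
    cand <- c(cand, list(polish_4pl(lc, viab, lm_fit$par)), list(lm_fit))
  }
  best <- cand[[which.min(map_dbl(cand, "value"))]]

  # Coarse grid rescue when the local fits are poor (RMSE above 5 points).
  if (best$value > length(conc) * 25) {
    grid <- fit_4pl_grid(conc, viab)
    polished <- polish_4pl(lc, viab,
                           c(grid$top, grid$bottom, grid$hill, grid$lic50))
    if (polished$value < best$value) best <- polished
  }
  if (!is.finite(best$value)) {
    abort("4PL fit failed to converge; inspect the viability curve")
  }
  list(top = best$par[1], bottom = best$par[2], hill = best$par[3],
       lic50 = best$par[4], rss = best$value)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>\n")
  cat(sprintf("  top %.1f  bottom %.1f  hill %.2f\n", x$top, x$bottom, x$hill))
  cat(sprintf("  ic50 %.4g%s  rss %.3g\n", x$ic50,
              if (x$censored) " (censored, > max tested)" else "", x$rss))
  invisible(x)
}

#' Default per-drug sensitivity cutoffs
#'
#' Highly sensitive lines are defined per drug as IC50 at or below 30 uM
#' (5-FU), at or below 10 uM (oxaliplatin) and strictly below 80 nM
#' (BEZ235).
#'
#' @return Tibble: `drug`, `threshold`, `comparison`
#'   (`"at_or_below"` or `"strictly_below"`).
#' @export
sensitivity_cutoffs <- function() {
  tibble(
    drug = c("5-FU", "L-OHP", "BEZ235"),
    threshold = c(30, 10, 80),
    comparison = c("at_or_below", "at_or_below", "strictly_below")
  )
}

#' Classify per-drug sensitivity from IC50s
#'
#' Applies the configured threshold comparison per drug.  Censored IC50s
#' (true value above the tested range) are never classified sensitive.
#'
#' @param calls Tibble with columns `drug`, `sample`, `ic50`, `censored`.
#' @param cutoffs Cutoff table as from [sensitivity_cutoffs()].
#' @return The input with a `sensitivity` column
#'   (`"sensitive"` / `"less_sensitive"`).
#' @export
classify_sensitivity <- function(calls, cutoffs = sensitivity_cutoffs()) {
  assert_cols(calls, c("drug", "sample", "ic50", "censored"), "IC50 calls")
  unknown <- setdiff(unique(calls$drug), cutoffs$drug)
  if (length(unknown)) {
    abort(sprintf("no sensitivity cutoff configured for drug(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  calls |>
    left_join(cutoffs, by = "drug") |>
    mutate(sensitivity = if_else(
      !.data$censored &
        if_else(.data$comparison == "at_or_below",
                .data$ic50 <= .data$threshold,
                .data$ic50 < .data$threshold),
      "sensitive", "less_sensitive")) |>
    select(-"threshold", -"comparison")
}

#' Fit all curves in a plate table
#'
#' Convenience wrapper: [viability_curves()] then [fit_ic50()] per
#' (drug, sample), returning a tidy table of curve parameters and IC50
#' calls.
#'
#' @param plates Long plate tibble (see [viability_curves()]).
#' @param cutoffs Optional cutoff table; when supplied, a `sensitivity`
#'   column is added via [classify_sensitivity()].
#' @return Tibble: `drug`, `sample`, (`unit`), `top`, `bottom`, `hill`,
#'   `ic50`, `censored`, `rss` (and `sensitivity`).
#' @export
fit_panel_ic50 <- function(plates, cutoffs = NULL) {
  curves <- viability_curves(plates)
  has_unit <- "unit" %in% names(curves)
  fits <- curves |>
    tidyr::nest(points = dplyr::any_of(c("conc", "viability", "sd"))) |>
    mutate(fit = map(.data$points, fit_ic50)) |>
    mutate(top = map_dbl(.data$fit, "top"),
           bottom = map_dbl(.data$fit, "bottom"),
           hill = map_dbl(.data$fit, "hill"),
           ic50 = map_dbl(.data$fit, "ic50"),
           censored = map_lgl(.data$fit, "censored"),
           rss = map_dbl(.data$fit, "rss")) |>
    select(dplyr::all_of(c("drug", "sample", if (has_unit) "unit")),
           "top", "bottom", "hill", "ic50", "censored", "rss")
  if (!is.null(cutoffs)) fits <- classify_sensitivity(fits, cutoffs)
  fits
}

#' Cluster samples by their IC50 profiles
#'
#' Hierarchical clustering of samples with distance `1 - Pearson r` between
#' IC50 profiles across drugs and complete linkage.  Censored IC50s are
#' expected already imputed at the maximum tested concentration.  Samples
#' with zero-variance profiles are dropped with a warning; leaf order is
#' made deterministic by sorting samples by id before agglomeration.
#'
#' @param ic50_wide Tibble with a `drug` column and one column per sample.
#' @return An [stats::hclust] tree over samples.
#' @export
cluster_ic50_profiles <- function(ic50_wide) {
  assert_cols(ic50_wide, "drug", "IC50 matrix")
  m <- as.matrix(ic50_wide[, setdiff(names(ic50_wide), "drug")])
  m <- m[, order(colnames(m)), drop = FALSE]
  if (ncol(m) < 2) abort("need at least 2 samples to cluster")
  v <- apply(m, 2, var)
  if (any(v == 0)) {
    warn(sprintf("dropping zero-variance profile(s): %s",
                 paste(colnames(m)[v == 0], collapse = ", ")))
    m <- m[, v > 0, drop = FALSE]
  }
  d <- as.dist(1 - cor(m, method = "pearson"))
  hclust(d, method = "complete")
}
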