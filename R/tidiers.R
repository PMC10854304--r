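#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a covariate-adjusted group comparison
#'
#' @param x A `dr_ancova` from [ancova_group_effect()].
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, plus the group-term
#'   test columns.
#' @export
tidy.dr_ancova <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = sub("^\\.group", "group", rownames(s)),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.dr_ancova
#' @export
glance.dr_ancova <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, group_effect = x$group_effect,
    f_stat = x$f_stat, df_num = x$df_num, df_den = x$df_den,
    p_value = x$p_value, n = x$n,
    r_squared = summary(x$fit)$r.squared
  )
}

#' Tidy a spectral decomposition
#'
#' @param x A `decomposition_result` from [fit_full()].
#' @param ... Unused.
#' @return `tidy()`: one row per (grid cell, component) with positive
#'   spectral value; `glance()`: one-row fit summary.
#' @export
tidy.decomposition_result <- function(x, ...) {
  cs <- x$components
  purrr::map_dfr(seq_len(cs$K), function(k) {
    v <- cs$spectra[, k]
    keep <- v > 0
    tibble::tibble(component = k,
                   t2star = cs$grid$cells$t2star[keep],
                   adc = cs$grid$cells$adc[keep],
                   value = v[keep])
  })
}

#' @rdname tidy.decomposition_result
#' @export
glance.decomposition_result <- function(x, ...) {
  tibble::tibble(
    K = x$components$K,
    sse = x$sse,
    final_objective = x$objective_trace[length(x$objective_trace)],
    iterations = length(x$objective_trace),
    restarts = x$restarts_used,
    converged = x$converged,
    seed = x$seed,
    n_voxels = sum(vapply(x$weight_maps,
                          function(w) nrow(w$weights), numeric(1)))
  )
}

#' Plot component T2*-ADC spectra
#'
#' Faceted heatmaps of each component's spectrum over the log-spaced
#' (T2*, ADC) grid, with the free-water diffusivity line marked.
#'
#' @param object A `component_set` or `decomposition_result`.
#' @param free_water_adc Reference line (0.3 mm^2/s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.component_set <- function(object, free_water_adc = 0.3, ...) {
  df <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble::tibble(component = paste("component", k),
                   t2star = object$grid$cells$t2star,
                   adc = object$grid$cells$adc,
                   value = object$spectra[, k])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$t2star, .data$adc,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_hline(yintercept = free_water_adc, linetype = "dashed",
                        colour = "white", linewidth = 0.3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "T2* (s)", y = "ADC (mm²/s)",
                  fill = "spectral\nmass")
}

#' @rdname autoplot.component_set
#' @export
autoplot.decomposition_result <- function(object, ...) {
  autoplot.component_set(object$components, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mean component weightings across gestation
#'
#' One panel per component, points per scan coloured by group, with a
#' smoothing line per group -- the standard way component weightings are
#' inspected across gestation.
#'
#' @param records Cohort tibble with `weight_1..K`, `ga_weeks`, `group`.
#' @param K Number of components (inferred from columns when NULL).
#' @return A ggplot object.
#' @export
plot_weightings_ga <- function(records, K = NULL) {
  wcols <- grep("^weight_\\d+$", names(records), value = TRUE)
  if (!is.null(K)) wcols <- paste0("weight_", seq_len(K))
  long <- tidyr::pivot_longer(records, dplyr::all_of(wcols),
                              names_to = "component", values_to = "weighting")
  long$component <- factor(long$component, levels = wcols,
                           labels = paste("component",
                                          seq_along(wcols)))
  ggplot2::ggplot(long, ggplot2::aes(.data$ga_weeks, .data$weighting,
                                     colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~component) +
    ggplot2::coord_cartesian(ylim = c(0, 0.8)) +
    ggplot2::labs(x = "gestational age (weeks)",
                  y = "mean ROI weighting")
}

#' Plot a scalar cohort summary across gestation
#'
#' @param records Cohort tibble.
#' @param outcome Column name (e.g. `"mean_t2star"`).
#' @return A ggplot object.
#' @export
plot_summary_ga <- function(records, outcome = "mean_t2star") {
  ggplot2::ggplot(records, ggplot2::aes(.data$ga_weeks,
                                        .data[[outcome]],
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "gestational age (weeks)", y = outcome)
}
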